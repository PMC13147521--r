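arm	bp	cM
2L	0	0.0
2L	580000	0.3
2L	4600000	13.0
2L	13000000	31.0
2L	18700000	48.5
2L	22000000	54.8
2L	23513712	55.0
2R	0	55.0
2R	6000000	55.5
2R	8900000	57.5
2R	12700000	67.0
2R	16700000	75.5
2R	22500000	100.5
2R	25286936	107.0
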