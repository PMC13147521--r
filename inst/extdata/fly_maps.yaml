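# Chromosome geometries mirroring the dm6 assembly.
# het_boundary = euchromatin/pericentric-heterochromatin boundary, expressed
# as distance in bp from the telomeric end of the arm (H3K9me3 domain edges,
# rounded; configuration constants, not inferred from data).
# gap_length = unassembled centromeric satellite region between arm
# assemblies; carries no SNPs and no crossovers.
chromosomes:
  - name: "2"
    shape: metacentric
    gap_length: 4000000
    arms:
      - name: "2L"
        length: 23513712
        orientation: telomere_to_centromere
        het_boundary: 22000000
      - name: "2R"
        length: 25286936
        orientation: centromere_to_telomere
        het_boundary: 19286936   # assembly [0, 6.0 Mb] is pericentric
  - name: "3"
    shape: metacentric
    gap_length: 4000000
    arms:
      - name: "3L"
        length: 28110227
        orientation: telomere_to_centromere
        het_boundary: 23000000
      - name: "3R"
        length: 32079331
        orientation: centromere_to_telomere
        het_boundary: 23879331   # assembly [0, 8.2 Mb] is pericentric
  - name: "X"
    shape: telocentric
    gap_length: 0
    arms:
      - name: "X"
        length: 23542271
        orientation: telomere_to_centromere
        het_boundary: 21400000
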