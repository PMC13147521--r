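---
title: "ndjmap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ndjmap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ndjmap` simulates and analyses spontaneous meiotic nondisjunction (NDJ) of a
metacentric chromosome, modelled on *Drosophila melanogaster* chromosome 2.
The experimental design it emulates recovers viable maternal disomy-2 males
through a cross to a compound-chromosome stock, backcrosses each male to
homozygous *w1118* females, and sequences each male's pooled offspring. This
vignette documents the generative model, the inference machinery, the
parameter defaults and their rationale, and the limits of what the simulation
can establish about real data.

## Coordinate model

All geometry lives in a `chromosome_map`: arms with lengths, orientation
flags, and per-arm euchromatin/heterochromatin boundaries (taken as
configuration constants mirroring dm6 and somatic H3K9me3 domains — the
package never infers them). Because dm6 stores 2L telomere-to-centromere and
2R centromere-to-telomere, every distal/proximal computation is phrased on a
"distance from the telomere" axis derived from the orientation flag, and a
single chromosome axis (left telomere → centromeric gap → right telomere)
indexes positions chromosome-wide. The unassembled centromeric satellite is
an explicit gap: it carries no SNPs and no crossovers, but a state change
across it is representable and is tested for by `call_cross_gap_event()`.

Two zone predicates drive the NDJ cause categories:

* **Distal**: `chromosome_fraction_from_telomere()` at most 0.24. The 24%
  figure originates from the distalmost marker interval of the classic
  telocentric X-chromosome data; for a metacentric chromosome the package
  applies it per arm by default because no convention exists for the
  metacentric case — `distal_scope = "per_chromosome"` is available, and the
  choice is a configuration, not a fit.
* **Pericentric**: inside the heterochromatin, or within the most proximal
  15% of the arm's euchromatin (again interval-derived on the X; here 15% of
  *that arm's* euchromatin, configurable via `pericentric_eu_fraction`).

On the shipped maps the two zones never overlap (asserted in the tests); on
pathological toy maps where they could, the categorizer's fixed precedence
applies and a warning is emitted.

Genetic-map positions for double-crossover distances come from a supplied
bp→cM anchor table with piecewise-linear interpolation, clamped at the
outermost anchors.

## Generative model

A meiosis is a four-chromatid bivalent. Per arm, a crossover count is drawn
from `co_count_dist` over {0, 1, 2}; positions are uniform over the
euchromatin by default (crossovers are suppressed in the pericentric
heterochromatin). Each crossover involves one chromatid of each homolog,
chosen uniformly and independently among the four non-sister pairs — no
chromatid interference and no crossover interference, matching the
assumptions of the chromatid-sampling probability model the package
reproduces. A gamma-renewal interference model was deliberately not added:
every detection probability below is an exact enumeration under the
no-interference assumption, and an interference knob would silently break
that correspondence.

Parental origin of a chromatid is anchored at its **centromere**: a
crossover at position *x* exchanges the telomere-distal material, so origin
at *p* is the host homolog's origin flipped once per breakpoint between *p*
and the centromere. This is the representation in which the classifier's
ground truth holds *by construction*: progeny of a meiosis I error (one
chromatid per homolog) are heterozygous across the centromere; progeny of a
meiosis II error (both sisters of one homolog) and monosomy-rescue progeny
(one chromatid duplicated) are homozygous there.

Segregation modes return 1 chromatid (`NORMAL`), one per homolog
(`MI_NDJ`), both sisters of one homolog (`MII_NDJ`), or one duplicated
(`MONOSOMY_RESCUE`).

**Pooled sequencing.** The backcross mother contributes a *w1118* (P2)
homolog to every offspring; males do not recombine, so the father's two
chromosome copies are transmitted unaltered, splitting the pool once per
sample as Binomial(`pool_size`, 1/2). At a SNP the pooled frequency of the
Oregon R-like (P1, "alt") allele is (P1 copies among transmitted
chromosomes) / (2 × pool size): in expectation 0, 0.25 and 0.5 for the
homozygous-P2, heterozygous and homozygous-P1 genotype states of a
two-chromatid father, and {0, 0.25} for single-chromatid tracks (the model
used for chromosomes X and 3 of the NDJ male). Depth is Poisson per SNP and
alt reads are Binomial at the error-adjusted frequency
`f(1-e) + (1-f)e`.

A consequence worth stating explicitly, because it shapes the caller: the
**homozygous levels are exact** (all paternal copies agree, so the pool
split cancels), while the realized heterozygous level is `0.25 ± δ` with
`δ = |n₁/pool − 1/2|/2` — a per-sample offset that phase-flips wherever
both transmitted chromatids carry the same breakpoint (a reciprocal
exchange, which carries no genotype-state information).

## Detection-probability model

`detection_probability()` enumerates, exactly, all equally likely
inheritance outcomes for a mode and crossover configuration (marginalizing
uniformly over the 4^k chromatid-pair assignments when they are not fixed)
and counts the outcomes whose noiseless state track is non-constant. For a
single crossover this yields the chromatid-sampling argument in closed
form: 50% detection for a normal meiosis, 50% for MI NDJ — the inheritance
classes being 50% one recombinant + one non-recombinant (detectable), 25%
reciprocal recombinants and 25% double non-recombinant (both fully
heterozygous, undetectable) — and 100% for MII NDJ. These enumerations are
the package's oracle: the Monte-Carlo segregation path and the full
simulate-plus-segment pipeline are both required (in the tests) to converge
to them, and the `co_class_fractions()` MII adjustment (halve the MII
single-crossover fraction, leave doubles alone, never renormalize) and the
`coefficient_of_exchange()` corrections (×2 for normal/MI sampling, ×1 for
MII) are derived from them at run time rather than hard-coded.

## Crossover calling

The published analysis identified crossovers by eye as "persistent" changes
in allele frequency. The package's deterministic surrogate is a maximum
a-posteriori state path under binomial emissions with a uniform
per-transition penalty (`switch_penalty = log(1e4)`: a state change must be
supported by about four orders of magnitude of likelihood), followed by
merging of segments shorter than `min_segment_snps = 10` into the cheaper
neighbour — the operational meaning of "persistent". Both parameters are
declared configuration, not values fitted to any dataset.

Two refinements address the sperm-split structure of pooled data:

* **Split heterozygous levels.** The per-sample offset δ is estimated by
  profile likelihood of a symmetric two-level mixture over the SNPs
  initially assigned to the heterozygous state; when it exceeds
  `min_het_split` the track is re-segmented with the heterozygous state
  split into its two phase sublevels. The sublevels share one label, so
  phase switches — real features of the pool, but not genotype-state
  changes — never become crossover calls.
* **Homozygous-segment validation.** A segment labelled with a noise-free
  state whose aggregate frequency is explained decisively better
  (likelihood ratio above `hom_lrt_crit`) by a level inside the
  heterozygous split band is relabelled: it is a shifted heterozygous
  stretch, not a homozygous island. Constraining the alternative to the
  split band is essential — an unconstrained alternative would reject
  error-free homozygous segments at a rate of `seq_error` nats per read.
  Validation runs before short-segment merging so absorbed SNPs of a
  different true state cannot contaminate the segment tests.

**Call intervals.** A crossover call is emitted at each boundary between
segments of different state labels. The reported flanking SNPs bound the
smallest local change-point credible set covering `flank_confidence`
(default 0.999) of the boundary posterior, computed from the emission
likelihoods of the two adjoining segments. With clean data this collapses
to the last SNP of the left segment and the first of the right; where the
boundary is data-limited (e.g. HET vs HOM_P1 at depth 30 gives only ~4 nats
per SNP, so the maximum-likelihood boundary wobbles by ±1–2 SNPs with a few
percent probability) the interval widens to say so. The crossover point
estimate is the interval midpoint, and the interval is always reported —
resolution is polymorphism-density-limited by design.

Direct `HOM_P1 ↔ HOM_P2` transitions are flagged rather than treated as
ordinary calls: in a two-chromatid track they cannot arise from a single
crossover unless both inherited chromatids share the breakpoint, and in a
track with no heterozygous segment anywhere they are the diagnostic
signature of monosomy rescue with a recombinant chromatid. They still count
as one crossover site in the per-event tallies.

## Classification

`classify_division()` reads the innermost segment state within a
pericentric window on each side of the centromere (the heterochromatin plus
`pericentric_pad` = 1 Mb of adjacent euchromatin, capped at half the arm's
euchromatin so small test maps keep a meaningful window): heterozygous →
MI, homozygous → MII. Discordant sides or absent pericentric coverage give
an explicit undetermined result with a warning — never a silent resolution.
`flag_monosomy_rescue()` implements the three-way outcome: any heterozygous
segment rules rescue out; a homozygous track with a `HOM↔HOM` switch is a
definite candidate; a single-state homozygous track is reported as
ambiguous (indistinguishable from a no-crossover MII event).
`categorize_cause()` applies the fixed precedence NO_CO → DISTAL_CO
(all calls distal) → PERICENTRIC_CO (any pericentric call) → OTHER; the
result is invariant to call order.

## Defaults and their provenance

| Parameter | Default | Why |
|---|---|---|
| `n_events` | 63 | size of the analyzed cohort the simulator emulates |
| `mode_mixture` | MI 49/63, MII 14/63 | the cohort's MI/MII composition; rescue 0 (none observed) |
| `co_count_dist` | {0.37, 0.53, 0.10} per arm | gives ~13.7% of chromosomes with no crossover on either arm, anchoring to the ~13.4% zero-crossover fraction of normal meioses |
| `pool_size` | 50 | plausible single-male backcross offspring pool; unstated in the source design, declared here |
| `mean_depth` | 30 reads/SNP | typical pooled nanopore coverage after enrichment; declared |
| `seq_error` | 0.005 | per-read flip probability; declared |
| `snp_spacing` | 20 kb | ~2,400 informative SNPs on chromosome 2 — about 2% of the real panel, chosen so a 500-event cohort segments in under a minute while leaving ≥10 SNPs in every resolvable segment |
| `min_depth` | 8 | the published per-observation depth cutoff |
| `min_var` | 0.01 | the published population-variance cutoff; computed on alt-allele frequencies with the divide-by-*n* estimator (the estimator is not specified in the source; the choice is documented and configurable) |
| low-coverage sample rule | ≥50% of panel at depth ≥8 | an explicit surrogate for the by-eye exclusion of low-coverage males; a threshold, not a tuned value |

## Numerical choices and degenerate inputs

Emission probabilities are clamped to `[1e-12, 1-1e-12]` so `seq_error = 0`
stays finite. Empty tracks give empty segmentations; empty cohorts flow
through the whole pipeline and produce valid, headed outputs. Ties in the
short-segment merge resolve toward the neighbour with the higher emission
likelihood over the merged stretch. The Mann-Whitney implementation uses
exact enumeration of the permutation distribution for total n ≤ 12 (valid
under ties, since it conditions on the observed values) and a tie- and
continuity-corrected normal approximation otherwise; the two-proportion z
applies the Yates correction capped at the observed difference, so its
two-sided p coincides with the corrected chi-square. One-tailed directions
must always be supplied by the caller.

## Problem sizes

The shipped tests segment a 500-event cohort at 20 kb SNP spacing and depth
30, and run 20,000-replicate Monte-Carlo checks of the detection model; the
acceptance script's Monte-Carlo target uses 20,000 simulated meioses
through the full read-sampling and segmentation path. These sizes give
binomial standard errors of ~0.35% on detection fractions — comfortably
inside the comparisons they serve.

## What the simulation does and does not establish

The simulator reproduces the *logical* structure of the assay: chromatid
sampling per segregation mode, the backcross dosage arithmetic, pool-split
and read-level noise, depth variation, pericentric crossover suppression,
and the unassembled gap. Passing tests therefore establish that the caller
and classifiers recover the truth of that model, including its analytic
detection probabilities.

Real data differ in ways the defaults deliberately do not model: crossover
interference (real double crossovers are > 2 Mb apart; the simulator's
independent placement occasionally produces closer pairs, which no
persistence-based caller can resolve — the tests treat such configurations,
and crossovers within one persistence scale of a telomere, as out of
resolution), non-uniform SNP density and coverage (adaptive sampling),
segmental depth artefacts, and reference/alignment error. Two known
limitations follow directly from the model: an MII event whose double
crossover encloses a heterozygous tract shorter than the persistence scale
is genuinely indistinguishable from monosomy rescue with a recombinant
chromatid; and crossovers within ~`min_segment_snps × snp_spacing` of a
track end are undetectable, which biases Monte-Carlo detection estimates
downward by a few tenths of a percent relative to the analytic 50%.

Cohort-level published quantities that depend on the real sequencing data
(the exact MI/MII fraction contrast, the 40.8% zero-crossover MI fraction,
the cause-category percentages) are not desk-reproducible; the pipeline is
instead required to produce internally consistent tables that converge to
its own generative truth, with the published normal-meiosis summary values
available as display-only reference constants
(`normal_meiosis_reference()`).
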