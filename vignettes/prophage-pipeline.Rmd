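---
title: "Models and methods behind prophagekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prophagekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prophagekit)
```

prophagekit implements the computational core of a prophage activity
study in a lysogenic bacterium such as *Vibrio natriegens*: locating
induced prophages in supernatant sequencing coverage, modelling the
site-specific recombination that excises them, quantifying spontaneous
prophage induction (SPI) by absolute qPCR, simulating the competitive
cost of carrying an inducible prophage, and comparing phage genomes by
MinHash sketches and fragment ANI. This vignette explains each model,
its assumptions, the defaults, and what the synthetic data generator
does and does not emulate.

## The attachment-site recombination model

A temperate phage integrates into the host chromosome by recombination
between a phage attachment site (attP) and a bacterial site (attB) that
share a short *core* sequence. Integration leaves hybrid sites attL and
attR flanking the prophage, each carrying one copy of the core — an
exact direct repeat at the two prophage–host junctions. Excision is the
reverse reaction: attL × attR → attB + attP.

`find_att_core()` exploits the direct repeat: it searches windows
(default 1000 bp) around each annotated region boundary for the longest
exact common substring with one copy near the region start and one near
the region end, breaking ties by proximity to the boundaries and then
leftmost position. The search is a binary search over repeat lengths
with substring-set intersection at each candidate length; the test
suite checks it against a dynamic-programming longest-common-substring
oracle. Matching is exact by design: attachment cores are exact repeats,
and a mismatch-tolerant mode is deliberately out of scope. Absence of a
repeat of at least `min_len` (default 10 bp) is a regular "no core
found" result, not an error.

The crossover is parameterised by a single integer k, the number of
leading core positions contributed by the donor site under 0-based
half-open slicing:

  * `attB = attL[0:k] + attR[k:]`
  * `attP = attR[0:k] + attL[k:]`

This single-crossover model rearranges but never invents bases: at
every core position i the unordered pair {attB[i], attP[i]} equals
{attL[i], attR[i]}. When attL and attR differ (an "impaired" core),
different k give different products, and `infer_crossover_interval()`
reports the full set of k consistent with an observed attP. That set is
always a contiguous interval — the prefix constraint is downward-closed
in k and the suffix constraint upward-closed — and an empty interval is
reported explicitly, meaning no single crossover explains the
observation (gene conversion or staggered-cut repair would be needed,
which this package does not model because the observed sequences do not
require it).

`excise()` applies the model to a genome: the host keeps a single
reconstituted attB core at the junction, and the phage leaves as a
circle whose junction core is attP. The returned circle sequence is the
full excised interval as a linear string — attL core, phage interior,
attR core — because that is the annotated entity with printed
coordinates; on circularisation the two terminal cores collapse into
the single attP junction. This representation makes the length
bookkeeping `len(host) + len(circle) = len(genome) + core_length` hold
exactly, with one core copy counted twice in the two linear sequences.
`integrate_phage()` inverts the operation (attB × attP → attL + attR)
and is an exact inverse of `excise()` for any k, impaired cores
included.

Published interval sizes mix two coordinate conventions — the same
printed coordinate pair can be reported as `end - start + 1` (1-based
inclusive) or `end - start` — so `region_length()` requires an explicit
`convention` argument and the package never guesses which one a given
printed size used. Internally all coordinates are 0-based half-open;
`printed_to_internal()` / `internal_to_printed()` convert.

## Coverage enrichment

After induction, lysed cells release phage DNA into the culture
supernatant; sequencing supernatant DNA yields coverage that is flat at
a residual host-gDNA background and elevated over induced prophage
regions. The model is additive: if a fraction f of cells induces a
phage with burst size b, the expected in-region depth is
`background * (1 + f * b)`.

* `estimate_background()` uses the median outside excluded regions
  (robust against the enriched regions themselves; the mean is an
  option, and is what the closed-form calibration tests use because the
  median of discrete counts sits slightly below the mean).
* `detect_enriched_segments()` smooths with a centered running mean
  (odd window, default 501 bp, truncated at the edges), takes maximal
  runs above `min_fold × background` (default 3), merges runs separated
  by under 1 kb, and drops runs under 5 kb — thresholds chosen so that
  genuine prophages (tens of kb, ≥10-fold enriched) are kept and local
  coverage noise is not.
* `refine_boundaries()` re-places each boundary at the split minimising
  the total squared error of a two-segment piecewise-constant fit
  within a window around it. The split is computed from cumulative
  sums in linear time and is checked in the tests against a naive
  per-split scan; a constant window is flagged degenerate and the
  boundary left unchanged. A generic change-point package would work
  here too, but the step fit is fully specified and oracle-checkable.
* `enrichment_ratio()` compares two phages by *excess* enrichment,
  `(fold_a − 1)/(fold_b − 1)`: phage DNA adds to, rather than replaces,
  the host background, so the released-DNA amounts are proportional to
  the excess, not the fold. The plain fold ratio is selectable. When
  the denominator's fold is ≤ 1 the excess ratio is undefined and
  returned as `NA` with a warning.

All statistics are invariant to rescaling the whole track, which is the
right property for "arbitrary unit" coverage: only ratios are
meaningful, absolute depths are not recoverable.

## The qPCR quantification chain

SPI is quantified by amplifying the attB junction, which exists only in
chromosomes that have excised the prophage. The chain is standard
absolute quantification:

1. `fit_standard_curve()`: OLS of Ct on log10(concentration) over a
   1:10 dilution series (all replicate points, not level means).
   Efficiency is `10^(−1/slope) − 1`; a slope of −3.3219 cycles per
   decade (−1/log10(2)) is perfect doubling. Curves with R² ≤ 0.95 are
   returned as rejected objects carrying their values, and
   `quantify()` refuses rejected curves.
2. `quantify()`: per-replicate inversion `10^((Ct − intercept)/slope)`,
   then averaging on the concentration scale (a geometric mean on the
   Ct scale), which is standard practice. A missing Ct is the
   no-amplification sentinel and contributes amount 0 — representing
   no-amplification as Ct = 40 would bias curve fits and averages, so
   the package never does.
3. `normalize_amount()`: division by the amount measured for a
   single-copy genomic reference gene (thymidine kinase). Division is
   the only operation that cancels input-mass differences between
   samples, which is the stated purpose of normalization; the package
   therefore implements N = target/reference and offers no
   multiplicative variant.
4. `spi_fraction()` and `strain_ratio()`: 100 × N(sample)/N(control),
   with the fully induced prophage-free genotype (attB in every
   chromosome) or the wild type as the 100% control. Values above 100%
   are flagged, never clamped — they indicate an assay or pipetting
   problem the analyst should see.
5. `phage_to_genome_ratio()` converts circular-phage-DNA and
   reference amounts to copy numbers through the amplicon lengths; the
   per-bp mass constant cancels in the ratio.

`predict_amplicon()` provides exact-match in-silico PCR (forward primer
and downstream reverse-complemented reverse primer on either strand,
unique product required, ambiguities reported with loci). Degenerate
bases and mismatch tolerance are out of scope.

## The competition model

Carrying an inducible prophage costs the lysogen a small fraction of
its population every generation: a lineage that lyses loses its
doubling. The minimal model consistent with that statement multiplies
strain i by `2(1 − s_i)` per generation, where s_i is the
per-generation lysis (SPI) probability. A repetitive-batch cycle runs
`log2(D)` generations at full regrowth to stationary phase (D = the
dilution factor, default 200, so 7.64 generations per cycle and ~91.7
over the default 12 cycles — "about 90"), then dilutes; deterministic
dilution leaves fractions unchanged. Growth-rate differences between
strains are supported but default to equal, matching the observation
that the deletion strains grow indistinguishably from the wild type in
monoculture.

The closed form for the strain ratio R (deletion strain : lysogen)
after n generations is `R_n = R_0 (1 − s)^(−n)`, and
`estimate_selection()` inverts it: `s = 1 − (R_0/R_n)^(1/n)`. On
deterministic trajectories this recovers s to machine precision (an
exact inverse pair); on stochastic trajectories it is unbiased within
Monte-Carlo error. The stochastic mode draws binomial lysis each
generation and a multinomial bottleneck (default read-outs use 10^5
cells) at each transfer; fractional final generations divide a
`Binomial(2^θ − 1)` subset of cells so the expected growth matches the
deterministic exponent. `generations()` and `od_to_cdw()` implement the
bookkeeping conversions (`n = log2(OD_final/OD_start)`;
CDW = OD600 × 0.27 g/L).

The model attributes the whole fitness difference to SPI. Real
competition data cannot separate SPI cost from other prophage-encoded
effects (a prophage gene product may burden the host independently of
lysis), so s estimated from ratio read-outs is an upper bound on the
SPI-specific cost. This is a limitation of the read-out, not of the
estimator.

## Phage genome comparison

`sketch()` builds a bottom-s MinHash sketch (defaults k = 21, s = 1000,
the parameters used for large prophage-database searches) over
canonical k-mers. Hashes are 64-bit FNV-1a with a fixed seed passed
through a splitmix64 finaliser, truncated to the top 53 bits so each
hash is exactly representable as an R double; truncation preserves
order, and at desk scale (≤ a few hundred thousand k-mers) the
collision probability at 53 bits is negligible. `mash_distance()`
estimates Jaccard similarity j from the bottom-s sketch of the merged
hash union and converts it to a mutation-rate distance
`d = −ln(2j/(1+j))/k`, capping j = 0 at d = 1. "Mash similarity" is
defined here as `100(1 − d)` percent with hits called at ≥ 70%
(inclusive); the transform is a package definition, made configurable
because other transforms of Mash output exist.

`ani()` re-implements fragment-based average nucleotide identity: the
query is chopped into consecutive 1020-bp fragments (common ANI
practice; a trailing partial fragment is dropped), each fragment is
locally aligned against the subject on both strands (match +1,
mismatch −1, gap open −5, gap extend −2 — documented defaults, not
empirical values), and fragments passing 70% identity and 70% coverage
filters contribute their identity. No passing fragment means the ANI is
undefined (`NA`), which `classify_species()` maps to "different" with a
flag; otherwise phages below 85% ANI are different species per current
taxonomy practice. `cluster_phages()` performs agglomerative clustering
(average linkage — a deliberate choice where published analyses often
inherit a plotting package's unstated default) via `stats::hclust`,
cross-checked in the tests against a brute-force average-linkage
implementation.

## The synthetic data generator

`generate_host_genome()` builds a desk-scale stand-in for a prophage
host chromosome: 200 kb of i.i.d. background at GC 0.45 with two
implanted prophages (30 and 35 kb) flanked by exact direct repeats of
their att cores. The bases immediately outside each core copy are
resampled where needed so the implanted repeat is *maximal* — a repeat
search then provably recovers exactly the implanted core rather than a
chance extension. Default induction parameters give excess enrichments
of 10× and 70× background (induced fraction 0.1 with burst sizes 100
and 700): only the seven-fold ratio between the two phages is
observationally constrained, so the defaults are calibrated to that
ratio and the absolute values are conventional.

`simulate_supernatant_coverage()` draws per-base negative-binomial
depth (default background 10×, size 10) — real sequencing is
overdispersed relative to Poisson, and the background models residual
host gDNA in the supernatant. `simulate_qpcr_plate()` generates
standards as five 1:10 dilutions from 1 ng/µl (ending at 10⁻⁵ ng/µl)
in technical duplicates and unknowns with Gaussian Ct noise (default
sd 0.15 cycles); a zero true amount yields the no-amplification
sentinel. `simulate_competition_experiment()` couples the passage model
to deletion-junction plates at the first and last cycles. All
randomness flows from a single seed; identical seeds give identical
outputs.

What the generator does *not* emulate: read-level sequencing (FASTQ,
error models, mappability), library-preparation biases, qPCR
inhibition or multiplexing artefacts, phage reinfection dynamics, and
osmolarity-dependent physiology (salt conditions enter only as user-set
SPI/growth scenarios). Passing tests therefore demonstrate that the
estimators recover the parameters of this generative model, not that
real libraries are free of the unmodelled effects.

## Numerical choices and problem sizes

Tolerances in the calibration tests are statistical: simulated
estimates must fall within three standard errors of the closed form
(plus a hair of numerical slack), never within an arbitrary band.
Monte-Carlo problem sizes — 60-kb genomes, 25–50 coverage replicates,
40–200 plate or trajectory replicates — were chosen so each sampling
distribution is resolved well below the effect sizes being checked
while the full suite stays quick on a laptop. Deterministic claims
(recombination algebra, excision round trips, curve inversion,
selection inverse pair) are asserted at machine precision. Degenerate
inputs have defined behaviour throughout: empty crossover intervals,
"no core found" results, flat step-fit windows, undefined ANI, and
undefined excess ratios are all explicit values, not exceptions, while
contract violations (negative depths, unsorted intervals, rejected
curves, missing attB) are errors.
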