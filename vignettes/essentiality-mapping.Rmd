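---
title: "Methods: gap-null essentiality mapping from transposon insertion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gap-null essentiality mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnseqr)
```

## The experiment and its statistical problem

A mini-transposon library in a small bacterium places one insertion per
clone at quasi-random genomic positions. Clones whose insertion disrupts an
essential element die out over serial passages; sequencing
transposon–genome junctions afterwards yields, for every surviving
insertion site, a coordinate and a read count. Two signals must be
separated: *where insertions are missing* (essential sequence) and *where
low-read noise insertions linger* (dead or dying clones, cross-
contamination, mapping artifacts). The statistical problem is that an
insertion-free stretch can also be a sampling hole: with `N` insertions on
a genome of length `G`, gaps of order `G/N` are expected by chance.

## The gap-null model

Under uniform insertion, a fixed span of length `L` receives none of `N`
insertions with probability `P_N(L) = (1 - L/G)^N`
(`gap_null_probability()`, computed as `exp(N * log1p(-L/G))` to stay
accurate when `L/G` is small and `N` large). A maximal insertion-free gap
with `P_N(L) <= alpha` is called significant; `alpha = 0.01` gives the
conventional 99% confidence. The genome is treated as circular throughout:
the gap past the last site wraps through the origin, and scores are
invariant under genome rotation (property-tested).

Every base then receives exactly one of three labels:

* **E-evidence** — inside a significant insertion-free gap;
* **NE-evidence** — within `w` bp of a threshold-passing site and *not*
  inside a significant gap;
* **neither** — close to no site, but inside a gap short enough to be a
  sampling hole.

The mutual exclusivity matters. Sites flanking an essential gene always sit
within `w` of its first and last bases; if their neighbourhoods could
override gap evidence, `P_NE` would be positive for essentially every gene
and the E category would be empty. Giving gap evidence precedence keeps the
two probabilities interpretable as complementary fractions of a region:
`P_E` and `P_NE` are the E- and NE-labelled fractions, rounded half-up to
two decimals (exact integer arithmetic, so a fraction of exactly 0.005
rounds to 0.01 and 0.004999... to 0.00). The category rule is then

* `E` : `P_E > 0` and `P_NE = 0`
* `NE`: `P_E = 0` and `P_NE > 0`
* `F` : both positive (mixed evidence — e.g. one essential and one
  dispensable domain) or both zero (below the screen's resolution).

An independent per-base brute-force oracle (scan outward from every base to
its nearest sites) reproduces the interval-arithmetic implementation
exactly on random toy genomes; this equivalence is part of the test suite.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.01 | significance level of the gap null (99% confidence) |
| `w` | `ceiling(G/(2N))` bp | dispensability radius: half the mean inter-insertion spacing, so NE-evidence tiles dispensable sequence exactly when insertions are at their average density |
| `read_threshold` | calibrated | reads per insertion below which a site is ignored |
| `circular` | `TRUE` | wrap gap computation past the origin |

With a dense screen (`N/G` around 0.05–0.1/bp) `w` is a handful of base
pairs, which is what gives these screens their few-bp resolution in
dispensable sequence.

## Threshold calibration and timepoint selection

Noise insertions in essential genes have few reads; genuine insertions in
dispensable genes have many. Given gold-standard sets of known-essential
and known-dispensable genes, `calibrate_read_threshold()` scans every
integer threshold `t` and counts misclassified insertions (kept inside
E-gold genes plus discarded inside NE-gold genes). All minimisers of this
error curve are equally supported: the smallest is reported as the
*relaxed* threshold and the largest as the *stringent* one, matching their
semantics (the stringent threshold never keeps more than the relaxed one).
Ties inside the argmin set are therefore a feature, not an ambiguity. When
the two read distributions are inseparable the curve is flat, a warning is
raised, and both thresholds collapse to the smallest minimiser. The fit
applies the stringent threshold by default and reports both.

`select_timepoint()` picks the analysis day: the earliest day at which the
mean insertion count per essential-gold gene has fallen to at most
`max(0.1 x first-day value, 0.5)` while the non-essential-gold mean stays
at or above 0.8 of its first-day value (guarding against population
bottlenecks). The baseline is the first day present in the series. If the
chosen day leaves a gold class with no insertions at all (late passages can
wash essential-gene noise out entirely), the fit falls back to the latest
day where both classes carry insertions and calibrates there — thresholds
must be learned where both distributions are observable.

## Domain-level essentiality

Domains are given in 1-based amino-acid coordinates and projected onto the
genome strand-aware (`domain_to_genome()`; the stop codon belongs to no
domain). Each domain is scored like any region; inter-domain linkers are
scored too but reported `unassigned` and never drive the *differential*
flag, which is raised exactly when two assigned domains receive different
categories. Overlapping input domains are trimmed at the overlap midpoint —
deterministic and order-independent. Note that a significant gap covering
an essential domain typically overruns slightly into the neighbouring
dispensable domain (up to the first insertion there), so the dispensable
domain of a mixed protein is often called F rather than NE; the
differential flag is robust to this.

## ncRNA co-expression and smORF scanning

Antisense ncRNAs are tested for co-regulation with the ORF they overlap on
the opposite strand across a growth time course. With only ~10 timepoints,
binned mutual-information estimators are unstable, so MI is computed from
the Pearson correlation under a Gaussian model, `MI = -0.5 log(1 - r^2)` —
non-negative, zero iff `r = 0`, monotone in `|r|`. Each pair's MI is
z-scored against the background MI distribution of both partners
(negatives clipped at zero) and combined as the root mean square
`clr = sqrt((z_i^2 + z_j^2)/2)`. We use the RMS rather than the plain
Euclidean norm so that the significance threshold reads as an average
background z-score: at the 2.5 threshold the measured null exceedance rate
(50 independent features, 10 timepoints) is about 3.6%, consistent with a
5% budget, whereas the unnormalised norm exceeds it (about 7%). Significant
pairs are signed by the Pearson correlation; `r = 0` is `undetermined` and
excluded. Per ncRNA, the percentage of its anti-correlated partners that
are essential is compared with that of correlated partners by Welch's
two-sample t-test (via `stats::t.test`, Welch–Satterthwaite degrees of
freedom); two zero-variance groups with equal means return `t = 0, p = 1`
by convention.

`scan_smorfs()` translates ncRNAs in their three forward frames under
genetic code 4 — the mollicute code in which TGA encodes tryptophan and
only TAA/TAG terminate — and reports maximal start-to-stop candidates of 1
to 99 residues (bacterial starts ATG/GTG/TTG by default). Conservation and
proteomic filtering of candidates is downstream of this package.

## What the synthetic generator emulates — and what it does not

`simulate_genome()` lays out non-overlapping ORFs (450–1500 nt), smORFs
(< 100 aa), conventional RNAs, essential intergenic elements and 5'-UTRs
with at least 100 bp of intergenic spacer, plus ncRNAs that are 95%
antisense inside host ORFs. Coding sequence is built codon-wise at the
configured GC content with genuine start/stop structure under genetic code
4. Ground truth: a configurable fraction of ORFs is essential
(default benchmark 0.6, mirroring the 50–60% essential gene fraction of
genome-reduced bacteria and yielding roughly a third to 40% essential
genome); fitness genes are generated as mixed-domain proteins with one
essential and one dispensable domain, so partial insertion depletion — not
a stochastic intermediate fitness coefficient — is what makes them F.
Antisense ncRNAs inherit their host ORF's truth (an independently essential
antisense ncRNA inside a dispensable ORF would be indistinguishable from a
partially essential host at the DNA level); only intergenic ncRNAs can be
independently essential.

`simulate_insertions()` places insertions uniformly at `insertion_rate_ne`
per dispensable bp and `noise_rate_e` per essential bp, optionally thinned
by `quadruplet_bias` at positions whose surrounding 4-mer (junction base
−1..+2) has ≥ 3 G/C. Read counts are negative binomial with overdispersion
`phi` (`Var = mu + phi mu^2`, the parameterisation used throughout
count-based genomics; default `phi = 0.5`, i.e. NB size 2 — heavy enough
that calibration is non-trivial while the gold-set read distributions stay
bimodal). Essential-insertion read means decay exponentially
(`decay_halflife_days`, default 2 d) from the first passage day; a site
whose drawn count is zero is absent from that day's table, which is how
essential-gene insertions vanish over passages. `simulate_expression()`
builds standard-normal profiles, plants each antisense pair as an exact
copy or exact negative of its host before adding Gaussian noise to all
values (so a planted pair's population correlation is `±1/(1 + sd^2)`,
about 0.9 in magnitude at the default `sd = 0.3`, and exactly `±1`
noiseless), and can couple the anti-correlation probability to host
essentiality (`anticorr_e_weight`) to give enrichment analyses a
generative truth.

Not emulated: sequencing base-call errors (beyond construction), PCR
duplicates, chromosomal replication-origin coverage bias, condition-
dependent essentiality, and real growth competition beyond exponential
decay. Passing tests on these simulations therefore demonstrate
correctness of the inference given the model's assumptions — not
robustness to every artifact of real libraries.

## Numerical and design choices

* **Benchmark sizes.** The test suite runs the full recovery benchmark on
  ten 200 kb screens (120 ORFs each), the calibration benchmark on fifty
  50 kb screens, scoring-oracle equivalence on one hundred 10 kb toy
  genomes, and CLR null/power on one hundred 50 x 10 matrices — sizes at
  which every property is measured on hundreds of features within minutes
  on one core.
* **Mapping.** Junction flanks are mapped by unique exact k-mer seed
  (default `k = 20`, refusing `k < 12` as an ambiguity floor for
  sub-megabase genomes); multi-locus seeds are counted ambiguous, never
  called. An aligner would add dependencies without changing desk-scale
  behaviour; the mapper is not the method's contribution.
* **Orientation.** Opposite-orientation sites at one position are kept
  distinct through insertion calling (the mini-transposon carries an
  internal promoter, so orientation is biologically meaningful) and merged
  for scoring, where only position matters. Only the 5' read prefix is
  interrogated for the inverted repeat — reads with internal or double IRs
  are a documented limitation.
* **Degenerate inputs.** `N = 0` (no threshold-passing insertion) is an
  error, not a result: every gap is maximal and the model collapses.
  Zero-variance expression features score zero MI with a warning. A gold
  class with no insertions anywhere makes calibration error out.
* **Determinism.** Every generator derives its RNG stream from the config
  seed; identical config and seed give byte-identical outputs, which the
  pipeline manifest (md5 per written file) makes checkable.

## Known limitations

Short elements (say, < 150 bp at benchmark densities) sit below the gap
null's detection length, so essential conventional RNAs and smORFs are
systematically under-called — the resolution limit of the method, not of
the implementation. False significant gaps arise in dispensable sequence
at a rate that grows with insertion density and shrinks with the essential
genome fraction (the global `N/G` rate the null uses is diluted by
insertion-free essential sequence); at the benchmark settings this puts a
few percent of dispensable ORFs into F. Fitness calls near `P_E` or `P_NE`
of 0.01 are sensitive to the two-decimal rounding boundary by
construction.
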