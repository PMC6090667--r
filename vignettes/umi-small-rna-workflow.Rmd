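---
title: "UMI-aware small RNA sequencing: models, parameters and design choices"
author: "umisrna maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UMI-aware small RNA sequencing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umisrna)
```

# Scope

`umisrna` implements the computational side of a gel-free small RNA
(sRNA) sequencing workflow built on two ideas:

1. **SPRI size selection below 100 nt.** Nucleic acids bind carboxylated
   paramagnetic beads in a length- and crowding-agent-dependent way. At a
   fixed 7.5% PEG, raising the isopropanol concentration lowers the
   length threshold for binding, so two fragments differing by roughly
   20 nt can be separated by choosing the right isopropanol percentage.
   The package ships a measured calibration (binding efficiency of
   19–66-nt ssDNA oligos across 30–54.5% isopropanol) and plans
   selections from it.
2. **UMI collapsing for quantification.** Each molecule receives a
   random 8-nt unique molecular identifier (UMI) before PCR, so
   amplification duplicates can be merged ("collapsed") and counts
   reflect molecules, not amplification efficiency.

Everything in between — demultiplexing by a 4-nt inline barcode,
3'-adapter scan-trimming, exact-match quantification against miRNA /
21U-RNA / genome references, replicate dispersion, negative-binomial
differential expression, the UMI label-collision model — is implemented
and validated against a library simulator with known ground truth.

# The SPRI planner

## Mixing equation

A binding reaction is assembled from the sample (volume $X$), a 20% PEG
bead solution and 100% isopropanol, such that final concentrations are
$P$% PEG and $Q$% isopropanol of the total volume $V$:

$$X + \frac{5PV}{100} + \frac{QV}{100} = V
  \quad\Longrightarrow\quad
  V = \frac{X}{1 - 5P/100 - Q/100}.$$

`computeMix()` solves this and reports the two component volumes; the
constraint $5P/100 + Q/100 < 1$ is validated and a violation raises an
explicit infeasible-mix error. A property test checks the defining
equation to $10^{-9}$ relative error on random feasible inputs.

## Calibration table and lookup

The packaged calibration (`spriCalibration()`) stores binding
efficiency (percent of input recovered in the eluate) by oligo length
and isopropanol percentage. Untested cells are **missing values, never
zeros** — an untested condition is not evidence of non-binding. Within
every length, efficiency is non-decreasing in isopropanol; a violation
at load time is a warning, not an error, because the monotonicity is an
empirical regularity rather than a law.

`bindingEfficiency()` is exact at tabulated knots and, on request,
interpolates linearly along the isopropanol axis between the nearest
non-missing knots. There is **no interpolation across lengths**: the
calibration gives no basis for a length model. Whether a recovery
prediction should use knot or interpolated values is left to the caller;
both modes are exposed throughout the planner.

## Separation planning

`planSeparation(table, keep, remove, min_keep = 40, max_remove = 5)`
scans tabulated concentrations from low to high and returns the first
one at which the kept length binds with at least `min_keep`% efficiency
while the shorter length binds with at most `max_remove`%. Design
choices:

* **Lowest qualifying concentration wins.** Short-fragment carry-over
  grows with isopropanol, so among qualifying conditions the lowest
  maximizes purity of the retained fraction.
* **Both efficiencies must be known.** A concentration where either
  efficiency is missing (directly, or by interpolation when enabled)
  never qualifies: separation is not asserted from untested cells.
* The defaults (40% / 5%) encode the empirical separation margin the
  calibration was built to demonstrate; for the packaged table every
  length pair differing by 18–23 nt admits a qualifying concentration.

`simulateTwoStep()` gives deterministic expectations for double-sided
selection (bind-long / re-bind-short); it conserves mass per length
exactly. Stochastic binding is deliberately left out of the planner —
sampling noise belongs to the library simulator, which owns the RNG.

# The library simulator

`makePopulation()` + `simulateLibrary()` generate FASTQ-ready reads with
complete ground truth. The model, stage by stage:

* **Species classes.** miRNA (22–23 nt), 21U-RNA (21 nt, 5' U),
  primary siRNA (26 nt, 5' G), secondary siRNA (21–22 nt,
  5'-triphosphate), rRNA degradation fragments (20–40 nt), other
  (15–30 nt). True molecule counts are log-normal
  (default `meanlog = 3.5`, `sdlog = 1.2`, i.e. a median of ~33
  molecules with a long right tail — a typical sRNA abundance spread).
* **Phosphate gate.** Direct 5'-adapter ligation requires a
  monophosphate 5' end; triphosphate species enter the library only
  when the layout is flagged RppH-treated. The enzymatic step itself is
  out of scope — the flag is its computational footprint.
* **Ligation bias.** Each species draws a ligation probability from a
  configurable distribution (default Beta(8, 2), mean 0.8). The
  magnitude of real adapter bias is not quantified in the underlying
  experiments; these are documented free parameters, not claims.
* **UMI labelling.** Every ligated molecule receives an independent
  uniform random UMI over $4^{\ell}$ sequences. Collisions therefore
  occur naturally when copy numbers approach the label-space size,
  which is exactly the saturation regime the collision model corrects.
* **PCR.** An exact Galton–Watson branching process: per cycle every
  copy duplicates with its template's efficiency (default Beta(8, 4),
  mean 2/3). This produces the duplicate-family structure that
  collapsing must undo — a lognormal yield shortcut would not.
  Duplicates keep their molecule's UMI; PCR never creates labels.
* **Sequencing.** Reads are drawn from the amplified pool without
  replacement when the pool is at least as deep as the read budget
  (so a noise-free run at matching depth reproduces the ligated
  molecule multiset exactly), with replacement otherwise. Reads are
  `[barcode][UMI][insert][3' adapter]`, padded with post-adapter filler
  `A`s to the 50-nt read length — real post-adapter content is
  irrelevant after trimming. Adapter dimers (insert length zero) are
  injected at the configured fraction (default 1%, matching the "below
  2%" contamination a clean library shows). Substitution errors are
  uniform; indels are out of scope for exact-match processing of short
  reads.

Seeded runs are byte-identical; all randomness flows through one seeded
generator per run.

# Read processing

* **Demultiplexing** routes reads by exact match of the first 4 bases.
  The barcode prefix is retained: the processing order is demultiplex →
  trim → collapse → strip, because collapsing must see the full
  `[barcode][UMI][insert]` string to define molecule identity.
* **3'-adapter trimming** scans candidate start positions in 1-nt
  steps from the 3' end and trims at the first full exact adapter
  occurrence — i.e. the rightmost. When an insert itself contains the
  adapter motif, rightmost-vs-leftmost is genuinely ambiguous; both are
  exposed (`match = "rightmost"` default, documented as this package's
  reading of "scan from the 3' end", not as the only defensible one).
  When no full match exists, a terminal adapter prefix of at least 5
  matched bases (configurable) counts, longest overlap preferred; with
  50-nt reads, a 12-nt prefix and ≤ 30-nt inserts the full adapter is
  almost always present, so this path rarely fires.
* **Statuses.** `ok` (insert ≥ `min_insert`, default 15 nt — the lower
  bound of the standard sRNA length-profile window), `dimer` (empty
  insert), `too_short`, `no_adapter`. No-adapter reads are kept and
  reported, never silently dropped: long-RNA exclusion is the bead
  selection's job, not the trimmer's.
* **Collapsing** is exact: raw counts tally reads per insert; collapsed
  counts tally distinct (UMI, insert) pairs. Error-tolerant UMI network
  merging (directional graphs) is a noted extension point, deliberately
  not implemented — sequencing errors can only split families here,
  never merge them, and the tests assert that direction.

# Quantification

Alignment is exact full-length substring matching, standing in for a
no-mismatch short-read aligner: annotation sets (mature miRNA, 21U) are
searched on the forward strand only (mature annotations are stranded),
genome indices on both strands. Hit-count gates mirror aligner `-m`
semantics: more than 1 hit against an annotation set (or more than 10
against the genome) marks the insert ambiguous and excludes it from
counting; within the gate a sequence counts once regardless of
multiplicity. Counting operates on distinct inserts with raw/collapsed
weights so both flavors share one alignment pass; assigned + ambiguous +
unassigned mass always equals the input mass. Counts live in a
`SmallRNAExperiment` (a `SummarizedExperiment` with parallel `raw` and
`collapsed` assays).

Profiles follow the standard sRNA views: per-length histograms over
15–30 nt with an overflow bucket, a nested per-length classification
(genome-aligned ⊇ not-miRNA ⊇ not-miRNA-and-not-21U), and weighted
first-nucleotide composition (e.g. the 5'-G preference of 26-nt primary
siRNAs).

# Statistics

* **Replicate dispersion** is the squared relative difference with the
  smaller value as base, `(hi − lo)² / lo²` — chosen because it
  reproduces the canonical worked example (a 10% difference gives
  exactly 0.01). For more than two replicates the mean over pairs is
  used. This is a deliberately literal statistic; a shrinkage NB
  dispersion estimator (as in DESeq-style tooling) is a different
  quantity, and squared-CV can be obtained by normalizing externally.
  A pair with one zero is reported as `Inf`; all-zero features are
  skipped with a notice.
* **Normalization** is median-of-ratios (`sizeFactorsMedianRatio()`),
  cross-checked in the test suite against DESeq2's implementation.
* **Differential expression** (`deTest()`) fits a per-feature NB
  dispersion by method of moments pooled across the two conditions
  (floor $10^{-8}$ for degenerate features) and applies a Wald test on
  log group means with delta-method variance $(1/m + \phi)/n$. Calls
  require at least a 5-fold change **and** BH-adjusted p < 0.01
  (both configurable). The 0.5 pseudocount appears only in the reported
  fold change, never in the statistic; features with a zero group mean
  cannot be Wald-tested and get `NA` p-values. The deliberate modesty —
  no shrinkage, no GLM designs — keeps the estimator transparent at
  3-replicate scale; planted-effect simulations show ≥ 80% power for
  8-fold effects with essentially no false calls.
* **UMI collision model.** With $n$ molecules and $K$ labels the
  expected distinct-label count is $K(1 - (1 - 1/K)^n)$;
  `umiCorrect()` inverts the Poisson form, $\hat n = -K\ln(1 - d/K)$,
  leaving a relative bias of order $1/(2K)$ — well inside the 0.5%
  round-trip tolerance the tests enforce for $n \le K/2$. Over
  copy/label ratios 0.2–0.6 the expected undercount runs ≈ 9–25%,
  which is why 8-nt UMIs saturate for highly expressed species and
  longer UMIs are preferable at high input or deep amplification.
* **Adapter bias metric.** The underlying experiments report a bias
  improvement from UMIs without fully specifying the statistic; the
  implemented metric, $|\log_2((c_1+0.5)/(c_2+0.5))|$ between two
  barcode libraries of the same sample, is a documented stand-in. The
  tested claim is its **direction** (collapsing lowers the median bias
  and improves most features), not any particular magnitude.

# What the simulator does and does not show

The simulator reproduces the library *structure* (read layout, species
classes, phosphate gating, ligation/PCR bias, dimers, UMI collisions),
so pipeline correctness can be checked against exact ground truth. It
does not emulate instrument error profiles, indels, isomiR heterogeneity,
RNA degradation kinetics, or sequence-dependent ligation preferences
beyond a per-species probability. Passing tests therefore demonstrate
algorithmic correctness and the direction of bias-removal effects — not
that any particular real library will show a specific bias magnitude.

Problem sizes in the test suite (populations of 20–40 species, libraries
of 10–40k reads, 3 technical replicates, 200-feature DE simulations)
were chosen as the smallest scales at which the tested contrasts are
stable across seeds; they are the package's own validation design.

# Degenerate inputs and numerical choices

* Infeasible mixes (denominator ≤ 0) and saturated UMI counts
  (d ≥ K) raise errors naming the violated constraint.
* `planSeparation()` failure carries the best trade-off found, so a
  caller can relax thresholds deliberately rather than silently.
* Interpolation returns missing (`NA`) when a bracketing knot is
  absent; callers must treat missing as "untested", not zero.
* Ties in `planSeparation()` cannot occur (the scan returns the first
  qualifying concentration); equal-abundance ties in profiles are
  resolved by alphabetical feature order inherited from the reference.
* All validation (thresholds, file existence, barcode uniqueness)
  happens at configuration time, before compute.

# Reproducibility

`runPipeline()` is a pure function of (inputs, configuration, seed):
the seed is recorded in the JSON report and identical seeds produce
byte-identical reports. The command-line wrapper
(`inst/scripts/umisrna-cli.R`) exposes each stage and the end-to-end
run as subcommands over these same functions.
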