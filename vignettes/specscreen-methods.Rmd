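---
title: "Methods: synthetic promoter sort-seq screens with specscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic promoter sort-seq screens with specscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

specscreen implements a complete desk-scale version of a sort-seq screen
for cell-state-specific synthetic promoters (SPECS): a library of
tandem-repeat transcription-factor binding-site (TF-BS) promoters is
introduced into cells of two (or more) states, cells are FACS-sorted into
five fluorescence bins, each bin is sequenced, and per-promoter activity
is estimated from the binned counts. This vignette documents the models,
defaults and numerical choices behind each stage, and what the simulated
screens do and do not establish about real data.

## Library design

Each construct repeats one TF-BS consensus `k` times, separated by a 3 bp
spacer, inside a fixed 129 bp synthesis budget:

    k = floor(129 / (L + 3))

where `L` is the binding-site length in bp. Floor is deliberate: a
partial repeat unit would exceed the synthesis budget, so the variable
region is always `k * (L + 3) <= 129` bp. Sites longer than 126 bp admit
no unit and are reported as un-designable rather than silently truncated.

The consensus takes the maximum-probability base at each motif position;
ties break alphabetically (A < C < G < T) so a design is a pure function
of its motifs. Both the consensus and its reverse complement become
constructs, deduplicated at the sequence level, so a palindromic
consensus yields one construct. The spacer is a fixed neutral `cgt`
trimer: any fixed choice works, but fixing it keeps designs
deterministic and the repeat period unambiguous.

Every construct carries a 17 bp random barcode drawn uniformly over
A/C/G/T, rejected on collision or if it contains the AscI recognition
sequence `GGCGCGCC`. The full oligo is

    flank5 + variable_region + AscI + barcode + flank3

The AscI site sits directly 3' of the variable region so that
preprocessing can trim reads at the site's 5' edge and recover exactly
the variable region; the barcode lies outside the trimmed region and
remains usable as a retrieval primer. The flanks are configurable
constants (real designs would carry the minimal-promoter and
vector-junction sequences there).

## The screen simulator

The simulator is first-class, tested code: it defines the study
conditions every downstream stage is validated against.

**Per-cell fluorescence.** A cell carrying construct *i* in state *s*
measures `2^N(m_is, sigma) + 2^N(b, sigma_b)` — a lognormal reporter
signal (log2-Normal, the standard cytometry model) on top of lognormal
autofluorescence. Defaults: `sigma = 0.8` log2 units of cell-to-cell
spread; autofluorescence median `b = 6` log2 a.u. with `sigma_b = 0.4`,
i.e. background around 64 a.u. on a four-decade instrument. Silent
constructs contribute no reporter signal at all, so they sit exactly on
the autofluorescence distribution.

**Ground truth.** Each construct is active with probability 0.4
(identical medians in all states), silent otherwise; active medians are
uniform on log2 [7, 16]. Planted state-specific constructs are active in
their target state only (medians uniform on [10.5, 15.5]), which at the
autofluorescence floor corresponds to measured fold-differences of
roughly 20- to 1000-fold — the regime real validated SPECS occupy. These
values were fixed once as the package's study conditions.

**Gating.** The negative gate is the 99.5th percentile of an
uninfected-control sample. Among fluorescence-positive cells, the top 5%
and top 5–10% gates sit at the 95th and 90th percentiles, and the
remaining 90% of positives split at their median into equal low/high
halves. Per-bin mean fluorescence (`ybar_b`) is the mean of cells inside
each gate; the five `ybar` values are strictly increasing by
construction. Real gate boundaries are instrument-specific, so the
simulator exposes them via its gate-derivation function rather than
hard-coding them.

**Sequencing.** Each sample (state x replicate x bin) draws exactly
`depth` reads (default 1e6) from a multinomial over construct bin
occupancies, with 200 cells sorted per construct per biological
replicate (>100-fold coverage). Technical replicates resample sequencing
only; biological replicates additionally perturb active medians by
Normal(0, 0.5 log2). With these defaults technical-replicate log-count
agreement exceeds biological-replicate agreement, qualitatively matching
the replicate-correlation gap observed in real screens (the real gap —
R² ≈ 0.8 vs ≈ 0.3 — reflects additional biology the simulator does not
attempt to reproduce quantitatively).

**Reads.** `emit_reads()` writes one FASTQ read per count:
`variable_region + AscI + barcode + flank3`, with optional per-base
substitution errors and an optional fraction of junk reads lacking the
AscI site. With `error_rate = 0` the emit → trim → match path
reproduces the simulated counts exactly; this round-trip identity is an
acceptance-level test.

**Not modeled.** PCR jackpotting, integration-site effects, sorting
cytotoxicity, optical spillover, indels in reads. Passing tests on
simulated screens therefore demonstrate the pipeline's correctness and
statistical behaviour under the stated noise model, not robustness to
every artefact of real sequencing.

## Preprocessing

Reads lacking `GGCGCGCC` are discarded; retained reads are truncated at
the site's 5' edge. Identical sequences are collapsed before matching.
Each unique sequence goes to the single best-matching variable region
within 2 mismatches (Hamming; roughly 1% of a 150 bp read). Ties at the
best distance are left unassigned — an ambiguous read must not vote. An
edit-distance mode (Levenshtein via `adist`) is available where indels
matter; substitutions-only is the default because the simulator and
short-read chemistry are substitution-dominated.

Size factors are native median-of-ratios: reference = per-construct
geometric mean across samples over constructs nonzero everywhere;
factor = median ratio to the reference. In a sort-seq screen strongly
active constructs have no counts in the negative bin and silent ones
none in the top bins, so libraries with few mid-activity constructs may
have *no* all-nonzero construct; `pseudocount = 0.5` extends the
estimator to that case and is what the package's own end-to-end flows
use. Median-of-ratios factors are invariant to a common scaling of all
samples and absorb per-sample scaling up to one global constant — both
properties are tested.

Counts are log-transformed downstream as `log2(1 + normalized count)` so
zeros are defined. The replicate filter retains a construct only if it
has nonzero counts in at least two replicates in *every* state, matching
the rule used before model fitting in the original screens.

Sanger clones from shotgun cloning are identified by aligning each
variable region globally against a local window of the clone
(`pairwiseAlignment`, global-local): an exact substring hit is *intact*;
a best alignment within 5 edit operations (mismatches plus indel bases)
is *mutated* with the edit count reported; anything else is
*unidentifiable*.

## Activity estimation

**Activity score.** For promoter *i*,

    A_i = sum_b( ybar_b * n_ib ) / sum_b( n_ib )

with `n_ib` the log2 normalized counts in bin *b* and `ybar_b` the mean
fluorescence of the bin. It is a weighted mean, hence bounded by the
extreme `ybar` values and monotone under moving count mass to brighter
bins. It serves to pick calibration promoters spanning the activity
range (random picks would be dominated by silent promoters) and as a
model-free sanity rank.

**Features.** Sort-seq predictors engineer features from the perceived
counts-fluorescence relationship; no single canonical list exists, so
the package fixes a documented schema spanning the natural families: five per-bin log2
counts, log2 total, five pseudocounted bin proportions, four
adjacent-bin log ratios, and the index of the maximal-count bin — 16
base features — plus all 120 pairwise products as first-degree
interactions. The schema is carried in the model object, so an
alternative schema can be swapped in behind the same interface.

**Elastic net.** Targets are log2 median fluorescence from per-cell
event tables of individually measured promoters (calibration set,
n = 81 by default, selected quantile-stratified along the activity
score). The split is 60/40 train/test *by construct*, so both states of
a promoter fall on the same side. On the training split a five-times
5-fold repeated cross-validation (folds also by construct) scans
`alpha` in {0, 0.25, 0.5, 0.75, 1} and 30 log-spaced `lambda` values in
[1e-4, 10], choosing the minimum mean RMSE (no one-standard-error rule).
Features are standardized to training-split mean/variance before
penalization; constant columns get unit scale. The final model refits on
the whole training split and reports Pearson R² and RMSE on the
untouched 40%, alongside an unregularized least-squares baseline on the
16 base features. Models serialize to a versioned JSON archive with
doubles stored as `%.17g` strings, so a reloaded model predicts
bit-identically.

## Specificity ranking

Fold-difference is `pred_A − pred_B` in log2, antisymmetric under state
swap, with ≥10-fold and ≥100-fold threshold flags. Candidate selection
returns four classes: top folds (specific to A), bottom folds (specific
to B), and a quantile-stratified range of predicted activity in each
state; all ties break by construct id, so selection is seed-free and
order-invariant.

Enrichment of a candidate subset against the library background uses the
two-sided Wilcoxon rank-sum test with the subset removed from the
background (one occurrence per value). For combined n ≤ 12 the p-value
is computed by exact enumeration of all rank assignments (valid under
ties); larger samples use the normal approximation with tie correction.
All values tied returns p = 1.

The low-coverage heuristic formalizes the manual shortlist used when
sorting cytotoxicity leaves a screen too sparse for the model: per
construct and state it computes total counts, negative-bin counts and
the maximal-count bin — the features that remain calculable at low
coverage. A construct is a candidate specific to state A when its
maximal bin in A is a positive bin with a negative-bin fraction below
0.25 (configurable; the original rule is qualitative) while its maximal
bin in B is the negative bin, and symmetrically. Candidates rank by
positive-bin count fraction in the "on" state, then total counts, then
id; a construct whose maximal bin is negative everywhere is never
promoted.

## Imaging statistic

Organoid time courses reduce to a 256 x days matrix: fluorescence
intensity is divided into the 256 bins of an 8-bit image and each day's
column holds `log10(1 + count_v / total)` per intensity bin — absent
bins map to exactly 0, and every entry is bounded by log10(2). The log
base is not dictated by the definition (any base rescales columns
uniformly); log10 is used and recorded in the output metadata.
Higher-bit-depth inputs are linearly min-max rescaled to 0..255 with the
mapping logged. The red channel is median-filtered before binning
(default 3x3, odd windows only, edge replication); the filter is
idempotent on constant images and matches a brute-force windowed median,
which the tests assert. Frequencies are computed per provided image;
stitched-mosaic aggregation is out of scope.

## Problem sizes and reproducibility

The shipped tests and the acceptance script exercise the pipeline at
sizes chosen to keep a full run in the order of a minute while leaving
every statistical conclusion stable across seeds: 200-construct screens
at 1e5 reads/sample for the read-level round trip, 500 constructs at
1e6 reads/sample with an 81-promoter calibration for fluorescence
recovery (held-out R² ≈ 0.99, library-wide Spearman ≈ 0.89 against
truth), 10 planted specifics among 500 for model-based shortlists, and
6 planted specifics among 200 at 1e5 reads/sample for the low-coverage
heuristic. All randomness flows from explicit integer seeds;
`scripts/acceptance.R --seed N --out F` recomputes every headline
quantity from scratch.

## Known limitations

* The feature schema is a reconstruction; real screens may have used
  additional bin relationships.
* The simulator's biological-replicate model (additive log2 median
  perturbation) is a deliberate simplification; it produces the correct
  ordering of replicate correlations, not their real magnitudes.
* Hamming matching requires length-preserving errors; indel-containing
  reads only match in edit-distance mode.
* Median-of-ratios with a pseudocount is biased for very sparse
  samples; at the depths simulated here the bias is negligible, but
  single-digit-count samples deserve caution.
* Predictions are relative (log2 a.u. on the training cytometer's
  scale); no absolute cross-instrument calibration is attempted.
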