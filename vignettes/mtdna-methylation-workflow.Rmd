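---
title: "Mitochondrial CpG methylation from nanopore per-read calls: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitochondrial CpG methylation from nanopore per-read calls: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmeth)
```

## The measurement model

Nanopore sequencing reads native DNA molecules, so 5-methylcytosine can be
called directly from the signal, without bisulfite conversion. A signal-level
caller emits, for every read and every CpG group it observes, a
log-likelihood ratio (LLR): the log-likelihood of the methylated state minus
that of the unmethylated state, over the k-mer window containing the CpG(s).
`mtmeth` starts from those per-read call tables and implements the
downstream analysis:

1. **Classification.** A call with LLR strictly above `llr_upper` (default
   +2) is methylated; strictly below `llr_lower` (default -2) unmethylated;
   anything in between — including values exactly at a threshold — is
   ambiguous. Ambiguous calls are counted but enter neither the numerator
   nor the denominator of any frequency. The strict inequality matters only
   on a set of measure zero for real data, but it is the printed rule and
   the package's tests pin it by grid search.
2. **Split-group reporting.** Callers merge CpGs that share a k-mer window
   into one group with a single LLR. `split_groups()` emits one record per
   CpG in the group, each inheriting the full group LLR (evidence is not
   divided). This matches the reference caller's split-group behaviour; it
   means calls at grouped CpGs are perfectly correlated within a read, which
   is why variance calculations in the tests use site spacings wider than
   the grouping window when independence is assumed.
3. **Methylation frequency (MF).** At each reference CpG site,
   `MF = n_methylated / (n_methylated + n_unmethylated)` over confident
   calls: the proportion of reads supporting methylation there. Sites with
   fewer than `min_called` confident calls (default 1) are omitted rather
   than reported as 0/0. Sample-level results are the unweighted mean ± SD
   of site MFs.

Coordinates are 0-based internally (matching both input dialects); all
reporting functions (`high_mf_sites()`, `annotate_positions()`) print
1-based `chrM:<pos>` labels, the convention used for mitochondrial site
lists.

## False-positive correction from an amplicon control

Long-range PCR erases methylation, so a sequenced amplicon of the
mitochondrial genome gives a per-caller false-positive rate:
`FPR = methylated calls / all confident calls` on the control
(`estimate_fpr()`). Two rules derive from the control:

- `adjust_mf()` subtracts the FPR from every site MF. One FPR per caller is
  applied uniformly; the subtraction is monotone so site rankings survive.
  Negative adjusted values are clamped to zero by default — a flag disables
  clamping because the signed error is the quantity of interest in bias
  diagnostics (and the package's own unbiasedness test uses it).
- `exclude_sites()` removes any site whose MF *in the control itself*
  strictly exceeds 0.2: such sites are systematically miscalled regardless
  of the global rate. Sites absent from the control are retained and listed.
  When two overlapping amplicons cover the genome, their calls are pooled
  before the test (default); a `combine = "max"` flag applies the stricter
  per-amplicon maximum instead, since the original design does not state
  which was used.

"All called cytosines" is read as *confidently* called (ambiguous excluded),
keeping the FPR on the same scale as the MF it is subtracted from. This is a
documented interpretation; the alternative (counting ambiguous calls in the
denominator) would shrink the FPR by the ambiguous fraction.

## Read-level filters

- **NUMT filter.** Nuclear copies of mtDNA segments are mostly shorter than
  500 bp, so reads are kept only when their alignment to the mitochondrial
  reference is strictly longer than 1 kb (`numt_filter()`); exactly 1000 bp
  is removed. Only the length rule is implemented — no sequence-similarity
  NUMT detection.
- **Pass/fail strata.** The base-caller classifies reads by mean Phred
  qscore; the cutoff (default 7) is applied inclusively (a read at exactly
  7.0 passes), matching the base-caller's convention since the printed rule
  does not state the direction. Highly methylated molecules tend to fail
  base-calling, so the failed stratum is enriched for methylation — the
  package reproduces this qualitatively through the generator's qscore
  model (below).
- **Coverage subsampling.** `subsample_to_coverage()` shuffles reads once
  (seeded) and takes nested prefixes per coverage target, mirroring the
  design of calling methylation on growing subsets of a run. Subsampling is
  read-level; the original analysis subsampled at the file level, which can
  differ slightly in granularity but not in expectation.

## Cohort statistics

Group comparisons use the two-sided Mann-Whitney U test (`mann_whitney()`,
exact for n1+n2 <= 16 without ties, normal approximation with tie and
continuity correction otherwise) and Spearman rank correlation
(`spearman_cor()`, midranks under ties, exact p for <= 10 tie-free pairs).
Both are computed through the standard `stats` routines; the package's tests
check them against full-enumeration oracles independently.

`compare_groups()` always reports **two pooling units**: site-pooled (every
per-site MF of every sample in a group forms one vector — the unit implied
by very small published p-values at n = 7-8 samples) and per-sample means
(one value per sample). Site pooling pseudo-replicates sites across samples,
so neither is hidden: both appear in every report with their n's. P-values
are exploratory and uncorrected, and are labelled as such. An age-vs-MF
correlation is a thin application of `spearman_cor()` over per-sample means
and needs no dedicated function.

`strand_concordance()` pairs sites seen on both read strands (plus =
L-strand, minus = H-strand) and reports their correlation, the
plus-vs-minus test and the mean difference; any comparator region's table
(e.g. a nuclear 45S rRNA locus extracted via a BED interval) can be passed
through the same function. `tool_concordance()` contrasts per-site with
per-sample agreement between two callers, which typically differ by an
order of magnitude.

## The synthetic-data generator

Raw nanopore runs are neither redistributable nor desk-scale, so every
moving part is exercised against `simulate_sample()`, a generator with known
ground truth. What it emulates:

- reads placed uniformly on a circular 16,569 bp contig (linear mode for
  short fragments), log-normal lengths (default mean 4.9 kb, the
  whole-genome run scale);
- molecule truth either per-site-independent Bernoulli with probability
  `truth` (native tissue; default 0.03, the corrected blood-derived scale)
  or whole-molecule with probability `pi` (the dilution design, which mixes
  fully methylated and fully unmethylated 897 bp molecules at ratios
  0/50/100%). `balanced = TRUE` fixes the methylated fraction exactly at
  `pi`, emulating a pipetted ratio; with full-length reads this makes the
  noise-free 1:1 dilution hit MF = 0.5 exactly at every site;
- per-call state flips `fpr_call`/`fnr_call`, then a Gaussian LLR emission
  (defaults N(+6, 3) / N(-6, 3)) — the simplest emission that produces
  ambiguous calls in [-2, 2]; it is parameterised, not claimed to match any
  caller's true emission;
- CpGs within `group_dist` (default 10 bp) on one read are emitted as one
  multi-CpG group inheriting the first member's state;
- read mean qscore `= 10 - 4 * (methylated fraction of covered CpGs) +
  N(0, 1)`, clamped at 0. The true qscore-methylation relationship is
  unknown; `qscore_delta` is a free parameter and conclusions that depend on
  it are qualitative (orderings, not magnitudes);
- optional short NUMT-like contaminant reads (100-500 bp), all removable by
  the 1 kb filter;
- full determinism from one seed; `simulate_cohort()` derives per-sample
  seeds as `base_seed + 1000 * i` and writes a manifest recording them.

What it does **not** model: signal-level (squiggle) noise, base-caller error
beyond the scalar qscore coupling, sequence-context-dependent call error,
strand-asymmetric truth, copy-number structure, or heteroplasmy. Passing
tests therefore certify the *analysis* — classification, aggregation,
correction, filtering, statistics — under a faithful rendering of the study
design, not the callers themselves.

## Numerical and design choices

- Ties at LLR thresholds are ambiguous; qscore boundary inclusive; NUMT and
  control-MF boundaries strict. All four are pinned by grid brute-force in
  the tests.
- Empty call tables yield empty site tables (not errors); an empty control
  map retains everything with a prominent warning; a control with zero
  confident calls is an error.
- Degenerate statistics are flagged rather than forced: single-site SDs are
  `NA`, constant-vector correlations are `NA` with a `constant_input` flag,
  correlations on fewer than 3 pairs are reported as underpowered.
- Parsers never drop rows silently: parsed + rejected = data lines, with
  line-numbered messages, and `on_error = "fail"` promotes row errors.
- Problem sizes in the test-suite simulations are chosen at desk scale and
  fixed: dilution fragment 897 bp with 25 CpGs at up to 10,000X; FPR
  recovery on ~51,000-call controls over 200 replicates; bias check at 250X
  over ~300 sites; type-I at 500 replicates of 3-vs-3 cohorts (30 sites,
  30X); power spot-check at 30 replicates of 4-vs-3 cohorts (300 sites,
  250X); coverage curves over 12 seeds at 25-400X.

## Known limitations

- The FPR correction is global; no site-specific (sequence-context) error
  model is attempted.
- Split-group records inherit the whole group's LLR, so grouped CpGs are not
  independent observations; per-site calibration at grouped sites holds only
  when the molecule state is constant across the group.
- The pass/fail re-analysis and the fail-enrichment results inherit the
  arbitrariness of `qscore_delta`; only orderings are asserted.
- Non-CpG (CpH) methylation is out of scope.
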