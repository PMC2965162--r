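---
title: "Exhaustive k-gene marker discovery: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive k-gene marker discovery: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`markerscan` implements a comparative marker-discovery workflow for tumor
versus control expression cohorts: per-gene differential-expression (DE)
testing, an exhaustive search over small gene combinations ranked by
cross-validated classification accuracy, intersection of DE genes across
several cancer types, and downstream filtering (gene-set enrichment,
blood-secretory annotation, survival correlation). This vignette explains
the statistical model behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical conventions that make every run reproducible.

## Differential expression

### The paired sign test

The primary design is paired: each patient contributes one tumor and one
adjacent-tissue control array. For a single gene, let $m$ be the number of
patients and $K$ the number of patients whose cancer value exceeds their
control value. Under the null hypothesis that the gene is not
differentially expressed, and assuming expression is continuous, each
patient independently satisfies cancer > control with probability $1/2$,
so $K/m$ is approximately normal with mean $1/2$ and standard deviation
$1/(2\sqrt{m})$. The standardized statistic

$$ z \;=\; \left(\frac{K}{m} - \frac{1}{2}\right)\, 2\sqrt{m} $$

is approximately $N(0,1)$; `paired_sign_test()` reports the one-sided
upper-tail p in the direction of the observed majority and the two-sided p
(twice the smaller tail, capped at 1).

Conventions worth knowing:

* **Ties.** Real (quantized) data can produce exact ties; they are dropped
  and $m$ reduced, the standard sign-test convention. Fewer than 10 usable
  pairs sets a `small_sample` flag because the normal approximation is then
  dubious.
* **Sidedness.** `call_differential()` thresholds the two-sided p by
  default, since both up- and down-regulated genes are reported; a
  `sided = "one"` flag reproduces the strictly one-sided reading of the
  statistic.
* **Continuity correction.** The default statistic is the plain normal
  approximation above. It is worth being explicit about its quality: the
  plain upper tail deviates from the exact binomial tail
  $P(\mathrm{Bin}(m, 1/2) \ge K)$ by up to 0.07 near $K \approx m/2$ even
  at $m = 100$. The `correct = TRUE` flag applies the usual $\pm 1/(2m)$
  continuity correction, after which the error is below $10^{-3}$ for
  $m \ge 30$; the test suite pins both behaviors. Near the 0.05 decision
  boundary the two variants rarely disagree, but the corrected variant is
  the one that genuinely tracks the exact test.

### Unpaired cohorts

Cohorts without patient pairing use the Mann–Whitney rank-sum test.
`mann_whitney_test()` has two modes: `"exact"` enumerates the full
permutation null of the $U$ statistic (correct in the presence of ties;
feasible for pooled sizes up to ~24, auto-selected at $\le 12$) with the
two-sided p defined as $P(|U - n_1 n_2 / 2| \ge |u_{obs} - n_1 n_2/2|)$;
`"normal"` uses the tie-corrected normal approximation (via
`stats::wilcox.test`, without continuity correction).

### The DE rule

A gene is called differentially expressed when **both** its p-value is
below `alpha` (default 0.05, raw — no multiple-testing correction by
default, with a Benjamini–Hochberg option) and its linear fold change is
at least `min_fc` (default 2) in either direction. Fold change is computed
as $2^{\overline{\log_2 \mathrm{cancer}} - \overline{\log_2 \mathrm{control}}}$,
i.e. the ratio of geometric means — the natural choice for RMA-style log2
intensities, whose arithmetic-mean counterpart (`fc_method = "arithmetic"`)
is dominated by a few bright arrays. The conjunction matters in practice:
under a pure null at $m = 40$, the p-threshold alone rejects ~4–5% of
genes, while adding the 2-fold filter removes essentially all of them
(the acceptance suite checks a residual rate below 0.5%).

## Exhaustive marker search

For each combination of $k$ DE genes ($k = 1\ldots4$), a linear-kernel
soft-margin SVM (LIBSVM through `e1071`, cost fixed at 1 by default) is
trained to separate cancer from control samples, and the combination is
scored by stratified 5-fold cross-validation. Accuracy is

$$ \mathrm{accuracy} = \frac{TP + TN}{N}, $$

with $TP$ and $TN$ the correctly classified cancer and control samples and
$N$ all samples. Two choices here were genuinely open and are worth
stating:

* **Pooled CV accuracy.** Held-out predictions from all five folds are
  pooled and scored once, which is literally $(TP+TN)/N$ over the whole
  cohort; the mean-of-fold-accuracies variant differs only at the third
  decimal on balanced cohorts and is available via `pool = "fold_mean"`.
* **Deterministic folds and tie-breaks.** Fold assignment is stratified by
  class and derived from a mandatory seed; equal accuracies are ordered
  lexicographically on the gene tuple. Rankings are therefore pure
  functions of (data, parameters, seed), which the test suite enforces by
  comparing against an independent brute-force re-computation.
* **No feature scaling.** Log2 expression values already share a scale;
  optional per-gene standardization would have to use training-fold
  statistics only and is deliberately not a default.

Candidates are then refit on the full training cohort and scored on
independent test cohorts. A test platform that does not measure one of a
combination's genes yields a missing value (`NA`) for that cohort rather
than an error or an imputed score — the combination simply cannot be
evaluated there.

**Compute budget.** The exhaustive search is factorially large:
$\binom{294}{4} \approx 3\times 10^8$ SVM fits is cluster-scale work. At
desk scale the `prefilter` option restricts the pool for $k \ge 3$ to the
top genes by single-gene CV accuracy — a documented deviation from the
fully exhaustive search — and `run_pipeline()` refuses enumerations beyond
`max_combinations` (default $4\times10^6$) unless forced.

## Multi-cancer analysis

Genes "consistently differentially expressed" across cancers are those DE
in at least `min_types` cancer types with the same regulation direction in
every cancer where they are DE (`require_consistency`, default on; the
all-up/all-down pattern is what makes a shared marker interpretable).
Combinations drawn from that shared pool are scored per cancer exactly as
in the single-cancer search; a combination *counts* a cancer when its
**training** CV accuracy reaches `accuracy_cutoff`. The cut-off default is
0.70, motivated by the convention of calling discerning power above 70%
useful for screening; membership is deliberately based on training
accuracy so that the availability (or platform coverage) of test cohorts
cannot change the count. Results are ordered count-first, then mean
training accuracy, then lexicographically.

## Downstream analyses

* **Enrichment.** Gene-set enrichment of DE gene lists is a one-sided
  hypergeometric over-representation test against user-supplied GMT
  collections, run separately for all/up/down DE lists; a set is enriched
  at raw $p < 0.05$. This is a plain, reproducible stand-in for hosted
  annotation services whose exact modified-Fisher statistic is not
  public; the background universe is the measured platform, not the whole
  genome — using the genome inflates enrichment of anything tissue-biased.
* **Secretory filtering.** Candidate panels are intersected with a
  user-supplied blood-secretory gene list (the original sequence-based
  secretome predictor is out of scope); a panel passes when all its genes
  are secretory and at least `min_qualifying` of its qualifying accuracies
  (CV accuracy for single-cancer tables, per-cancer training accuracies
  for multi-cancer tables) reach `accuracy_floor` (default 0.70). The
  per-cancer reading of the floor is intentional: a multi-cancer panel can
  be a useful serum-marker candidate in the three cancers where it works
  even if it scores below the floor elsewhere.
* **Survival correlation.** Across cancer types, the number of DE genes is
  correlated (Pearson by default, Spearman optional) with the five-year
  survival rate. The bundled `inst/extdata/synthetic_survival.tsv` is a
  synthetic illustration table; survival registries publish the real
  rates, and no specific coefficient is asserted anywhere in the package.

## The synthetic cohort generator

All tests and the acceptance script run on cohorts from
`simulate_study()` / `simulate_panel()`, which generate log2 expression as

$$ x_{gs} = \mu_g + o_{p(s)} + \Delta_g\,[s \in \mathrm{cancer}] + \varepsilon_{gs} $$

per-gene baselines $\mu_g \sim N(7, 2^2)$ (RMA-like log2 intensities),
a per-patient offset $o_p \sim N(0,1)$ shared by a patient's tumor and
control arrays (this is exactly what makes the paired test more powerful
than the unpaired one), signed log2 fold changes $\Delta_g$ for a minority
of DE genes, and $N(0,1)$ measurement noise. Defaults mirror the paired
microarray cohorts the pipeline targets: 43 patients, 5% DE genes, |log2
FC| drawn from [1, 2], ~30% of DE genes up-regulated. Baselines are part
of each cancer's gene-level truth and are shared between its training and
test cohorts — without that, no classifier could transfer across cohorts.
Where the emulated studies do not state noise magnitudes, the defaults
were chosen once for testability at these cohort sizes, not to mimic any
specific series.

Planted discriminative panels receive alternating shifts
$\pm\,\mathrm{margin}/\sqrt{k}$ along the panel's genes plus a shared
per-sample latent component (sd `panel_latent_sd`, default 3). Along the
sign-alternating direction the latent, the patient offset and the shared
baseline all cancel, so the panel is linearly separable at the configured
margin, while each member gene alone is noisy. An earlier, simpler design
(equal-sign shifts) made every panel gene individually near-perfect, so
dozens of panel-gene/decoy pairs tied at accuracy 1.0 and recovering the
exact planted pair became a lottery over tie-breaks; the alternating
construction is what "jointly, not marginally, discriminative" requires
under a linear classifier.

What the generator deliberately does **not** emulate: probe-level
artifacts, normalization residuals, batch or platform shifts between
training and test series, correlated co-expression modules beyond the
planted panels, and stage-dependent effect sizes (stage labels are
assigned at random). Passing tests therefore demonstrate the statistical
machinery — calibration, power at planted effect sizes, recovery of
planted structure, determinism — on data satisfying the model's
assumptions; they do not certify performance on real arrays, where
cross-series shifts in particular will reduce test-cohort accuracy.

## Problem sizes used by the automated checks

The test suite and `scripts/acceptance.R` use cohorts of 40–86 samples and
60–2000 genes: large enough that the null calibration window
([0.03, 0.07] at $\alpha = 0.05$ over 2000 genes), the $\ge 0.9$
sensitivity bound for planted 4-fold changes at $m = 40$, and the
planted-panel recovery rate (top-5 in $\ge 80\%$ of 20 seeds, 50 decoys)
are all informative, while the exhaustive $k = 2$ searches stay at around
$10^3$–$10^4$ SVM fits. The multi-cancer chance-overlap check compares the
observed mean number of coincidental three-cancer intersections with its
analytic expectation $(n-s)\,(d/(n-s))^3\,(u^3 + (1-u)^3)$ over 20
simulated panels.

## Known limitations

* The exhaustive search is exact only up to the declared compute budget;
  beyond it, prefiltering makes the search heuristic (the top pool is
  chosen by single-gene accuracy, which can miss purely synergistic
  pairs).
* The sign test ignores effect magnitude by design; the fold-change filter
  restores a magnitude criterion but uses a hard threshold, so effects
  straddling 2-fold are called inconsistently across cohorts.
* Enrichment p-values are raw and one-sided; with many sets, expect 5% of
  independent null sets to appear enriched.
* `survival_correlation()` with seven points has low power; its p-value
  should be read as descriptive.
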