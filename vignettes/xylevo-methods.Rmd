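---
title: "Methods: growth metrics, expression ratios and adaptation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth metrics, expression ratios and adaptation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylevo)
```

xylevo analyses serial-dilution evolution experiments in which microbial
strains adapt to a poorly utilised carbon source — the motivating system is
budding yeast propagated on xylulose, the one pentose it can metabolise —
and asks two questions: *how much did growth improve*, and *which gene
expression programmes moved with that improvement*. This vignette is the
package's own account of the models and conventions behind each stage, the
parameters that matter, and the choices made where more than one reasonable
definition exists.

## Growth model and metric extraction

### The effective growth rate

Batch growth improvements come in different flavours: some strains speed up
their log phase, others raise their saturation density, others shorten the
lag. No single classical parameter captures all three, so the central
summary used throughout the package is the **effective growth rate**,

$$ v_\mathrm{eff} = \frac{\mathrm{OD}_\mathrm{max}}{t_\mathrm{sat}}, $$

the maximum optical density reached divided by the time elapsed until
saturation (units: OD per hour). It rewards both a higher yield and reaching
it sooner, and its evolved/ancestor ratio is the package's per-strain
measure of adaptation. By construction the reported value always equals
`max_od / time_to_max_od` exactly, and the fold change factorises as
(max-OD fold) / (time fold).

### Definitions that needed a decision

* **Time to saturation.** "Time to maximum OD" is ambiguous on a noisy,
  asymptoting curve: the literal argmax of a smoothed series is dominated by
  plateau jitter. `compute_metrics()` therefore reports the earliest time
  the smoothed curve reaches `saturation_fraction` (default 0.95) of its
  maximum; `saturation_fraction = 1` recovers the literal earliest argmax,
  and ties at the maximum always resolve to the earliest timepoint. By
  default the threshold crossing is located by linear interpolation between
  the two bracketing readings, so the estimate is not quantised to the
  sampling interval; `interpolate = FALSE` gives the raw grid reading.
* **Log-phase rate.** No fitting procedure is canonical; the package slides
  a window (default 5 points) along `ln(OD)` vs time and reports the maximum
  least-squares slope. For curves with a substantial inoculum baseline the
  `baseline` option subtracts it before taking logs (points at or below the
  baseline are dropped); this recovers the intrinsic logistic rate constant
  on simulated curves to within 1%. With the default `baseline = 0` the
  estimate is the maximum specific slope of the raw signal, which is the
  robust choice when the true blank is unknown.
* **Smoothing.** A running median (window 5) removes single-reading spikes
  (bubbles, condensation) without flattening the sigmoid; a running mean of
  the same width then suppresses residual jitter. Windows truncate at the
  series ends. `smooth_window = 1` disables smoothing.
* **Replicates.** Metrics are computed per replicate well and combined
  across replicates by geometric mean before ratios are taken; the geometric
  mean commutes with the ratio, so the combined fold equals the geometric
  mean of per-replicate folds and the effective-fold identity survives
  averaging.
* **Degenerate curves.** A curve whose smoothed maximum does not exceed its
  first reading has no net growth; it is flagged and warned about rather
  than erroring, so a bad well cannot abort a plate-scale batch.

`classify_improvement()` labels a strain improved when its effective fold
strictly exceeds 1 (the threshold is an argument). `generations_elapsed()`
encodes the serial-dilution bookkeeping: a dilution by factor $d$ regrown to
saturation is $\log_2 d$ doublings, so a daily 1:64 dilution is 6
generations per day and 50 cycles span 300 generations.

## Expression pipeline

Inputs are matrices of UMI-deduplicated mapped-read counts over a factorial
design: strains × {ancestral, evolved} × {glucose, xylulose} × replicates.
The stages, in order:

1. **Depth normalisation** (`normalize_to_million()`): each sample is scaled
   to one million total counts (CPM). Idempotent; all-zero samples are
   rejected by name.
2. **Replicate averaging** (`average_replicates()`): arithmetic mean per
   condition, after normalisation so depth differences do not weight
   replicates.
3. **Condition ratios** (`log_ratio_xyl_glu()`): per gene and strain,
   $\log_2((x + c)/(g + c))$ of xylulose over glucose expression. Logs are
   base 2 throughout (fold-change units); the pseudocount $c$ (default 1, in
   normalised-count units) keeps zeros finite and is negligible for
   well-expressed genes.
4. **Changed-gene calling** (`identify_changed_genes()`): a gene is changed
   when the absolute median ratio across strains reaches a threshold
   (default 1, i.e. two-fold) *and* the median's sign recurs in a minimum
   fraction of strains (default 2/3). With only two replicates per condition
   a per-gene variance model would be unstable, so the rule is deliberately
   a robust median-plus-sign-consistency filter rather than a per-gene test;
   both knobs are exposed.
5. **Gene-set projection** (`enrichment_test()`, `group_summary()`): changed
   genes are projected onto named gene sets (GMT input) — functional
   modules such as amino-acid biosynthesis, ribosomal proteins, ribosome
   biogenesis, stress-response arms, or transcription-factor regulons.
   Enrichment is the upper-tail hypergeometric probability of the observed
   overlap, Benjamini–Hochberg-adjusted across the collection — the
   standard treatment for set projection. Group summaries average gene
   ratios **within strain first, then across strains**, with the standard
   error taken across strains; the alternative order (pool genes over all
   strains) weights strains by detected-gene count and is not implemented.
   Genes present in a set but absent from the matrix are dropped and
   logged, never imputed.
6. **Per-gene paired profiles** (`per_gene_group_profile()`): for within-
   group gene-by-gene comparison of ancestral vs evolved expression, each
   gene's two status means (on the chosen sugar, averaged over strains) are
   divided by that gene's total reads over all samples, putting lowly and
   highly expressed members on a common scale.

## Adaptation analysis

`expression_change()` computes, per strain, the log2 ratio of a group's
mean expression in the evolved population over its ancestor, on xylulose by
default — the condition under selection. The legend-level alternative
(a ratio of xylulose/glucose ratios) can be assembled from
`log_ratio_xyl_glu()` output if wanted; the direct evolved/ancestor ratio on
xylulose is the default because the glucose reference cancels in the
quantity of interest and halves the noise.

`correlate_change_with_growth()` tests whether strains that improved more
changed a group's expression more. It reports the Pearson correlation with
the two-sided parametric p-value (t transform, $n-2$ degrees of freedom) —
two-sided because the sign is part of the hypothesis being reported, not
assumed — plus a seeded permutation p-value (default 10,000 shuffles of the
improvement vector, two-sided via $|r|$, with the add-one estimator
$(1+k)/(1+B)$) as a distribution-free robustness column. At $n = 12$ strains
the permutation and parametric values agree closely for well-behaved data;
divergence flags influential points. Fewer than 3 strains, missing values,
or zero variance raise errors rather than returning nonsense.

`group_vs_group_coordinates()` places each population in the plane spanned
by two programmes' mean ratios (e.g. amino-acid biosynthesis vs ribosomal
proteins) and reports the average displacement acquired during evolution —
on synthetic data with ancestral amino-acid induction switched off by
evolution and growth-coupled ribosomal expression, that displacement points
down on the amino-acid axis and up on the ribosomal axis.

## The synthetic-data generator

The generator exists so that every stage, and the full pipeline, can be
validated against known ground truth without any external download. It
emulates the *statistical structure* the analysis assumes; every numeric
default is invented and labelled as such.

**Growth curves** are baseline-shifted logistics with an explicit lag:
$\mathrm{OD}(t) = b + K/(1 + e^{-r(t - t_m)})$, with $t_m$ placed so the
logistic term is 1% of $K$ at the end of the lag. Gaussian measurement
noise (SD 0.005 OD by default) is added and readings are clipped at a
positive floor. Defaults (baseline 0.05 OD, capacity 1.0 OD, rate 0.3/h,
lag 2 h, reading every 0.25 h) resemble a slow plate-reader batch culture.
This is the minimal model that lets the three observables — maximum OD,
time to saturation, log-phase rate — be dialled independently.
`simulate_strain_panel()` inverts the model in closed form: given per-strain
target folds in maximum OD and saturation time, it sets the evolved
capacity from the first and solves the evolved rate constant from the
second, so the analytic effective-growth-rate fold equals their quotient
exactly and the pipeline's recovered fold can be checked against it. All
wells of a panel share one rectangular time grid, as a real plate would.

**Count matrices** are negative-binomial draws (variance
$\mu + \phi\mu^2$, one shared dispersion $\phi$, default 0.05; $\phi = 0$
gives Poisson) around per-gene means. Glucose means are log-normal
baselines rescaled so each sample expects one million counts; xylulose
means multiply the baseline by $2^{\mathrm{effect}}$:

* amino-acid module, ancestral: effect $= a - b\,g$ with intercept $a$
  (default 1 log2) and slope $b$ (default 5 log2 per OD/h) against the
  strain's growth rate $g$ — induction anti-correlated with growth rate;
* amino-acid module, evolved: a residual (default 0 — the induction is
  lost);
* ribosomal module: effect $= c\,g$ (default $c = 2$ log2 per OD/h) in both
  states, so evolved (faster) strains sit higher;
* background: 0.

Default strain growth rates are an invented ancestral spread (0.04–0.14
OD/h) whose evolved counterparts converge toward a common faster rate
(`0.10 + 0.5 g`), so slower ancestors improve more — the regime in which an
expression change that mirrors ancestral induction is anti-correlated with
improvement. Every simulation returns a truth record (per-strain rates,
folds and module effects, plus per-gene baselines), so recovery tests never
re-derive the injected signal.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: per-gene dispersion variation, GC or length
bias, batch effects between replicates, diauxic or multi-phase growth,
evaporation drift, correlated noise within modules beyond the shared mean
shift, and any mapping/UMI artefacts upstream of the count matrix. Tests on
synthetic data demonstrate that the estimators recover what the model
injects at realistic noise, not that the model is the biology.

## Numerical choices and problem sizes

* Depth normalisation before any ratio; pseudocount 1 on normalised counts.
* Saturation fraction 0.95 with interpolated crossing; smoothing window 5;
  slope window 5.
* One global seed fans out to per-stage seeds by fixed offsets, so a stage
  re-run in isolation reproduces its in-pipeline output; simulation,
  permutation draws and manifests are bit-reproducible given the seed.
* TSV (tab, `.` decimal, header) is the canonical tabular format; GMT for
  gene sets; YAML for configuration (written at 17 significant digits so a
  config round-trips losslessly); the run manifest records an MD5 per
  artifact. Plate CSVs are re-read with base R's correctly-rounded parser
  so write/read round-trips are bit-exact.
* Test and validation sizes are chosen to exercise the estimators at
  experiment-like scale while keeping the suite quick: recovery fixtures
  use 400–2000 genes × 12 strains × 2 replicates; the correlation-recovery
  study uses 100 seeded panels of 400 genes; permutation checks use
  10,000–20,000 shuffles. The vignette and README show outputs the code
  actually produced.

## Known limitations

* The changed-gene rule is a filter, not an inference procedure; it has no
  error-rate guarantee and its thresholds are conventions.
* The hypergeometric enrichment treats genes as exchangeable; co-regulation
  within modules makes its p-values optimistic on real data (a standard
  caveat of set projection).
* With two replicates, replicate-level variance is essentially
  unidentifiable per gene; all strain-level inference leans on the
  twelve-strain panel instead.
* Correlation across 12 strains has wide confidence bands; the package
  reports $n$ alongside $r$ and both p-values, and draws no causal
  conclusion from them.
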