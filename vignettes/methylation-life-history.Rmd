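---
title: "Methylation predictors of life-history traits: models, defaults and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation predictors of life-history traits: models, defaults and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its own science: the statistical
model, the cross-validation schemes, every tunable default with its units
and rationale, what the synthetic-data generator does and does not emulate,
and the decisions taken where the methodology was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

Maximum life span, gestation time and age at sexual maturity are traits of
a species, not of an individual. Methylation levels at CpG sites conserved
across mammals carry enough cross-species signal to predict these traits:
a sparse linear model fitted to species-averaged β values generalises to
species never seen in training. The scientific difficulty is not the fit —
with thousands of CpGs and ~10² species, a penalized regression will always
fit — but the *evaluation*: close phylogenetic relatives resemble each
other both in traits and in methylation, so a predictor can look accurate
while merely interpolating between relatives. The package therefore treats
the cross-validation schemes and the phylogenetic baseline as first-class
parts of the method.

## Trait scale

All traits are modelled as natural logarithms (`to_log()` / `from_log()`):
trait distributions are strongly right-skewed, and the log scale makes the
Gaussian working assumptions of penalized least squares reasonable.

Two corrections precede modelling:

* **Record correction.** Recorded maximum life spans understate the true
  species potential when they derive from few observed individuals.
  `apply_lifespan_correction()` multiplies every species' maximum life span
  by `factor = 1.3`, exempting `Homo sapiens` and `Mus musculus` whose
  records come from enormous observed populations. The 30% increment is a
  convention, not an estimate — hence a parameter rather than a constant —
  and rows carry a `lifespan_corrected` flag that makes the operation
  idempotent. The correction is applied before the log transform and
  before any fitting.
* **Phylogenetic imputation.** Species with no life-span record receive
  the value of their patristically nearest neighbour with one
  (`impute_lifespan()`, K = 1; ties broken by lexicographic species name
  so the result is auditable). Imputed rows are flagged; the LOCO analysis
  excludes them entirely, because an imputation that copies a neighbour's
  value would bias the comparison in favour of the phylogenetic baseline.

## Preprocessing

`filter_probes()` keeps a CpG when its per-species Benjamini–Hochberg
adjusted median detection p-value is below 0.05 in at least
`ceiling(0.85 × n_species)` species. Two interpretation decisions: BH runs
*within* each species across CpGs (detection quality is a per-array,
per-species property), and species with missing detection values count in
the denominator with p treated as 1 — the conservative reading.

`aggregate_methylation()` averages β per species (tissue-agnostic) or per
(species, tissue) stratum, ignoring missing values; any cell still empty
after aggregation is imputed with the column mean across strata. Column-mean
imputation completes the design matrix without inventing trait signal. In
tissue-aware mode each stratum is one observation with equal weight; no
reweighting by sample count is attempted.

`select_young()` retains samples with known age below both the species'
age at sexual maturity and 5 years; samples with unknown age are excluded
because neither condition can be verified.

## The predictor

`trait_predictor()` fits an elastic net of the log trait on stratum-mean β
values:

* mixing parameter α = 0.5 — the convention of methylation-clock work,
  exposed in the interface;
* predictors standardized to zero mean and unit SD at fit time,
  coefficients reported back on the β scale;
* penalty strength λ chosen by internal 10-fold cross-validation on the
  training strata only, minimizing mean squared error (`lambda.min`);
  folds are drawn from the run's single RNG stream, so one seed reproduces
  everything;
* optional one-hot taxonomic-order indicators as candidate predictors
  alongside the CpGs; their selection status is kept in the fitted object
  (`taxonomy_coef`), so "does the penalized model prefer CpGs over
  taxonomy?" is a stored fact, not an anecdote.

After fitting, predictions are **calibrated**: an affine map rescales them
so their mean and SD on the training data equal those of the observed
trait. The map is fitted on the model's in-sample fitted values — the
methodology leaves open whether fitted or cross-validated predictions
should be used; fitted values were chosen because the calibration then
composes deterministically with the final model and is frozen for external
application (it is serialized inside the model JSON). Calibration is
affine, so it changes no correlation, only the reporting scale.

`predict_samples()` applies a species-level model to individual samples,
imputing absent CpGs with the stored training means; a sample missing more
than 20% of the model's CpGs is flagged `low_confidence` but still
predicted.

Degenerate inputs: a constant response is refused (`degenerate-response`),
as are designs with fewer than 10 strata and predictions with zero SD at
calibration time. A model whose penalty removed every CpG predicts the
calibrated intercept.

## Evaluation schemes

* **LOSO** (`loso_cv()`): one fold per species; in tissue-aware mode all
  strata of the held-out species leave together. The penalty is
  re-selected within every fold — reusing one λ across folds would leak
  information from the held-out species into its own regularisation.
* **Modified LOCO** (`loco_cv()`, folds from `loco_folds()`): one fold per
  taxonomic order. Orders with more than 20 species keep exactly two
  members in training — those with the minimum and the maximum life span —
  and the rest are tested; orders with 20 or fewer species (the boundary
  read strictly as "over 20") are held out completely. Extremes are
  located on the corrected values, since those are what the model sees;
  ties break lexicographically. Imputed species are excluded before folds
  are formed.
* **Random 70/30 species split** (`split_train_test()`), split by species
  so no species straddles the boundary.

Accuracy is always reported as Pearson R with its two-sided unadjusted
p-value and the median absolute error on the log scale
(`accuracy_metrics()`).

The comparator is k-NN regression on patristic distances
(`knn_predict()`): the unweighted mean of the K nearest training species'
log traits, ties broken by name. Patristic distance on the supplied tree is
used as "closeness" (for an ultrametric time tree this is equivalent to
divergence time); averaging is unweighted because the baseline is meant to
be the plain k-NN reading, and it consumes exactly the same corrected,
log-transformed traits as the elastic net so the comparison is fair.

## Downstream readouts

* `sex_difference()`: per (species, tissue) stratum with at least 2
  samples per sex (smaller cells carry no rank information), a two-sided
  Wilcoxon rank-sum test of female vs male predictions — exact for small
  untied samples, normal approximation with tie correction otherwise. The
  species verdict is `+` when ≥ 1 tissue is significant at P ≤ 0.01 and
  *all* significant tissues have a positive female−male difference, `−`
  symmetrically, `.` otherwise. Where one tissue is significant and
  another shows an opposite but non-significant difference, only the
  significant tissues vote.
* `age_association()`: per-stratum Pearson correlation of predictions with
  age (≥ 4 aged samples; constant-age strata skipped). Unadjusted
  p-values, by design; a BH option exists on `sex_difference()` for users
  who want it.
* `weight_adjusted_analysis()`: OLS of observed log life span on
  {prediction, log weight} with Wald tests, and the weight-adjusted R
  defined concretely as the partial correlation of observed and predicted
  given weight (the correlation of the two weight-residual vectors).
* `group_comparison()`: per stratum, a two-group OLS Wald statistic
  referred to the standard normal — not Welch — matching the
  "standard normal under the null" framing of intervention contrasts;
  adequate for the group sizes used here (the null calibration check runs
  at 50 + 50).
* `ageaccel()`: raw OLS residual of prediction on age; zero mean and zero
  age-correlation by construction.
* `breed_analysis()`: breed means of predicted log maximum life span,
  with each breed's maximum life span derived as 1.33 × its median life
  span, and correlations against log derived maximum and log mean weight.

## The synthetic-data generator

`simulate_dataset()` produces a complete study — tree, trait table,
sample-level β matrix, detection p-values and planted truth — with the
statistical structure the analyses assume. Defaults (all overridable in
`sim_config()`) define the package's reference study conditions:

| parameter | default | units / meaning |
|---|---|---|
| `n_species` | 120 | tree tips |
| `n_cpgs`, `n_informative` | 3000, 300 | CpG universe; planted subset |
| `effect_scale` | 0.4 | logit β per log-year at informative CpGs |
| `noise_sd_species` | 0.05 | idiosyncratic species β noise |
| `noise_sd_phylo` | 0.04 | tip SD of Brownian species β noise |
| `noise_sd_sample` | 0.03 | within-species β noise |
| `tissues` | blood +0.02, liver 0, skin −0.02, muscle +0.01 | β offsets |
| `n_sex_dimorphic`, `sex_effect` | 8, 0.04 | species; β offset at informative CpGs |
| `n_age_strata`, `age_slope` | 10, 0.003 | strata; β per year |
| `dropout_rate` | 0.05 | P((species, CpG) fails detection) |
| `brownian_sigma` | 0.6 | log-years per √(unit branch length) |
| `root_lifespan` | 20 | years at the tree root |
| `missing_lifespan_rate` | 0.05 | withheld records (for imputation) |
| `anage_shortfall` | 1.3 | recorded = true / shortfall |

Generative choices worth spelling out:

* **Tree and orders.** A random coalescent tree; taxonomic orders are
  derived by cutting the tree at a depth chosen so that the partition is
  as lopsided as mammalian taxonomy — at least one order above 20 species
  and at least one singleton (proportionally smaller targets for small
  test panels). The LOCO scheme is only meaningful under such
  heterogeneity.
* **Traits.** Log maximum life span evolves by Brownian motion from
  log(20 years); log gestation, maturity and weight are linear in it plus
  independent noise. With the default rate, simulated life spans span
  roughly 4–110 years. Recorded values are divided by 1.3 so the
  pipeline's correction step recovers the generative scale, and 5% of
  records are withheld to exercise imputation.
* **Methylation.** Informative CpGs follow
  `β = plogis(baseline + slope × centred log life span)` — logistic
  squashing keeps β in [0, 1] while preserving monotonicity — then
  species-level noise, tissue offsets and sample noise are added on the β
  scale and the result is hard-clipped to [0, 1]. With all noise at zero
  the species mean of an informative CpG is an exactly monotone function
  of the trait (asserted in the tests).
* **Phylo-correlated noise.** Species-level noise has two components: an
  iid signature per species and a Brownian-on-the-tree component. The
  second is essential: real consortium data shows phylo-epigenetic
  structure beyond what traits explain, and it is precisely what makes
  leave-one-clade-out evaluation harder than leave-one-species-out, and
  what lets a phylogenetic k-NN look competitive under LOSO. Without it, a
  simulator makes LOCO as easy as LOSO and the scheme comparison becomes
  vacuous. The two SDs were set so that default-condition LOSO accuracy
  sits in the realistic R ≈ 0.85–0.95 regime.
* **Sex and age effects** are β offsets applied to the informative CpGs
  along each CpG's slope sign (female−male offset `sex_effect` with a
  random per-species sign; `age_slope × age` in designated strata). Planting
  along the trait direction means the effects project coherently onto model
  predictions, so downstream power measures the pipeline, not a single
  lucky CpG. Dimorphic species get 12 samples (6 per sex, one tissue):
  with fewer than 5 per sex, an exact two-sided rank-sum test cannot reach
  P ≤ 0.01 at all. Age-trend species get 8 samples in the designated
  tissue; everyone else gets 2–8 samples over 1–4 tissues with ages
  uniform on [0, 0.8 × life span].
* **Detection.** Each (species, CpG) pair fails with probability
  `dropout_rate`; failing pairs draw p from Uniform(0.1, 1), passing ones
  from Uniform(0, 10⁻⁴), and failing pairs' β values are set missing.
  Detection is generated at (species, CpG) granularity because only the
  per-species median is consumed downstream.
* **Breed clade.** Optionally, one clade's members share the methylation
  signature implied by the clade-mean trait (within-clade β SD
  ~0.002) while their individual traits scatter around the clade mean
  (SD 0.3 log-years). This is the within-species analogue of dog breeds:
  recent selection has moved the trait but not the species-level
  epigenetic signature. The correct way to evaluate it is as an *external*
  application set — train the model without the clade members' individual
  traits, then apply it to their samples. Training on the individual
  pseudo-breed traits instead lets the penalized fit memorise them
  in-sample and manufactures a spurious breed–trait correlation.

What the generator does **not** emulate: probe sequences, genomic
coordinates or CpG-island context; array-version differences; non-Gaussian
β distributions (real β values are bimodal); tissue-specific *slopes*
(tissue enters only as an offset); measurement batch structure; and any
methylation signal for gestation or maturity beyond their correlation with
life span. That last point matters when reading results: on synthetic data
the gestation and maturity predictors can only be as good as the
trait-link correlation allows (LOSO R ≈ 0.65 at the defaults), whereas on
real data those traits have their own epigenetic signal. Passing tests
demonstrate that the pipeline recovers what was planted under this
structure — not that real data behaves identically.

## Problem sizes and numerical choices

The reference conditions used by the test suite and the acceptance script
are 120 species × 3000 CpGs (300 informative), seed 1 — large enough that
the probe filter, LOCO fold rule and planted-signal recovery all operate in
their intended regime, small enough for interactive iteration. Null
calibration of the downstream tests uses 1000 independent strata per test
(10 + 10 for the rank-sum test, 10 for age, 50 + 50 for group contrasts);
group-contrast power uses 200 strata at a +0.5 log-year shift with noise
SD 0.3.

Numerical conventions, collected: β clipped to [0, 1] after noise;
distance and trait ties broken by lexicographic species name everywhere a
choice is needed; internal CV folds seeded from the single run seed;
`grouped = FALSE` is passed to the internal CV when folds would hold fewer
than 3 observations; calibration demands SD(predictions) > 0 and equality
checks in the tests use 10⁻⁹ (calibration moments) and 10⁻¹² (log
round-trip).

## Known limitations

* Age-trend power depends on the species' age range: with ages drawn up to
  0.8 × life span, short-lived species offer little age spread, and at the
  default slope (0.003 β/year) a planted stratum in a short-lived species
  can go undetected at some seeds.
* The breed negative control correlates ~11 breed means with breed traits;
  the null SD of a correlation at that n is ≈ 0.3, so its value is noisy
  across seeds even when predictions are essentially flat.
* `group_comparison()` refers the Wald statistic to the standard normal;
  at very small group sizes this is anticonservative relative to a t
  reference (the package's calibration checks therefore run at 50 + 50).
* Species matching is exact-string on binomials; no synonym resolution.
* The elastic-net nonzero set is reported, but no inference is attached to
  individual coefficients — selection among correlated CpGs is unstable by
  nature, and only the prediction, not the support, is treated as the
  model's output.
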