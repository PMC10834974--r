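---
title: "Methods: age-adjusted metabolomic screening and diagnostic panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-adjusted metabolomic screening and diagnostic panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabodiag)
```

# The problem

Targeted plasma metabolomics is increasingly used to screen for ischemic
heart disease (IHD): dozens of acylcarnitines, amino acids, tryptophan
catabolites and NO/urea- and methionine-cycle intermediates are quantified
by LC-MS/MS, compared between patients and controls, and fed into
classifiers. Two statistical obstacles dominate in practice:

1. **Age confounding.** Case cohorts are typically decades older than
   healthy controls (here: ages 64 [58–71] versus 34 [26–44] years), and
   many plasma metabolites drift with age. Without correction, a large
   fraction of "significant" metabolites merely re-measure age.
2. **Small cohorts, many features.** With roughly a hundred subjects and
   as many features, classifier comparisons need a disciplined
   cross-validation protocol, and single-model feature rankings are
   unstable — motivating consensus selection across model families.

`metabodiag` implements a complete pipeline for this setting, together
with a synthetic-cohort generator whose ground truth makes every stage
testable.

# The age-adjustment correction

The correction removes the age-associated component of each metabolite
using only the control (non-CVD) group as reference:

1. select the control subjects and bin them into fixed-width age strata
   (default 5 years, half-open bins anchored at multiples of the width);
2. compute the median concentration of each metabolite in each stratum;
3. fit an ordinary least-squares line through the (stratum age, median)
   points, giving a slope $\hat\beta_m$ per metabolite $m$;
4. the age-associated delta for a subject of age $a$ is
   $\hat\beta_m (a - a_0)$, where $a_0$ is the reference age;
5. subtract the delta from every subject's absolute concentration (both
   groups).

Stratum medians — rather than per-subject regression — make step 3 robust
to skewed concentration distributions and outliers within strata.

Choices the procedure leaves open, and the package's defaults:

* **Representative stratum age**: the bin midpoint.
* **Reference age $a_0$**: the control-group median age rounded to the
  nearest year (`reference_age = "auto"`), anchoring corrected values to
  the reference population's center; any fixed age can be supplied.
* **Sparse strata**: strata with fewer than `min_stratum_size = 2`
  controls are dropped with a warning (a median of one subject is noise).
* **Weighting**: unweighted OLS on the median points by default — the
  literal stratified-median algorithm; `weighted = TRUE` weights by
  stratum size.
* **Negative adjusted values** are kept and counted (the correction is a
  statistical transform, not a concentration estimate); `clip = TRUE`
  floors them at zero for consumers that require positivity.
* Metabolites whose fit is impossible (fewer than two usable strata) get
  a null slope and pass through unchanged, with a warning.

## What the correction can and cannot do

The identity and location-shift properties are exact: a zero-slope model
is the identity map, and within any fixed age the correction shifts all
subjects by the same constant, preserving within-stratum variance.

On synthetic cohorts the correction removes essentially all of the
*systematic* age trend: post-correction control-group slopes are below
10% of the injected slopes, and injected slopes are recovered within a
few percent at `n_control = 200` and noise CV 0.1 (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`).

There is, however, a structural limit that the test suite measures and
deliberately leaves visible. The fitted slope carries sampling error of
order $\sigma/(\mathrm{sd}(a)\sqrt{n})$, and the correction propagates
that error across the *between-group* age gap (~29 years here). Because
the slope error and the residual noise scale together, the induced
spurious group shift is a roughly constant fraction of the noise SD
(~0.2 at these sample sizes) regardless of the noise level — enough for
a Mann–Whitney test at $n = 200$ per group to reject in a large fraction
of null metabolites. The acceptance suite asserts the idealized
post-correction false-positive band [0.01, 0.10] at $\alpha = 0.05$ and
records the measured fraction (~0.5 under the stated conditions); the
robust, attainable property — an order-of-magnitude reduction from a
pre-correction fraction of ~1.0 — is asserted in the module tests. The
practical reading: the correction is effective for removing age trends,
but residual-confounding false positives remain likely when the group
age gap is large relative to the control age range, and findings should
be triaged accordingly.

# Univariate screening

Per feature (87 panel metabolites plus the Fischer ratio
$(\mathrm{Val}+\mathrm{Ile}+\mathrm{Leu})/(\mathrm{Phe}+\mathrm{Tyr})$
and the GSG ratio $\mathrm{Gln}/(\mathrm{Ser}+\mathrm{Gly})$):

* **Test routing**: Shapiro–Wilk at $\alpha = 0.05$ in each group; the
  Student t-test is used only when *both* groups pass, otherwise the
  Mann–Whitney U test. Degenerate groups (n < 3, zero variance) route
  non-parametrically with a warning.
* **AUC**: the rank-based (Mann–Whitney) AUC with midrank ties, reported
  direction-agnostically as $\max(a, 1-a)$ so that the value is always in
  [0.5, 1]; the side of the effect is carried by the direction column.
* **Youden statistic**: an exhaustive scan over all empirical cutoffs in
  both orientations. Both $J = \mathrm{sens} + \mathrm{spec} - 1 \in
  [0,1]$ and $\mathrm{sens} + \mathrm{spec} \in [0,2]$ are reported —
  published panels sometimes print the latter under the name "Youden
  index", and reporting both removes the ambiguity. Ties in $J$ break
  toward higher specificity.
* **Fold change**: $\log_2$ of the case/control *median* ratio, computed
  on the raw (pre-correction) scale where concentrations are positive.
* **Significance filter**: `p < 0.05` and `AUC > 0.65` by default, both
  configurable. No multiple-testing correction is applied by default —
  this reproduces the behavior of a raw per-metabolite screen;
  `p_adjust = "BH"` switches the filter to Benjamini–Hochberg adjusted
  p-values, which is the safer option when the screen feeds decisions
  rather than a descriptive table.

The GSG numerator deserves a note: the ratio is defined in the field
both as glutamate- and glutamine-based. The package defaults to
glutamine over serine plus glycine, with glutamate present in the panel
and the definition fully configurable via `defaultRatioDefinitions()`.

The PCA overview standardizes every metabolite to unit variance
(concentration scales span five orders of magnitude across the panel),
flags subjects beyond the 97.5% chi-square contour of the first two
component scores, and never removes anything silently.

# The diagnostic-model stage

Five classifier families are compared: ridge-penalized logistic
regression (`glmnet`), linear-kernel SVM (`e1071`), CART decision tree
(`rpart`), random forest (`randomForest`) and gradient boosting
(`xgboost`). The bespoke content is the protocol around them:

* **Evaluation protocol.** One stratified k-fold split (default k = 5)
  is shared by all models. Within each training fold, hyper-parameters
  are grid-searched by inner stratified cross-validation scored by AUC;
  the tuned model is refitted on the training fold and scores the
  held-out fold. Pooling the out-of-fold scores yields a single
  full-cohort confusion matrix and ROC per model — the natural way to
  report one confusion matrix over the whole cohort while keeping every
  prediction out-of-sample. This protocol is an interpretation: published
  comparisons of this kind often report a full-cohort matrix without
  stating the split.
* **Positive class** defaults to the case (IHD) label and is explicit
  configuration; note that published 2x2 tables sometimes imply the
  control group as "positive" (TP + FN equal to the control margin).
* **Decision threshold** 0.5 on the predicted probability;
  `threshold = "youden"` selects the Youden-optimal cutoff instead.
* **Standardization**: features are z-scored for the linear models with
  statistics fitted on training data only; tree models take raw
  features.
* **Class imbalance** (36 vs 76) is left unweighted by default,
  matching common practice in small biomarker studies.
* **Grids** are modest (at most 12 combinations per family); grid search
  at this cohort size is about guarding against pathological settings,
  not fine optimization.

**Consensus panel.** Each model contributes its top-15 features (linear
models by absolute standardized coefficient, trees by impurity
importance). A feature enters the consensus panel when it appears in a
majority of model sets (default 3 of 5) *and* passes the univariate
filter; the panel is ordered by supporting-model count, then univariate
AUC. The majority-vote rule is the package's own formalization of
"significant in most models".

# The synthetic-cohort generator

The generator exists so that every stage above can be tested against
known ground truth. For subject $i$ and metabolite $m$:

$$c_{im} = \max\!\left(10^{-9},\;
  \big(b_m + s_m (a_i - a_0)\big)\cdot
  2^{\delta_m \mathbf{1}[i \in \mathrm{case}]}\cdot \eta_{im}\right)$$

* **Ages** are truncated normal on [18, 95], with mean the target median
  and SD = IQR/1.349 — the simplest family reproducing a median/IQR
  summary. Defaults: 36 controls at 34 [26–44] and 76 cases at
  64 [58–71] years.
* **Noise** $\eta_{im}$ is multiplicative log-normal with unit mean and
  CV 0.25 (typical combined analytical plus biological variability);
  concentrations stay positive and CVs are scale-free.
* **Group effects** are multiplicative on the age-detrended mean
  (additive effects would break positivity). The default panel's signed
  log2 effects are calibrated so that each disease analyte's *expected
  standalone* rank AUC under the default noise lands on the 0.62–0.84
  scale reported for IHD panels, via the binormal relation
  $|\delta| = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})\,\sigma_{\log}/\ln 2$.
* **Age slopes** (fractions of baseline per year, positive for e.g.
  cystathionine, citrulline, dimethylarginines, long-chain
  acylcarnitines, kynurenine intermediates; negative for serotonin,
  glycine, taurine) reflect literature-typical directions; metabolites
  without documented trends get zero slope.
* The reference age $a_0 = 40$ is a free generator parameter recorded in
  the ground truth; panel metabolites not assigned an effect act as null
  fillers.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: metabolite–metabolite correlation
(features are conditionally independent given age and group, which makes
multivariate separation *easier* than in real cohorts — synthetic
full-panel AUCs near 1.0 should not be read as a performance claim),
batch effects and instrument drift, censoring at the LOD, non-linear age
trends, and clinical covariates beyond age/sex/group.

# Numerical choices and degenerate inputs

* Medians are the standard order statistic (mean of central pair).
* The Youden scan uses midpoints between adjacent sorted unique pooled
  values plus sentinels outside the range, so the degenerate "always
  positive"/"always negative" rules are always candidates and $J \ge 0$.
* Undefined metrics (empty confusion-matrix margins, single-class test
  sets) are reported as `NA`, never 0.
* Zero-variance features: excluded from PCA with a warning; constant
  columns min–max normalize to zeros with a warning.
* Ratio denominators $\le 0$ give missing values with a warning, never
  silent drops.
* All randomness flows through explicit integer seeds; cohort
  generation, fold assignment and all five model fits are bit-identical
  under a fixed seed (stochastic learners are fitted inside a
  seed-scoped RNG context that restores the caller's RNG state).

# Problem sizes used by the test and acceptance suites

Chosen as the smallest sizes at which the tested properties are stable:
oracle equivalence of the rank AUC on instances up to 100 x 100;
age-slope recovery and de-trending at 200 controls; the confound study
at 200 + 200 subjects and 500 metabolite-replicates; consensus recovery
over 20 seeded replicates of a 36 + 76 cohort with 11 affected
metabolites among 40 (single-point tuning grids and lighter ensembles
in replicated studies, full grids elsewhere); the end-to-end demo at the
default 87-metabolite, 112-subject configuration.

# Known limitations

* The age model is strictly linear; splines or quadratic trends are out
  of scope by design.
* The correction addresses age only — no sex, BMI or medication
  covariates.
* Residual confounding from slope-estimation error is quantified but not
  eliminated (see above); methods that model the covariate per subject
  (e.g. covariate-adjusted regression on all subjects) trade robustness
  for efficiency and are deliberately not substituted for the
  stratified-median algorithm.
* Consensus voting treats model families equally regardless of their
  individual performance.
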