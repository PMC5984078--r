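---
title: "Two-stage multi-site meta-analysis of diffusion MRI ROI measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage multi-site meta-analysis of diffusion MRI ROI measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design this package implements

Large consortia studying white-matter microstructure in psychiatric disease
face a basic obstacle: subject-level diffusion MRI data usually cannot leave
the acquiring site. The coordinated (prospective) meta-analysis design works
around this. Every site runs *identical* statistical models on its own
subjects — case–control contrasts and clinical regressions on region-of-
interest (ROI) summaries of the tract-based white-matter skeleton — and
uploads only summary statistics. A central stage pools those summaries with
random-effects inverse-variance weights, quantifies between-site
heterogeneity, and applies family-wise error control across the ROI family.

`dtimeta` implements both stages plus the surrounding machinery: a
calibrated synthetic multi-site cohort generator (so the full pipeline is
testable end to end without any real data), ROI summaries of voxelwise
skeleton values with a core/periphery decomposition, a CSV interchange
dialect for site summary tables, and a manifest-driven driver.

## The per-site model

For each ROI $r$ and metric (FA, and optionally MD, AD, RD), each site fits

$$ y_i = \beta_0 + \beta_{dx}\,\mathrm{dx}_i + f(\mathrm{age}_i,
   \mathrm{sex}_i) + \varepsilon_i, $$

where $f$ contains age, sex, age$\times$sex, age$^2$ and
age$^2\times$sex — linear and nonlinear age/sex structure is well
documented for FA, so it is part of the base covariate set everywhere,
including the clinical moderator regressions. Age is mean-centered within
site *before* squaring; this tames the collinearity between age and
age$^2$ without changing the diagnosis contrast. Rows with a missing
outcome or covariate are dropped listwise, and a site contributes a given
contrast only when both groups retain at least 10 subjects after deletion
(`MIN_GROUP_N`); every exclusion is logged with its triggering rule.

The diagnosis contrast is converted to Cohen's *d* (patients minus
controls; negative means lower in patients) from the coefficient's $t$
statistic:

$$ d = t\,\frac{n_1+n_2}{\sqrt{n_1 n_2}\sqrt{\nu}},\qquad
   \mathrm{se}(d) = \sqrt{\frac{n_1+n_2}{n_1 n_2} +
   \frac{d^2}{2(n_1+n_2-2)}}, $$

with $\nu$ the residual degrees of freedom. These are the Hedges–Olkin
large-sample expressions used by the consortium effect-size scripts; in the
plain two-group model they equal the classical pooled-s.d. *d* times
$\sqrt{(n_1+n_2)/\nu}$, and no small-sample (Hedges $g$) correction is
applied. Subgroup contrasts (smokers vs nonsmokers, medication classes) run
through the same machinery with the diagnosis indicator replaced by the
subgroup indicator; dispersion differences between groups are compared by a
variance-ratio $F$ test, with a Brown–Forsythe-style option (t test on
absolute deviations from group medians) for robustness.

## The pooled stage

Site records $(y_i, s_i)$, $i = 1 \dots k$, are pooled with random-effects
inverse-variance weights. Fixed-effect weights $w_i = 1/s_i^2$ give
Cochran's $Q = \sum_i w_i (y_i - \bar y_{FE})^2$, and

* **DerSimonian–Laird**:
  $\hat\tau^2 = \max\!\left(0, \frac{Q-(k-1)}{\sum w_i - \sum w_i^2/\sum
  w_i}\right)$ — closed form, used in closed-form tests;
* **REML** (default): the root of the restricted-likelihood score in
  $\tau^2$, found by bracketed root-finding to $10^{-10}$ with the
  boundary solution $\hat\tau^2 = 0$ when the score at zero is
  non-positive. REML is the default of the metafor generation of tools this
  stage mirrors.

Random-effects weights $w_i^* = 1/(s_i^2 + \hat\tau^2)$ yield the pooled
estimate, its standard error $(\sum w_i^*)^{-1/2}$, a two-sided normal
p-value, and $I^2 = \max\{0, 100\,(Q-(k-1))/Q\}$, defined as 0 for
$k = 1$. No Knapp–Hartung adjustment is applied. The primary case–control
FA family is tested against the Bonferroni threshold $\alpha/m$ with
$\alpha = 0.05$ and $m = 25$ measures, i.e. 0.002; secondary families
(diffusivity metrics, moderators) default to the same rule per family.
Report tables are sorted by decreasing $|d|$, ties broken by ROI name.

Cross-ROI secondary analyses: a paired t test across the 25 per-ROI
effects compares sex-stratified effect vectors; Pearson correlation of
effect size with $\sqrt{N_\mathrm{voxels}}$ (signed and magnitude)
quantifies the ROI-size artifact; and site-attribute partitions (e.g. high
vs low gradient-direction counts) are pooled per group and contrasted with
a normal z test on the difference of pooled estimates.

## What the generator emulates — and what it does not

No subject-level generative model is published for this design (the
consortium analyzed real scans), so the generator adopts the minimal
structure under which the per-site covariate model is correctly specified:

$$ y = \mu_r + u_s + \kappa_s\big[\sigma_{r,g} f_\mathrm{std}(\mathrm{age},
   \mathrm{sex}) + \ell(\mathrm{moderators}) + \mathrm{dx}\,(\delta_r +
   b_{sr} + \mathrm{shifts})\,\sigma^\mathrm{pool}_{\varepsilon,r} +
   \varepsilon \big] $$

* **Sites.** 29 cohorts by default; per-group sizes drawn uniformly on
  20–250, spanning realistic cohort sizes. Site intercept shifts
  $u_s \sim N(0, 0.005^2)$ FA units; an optional multiplicative scale
  jitter $\kappa_s$ defaults to off because a per-site scale would
  contradict the per-site marginal-s.d. calibration targets by definition
  (Cohen's *d* is invariant to it either way — the demo manifest enables
  it).
* **Diagnosis effects.** Standardized per-ROI truths $\delta_r$ default to
  the registry's reference FA effect column (whole-skeleton −0.42, anterior
  corona radiata −0.40, ...), injected in units of the pooled residual
  s.d.; site deviations $b_{sr} \sim N(0, \tau^2)$ with $\tau = 0.05$
  encode between-site heterogeneity on the *d* scale. Optional
  sex-dependent (`d_sex_shift`) and smoking (`smoker_d`) shifts support the
  interaction and subgroup analyses.
* **Calibration.** The residual s.d. is solved analytically per ROI and
  group so the *within-site marginal* s.d. of each measure matches its
  target — 0.0194 (controls) and 0.0176 (patients) for whole-skeleton FA,
  0.030 for tract ROIs in controls — after subtracting the variance of the
  systematic component (age/sex trends plus latent moderator links). Those
  moments are computed by a fixed-seed Monte-Carlo quadrature (n = 200 000,
  private RNG stream restored afterwards), which captures all covariances
  exactly (onset and duration both feed age), and the validator rejects
  configurations whose systematic variance exceeds the marginal target.
  Site shifts sit *on top* of this within-site calibration as between-site
  variation; this is the package's calibration convention and makes the
  printed dispersions a testable target rather than a label.
* **Demographics and clinic.** Controls: age uniform on 18–54 (mean 36),
  53.4% male. Patients: 67% male; age at onset truncated-normal (mean 23,
  s.d. 4, minimum 13 — the s.d. keeps the truncation bias on the mean
  negligible while staying clinically plausible), illness duration gamma
  (mean 13.2 y, shape 4), and age = onset + duration, so the onset/duration
  decomposition holds exactly and patient mean age lands near 36.
  CPZ-equivalent dose is gamma with mean 371.23 mg and shape 4
  (coefficient of variation 0.5, typical of dose distributions); symptom
  scales are normal around the printed consortium means (PANSS total 55.90,
  SANS 16.72, SAPS 13.70); medication classes follow 71/6/10/13%
  atypical/typical/both/none, with doses only for medicated patients; 51%
  of patients smoke. Only means are printed for most of these, so the
  shapes are the package's documented choices. Per-site *coverage* masks
  whole sites' clinical fields, emulating scales that only some cohorts
  recorded (e.g. CPZ at 10 of 29 sites).
* **Correlation.** ROI residuals are compound-symmetric across measures
  ($\rho = 0.5$ by default) so whole-skeleton FA covaries with tract ROIs;
  the true cross-ROI covariance of skeleton data is unpublished, so this
  is an exposed assumption.

What it does **not** emulate: raw diffusion images, tensors, registration
or skeleton-projection error; scanner-protocol confounds beyond site
location/scale; non-Gaussian tails or outliers; subject-level missingness
within a recorded site; and within-subject aggregation identities between
composite and component ROIs (measures are simulated as 25 separate
correlated outcomes — the exact voxel-level identities live in the skeleton
module, where they are enforced and tested). Passing tests therefore show
parameter recovery and error control *under this model*, not robustness to
artifacts real pipelines produce upstream.

## Skeleton ROI summaries

The skeleton module operates on flat labeled voxel vectors (no geometry is
needed for means). Hemisphere labels (`ACR_L`/`ACR_R`) are combined by
pooling voxels, i.e. a voxel-count-weighted average of hemisphere means;
composite ROIs (full corpus callosum, corona radiata, internal capsule) are
voxel-count-weighted means of their components. The whole-skeleton average
splits exactly into the atlas-labeled "core" and the remaining "periphery":
$N \bar y = N_c \bar y_c + N_p \bar y_p$, an identity tested to $10^{-12}$
and used to recover subject-level periphery FA from the average and core
when voxel data are not available. The real 112 889-voxel template is not
shipped; `synthetic_atlas()` builds a small flat atlas with
registry-proportional ROI sizes for tests and demos. ROIs with no voxels
are reported missing, never zero; an atlas without periphery voxels
degrades to average = core with a warning.

## Numerical choices and degenerate inputs

* $k = 1$ pooling is the identity with $Q = I^2 = \tau^2 = 0$.
* $I^2$ is clamped to 0 whenever $Q < k-1$.
* Rank-deficient site designs fail loudly, naming the collinear terms.
* Adjusting whole-skeleton FA for itself (global covariate `average_fa`,
  ROI `AverageFA`) is an exact self-regression and is skipped for that one
  measure.
* Identical effect vectors give zero-variance paired differences; the
  paired statistic is undefined and raises an error rather than reporting
  $t = 0$.
* Interchange CSVs serialize floats with 17 significant digits, so
  write-then-read round-trips to full double precision.
* All case–control fits in one site share a single QR factorization across
  ROI outcomes (the design is identical after listwise deletion on
  covariates); a test pins the fast path to `stats::lm` output at
  $10^{-10}$.

## Problem sizes used by the test suite

The suite exercises the pipeline at desk scale, chosen as the smallest
sizes at which the targeted properties are sharp: calibration at one site
of 5000 + 5000 subjects; headline-effect recovery over 20 generator seeds
of the full 29-cohort design (20–250 per group, $\tau = 0.05$); family-wise
error control over 240 replicate 29-site meta-analyses with 20–60 subjects
per group (type-I behavior does not depend on site size); and
moderator-null z calibration over 125 small sites.

## Known limitations

* Because each site's $\mathrm{se}(d)$ depends on its own $\hat d$,
  chance-extreme sites are slightly downweighted, attenuating pooled $|d|$
  by roughly 1–3% at 20–250-per-group sites — a known property of
  standardized-mean-difference meta-analysis with estimate-dependent
  variances, inherited deliberately from the pinned conversion formulas.
* The exact dispersion test behind the published patients-vs-controls
  s.d. comparison is unreported; both implemented variants (F ratio,
  Brown–Forsythe) are labeled, and neither is claimed to reproduce the
  unreported statistic.
* p-values are normal-theory; with very few sites they are anti-
  conservative compared with Knapp–Hartung-type adjustments, which are not
  implemented.
* The generator's defaults are the study conditions; they are exposed in
  `generator_config()` but the package does not claim robustness outside
  them.

## A minimal end-to-end run

```{r demo}
library(dtimeta)
man <- demo_manifest(seed = 7)
res <- run_pipeline(man)
head(res$table1)          # primary FA case-control report (25 rows)
res$report                # every pooled ROI x metric x model cell
list.files(man$out_dir)   # interchange CSVs, reports, forest data, provenance
```
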