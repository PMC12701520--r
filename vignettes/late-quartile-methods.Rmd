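---
title: "Methods: hippocampal-volume quartile enrichment for suspected LATE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hippocampal-volume quartile enrichment for suspected LATE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lateq)
```

## The stratification model

`lateq` implements a deliberately simple in-vivo proxy for concomitant
limbic-predominant age-related TDP-43 encephalopathy (LATE) in patients on
the Alzheimer's disease (AD) continuum: disproportionate hippocampal
atrophy. The working measure is the total hippocampal volume (anterior +
posterior hippocampus) of the *smaller* hemisphere. The minimum — rather
than the mean — is used because LATE neuropathologic change (LATE-NC) is
frequently asymmetric, so averaging would dilute exactly the signal of
interest. The same minimum-hemisphere convention is applied wherever a
single per-subject value is needed (the ERC/PHC ratio uses it too, with a
mean-of-hemispheres option), for internal consistency.

Volumes are adjusted to a cognitively unimpaired (CU) reference by ordinary
least squares of minimum-hemisphere HV on age at MRI and intracranial
volume (ICV), fitted in amyloid-negative CU subjects only. Sex is
deliberately not a covariate: ICV carries the sex difference in head size,
and adding both would split one effect across two collinear terms. The
adjustment keeps the mm^3 scale,

$$\mathrm{HV}_{adj} = \mathrm{HV}_{min}
  - \hat\beta_{age}(age - \overline{age}_{CU})
  - \hat\beta_{ICV}(ICV - \overline{ICV}_{CU}),$$

so a subject at the CU covariate means is unchanged and an older subject is
credited back the age-expected loss. Quartile cut-offs are the 25th and
50th percentiles of adjusted HV among amyloid-positive cognitively impaired
(CI) subjects — the distribution in which LATE co-pathology is hypothesised
to populate the lower tail. The convention is linear interpolation between
order statistics (R's type 7); it is configurable because no single
convention is canonical, and at realistic sample sizes the choice moves the
cut-offs by fractions of a millimetre cubed. Boundary values (adjusted HV
exactly at a cut-off) fall into the excluded middle band, honouring the
strict inequalities in the group definitions ("percentile < 25",
"percentile > 50"). The same amyloid-positive-derived `q25` is applied to
amyloid-negative CI subjects to define the suspected LATE-only reference
group; amyloid-negative CI subjects above `q25` are labelled
`UNCLASSIFIED` rather than silently pooled anywhere.

Assumptions worth keeping in mind: the adjustment regression is assumed
transportable from CU to CI subjects (it removes normal-aging structure,
not disease effects), and the quartile cut-offs are cohort-relative —
absolute thresholds do not transfer across scanners or segmentation
pipelines.

## Imaging features

* **Asymmetry index** `|L − R| / (L + R) × 200`: percent-scale, in
  `[0, 200]`, symmetric in its arguments and invariant to common scaling.
  Raw (unadjusted) volumes are used: asymmetry is a within-subject
  contrast, so between-subject covariates cancel.
* **ERC/PHC thickness ratio**: entorhinal over parahippocampal cortical
  thickness; lower values indicate the anterior-predominant medial temporal
  thinning associated with TDP-43.
* **Amyloid positivity**: tracer-specific SUVR thresholds, ≥ 1.11
  (florbetapir) and ≥ 1.08 (florbetaben). Unknown tracers are an error;
  there is no defensible default threshold.
* **Tau-MaX**: per region of interest, a two-component unequal-variance
  Gaussian mixture is fitted cohort-wise to the tau-PET SUVRs (EM via
  mclust, whose model-based hierarchical initialisation is deterministic);
  the higher-mean component is pathologic. The subject-level measure is the
  pathologic-posterior-weighted magnitude summed over an ROI set,
  $\sum_r p_r \,\max(0, (SUVR_r - \mu_{neg,r})/\sigma_{neg,r})$, so extent
  enters through how many regions carry non-negligible posterior and
  magnitude through the standardized elevation. This is a documented
  variant of the extent-and-magnitude family of measures, not a claim of
  numerical equivalence with any specific published implementation; only
  its contracts (non-negativity, monotonicity in each SUVR, group ordering)
  are relied on downstream. A mixture fit that fails or degenerates is
  flagged and its region contributes posterior zero rather than a silent
  guess.

## Mass-univariate inference on meshes

Surface and voxel analyses are re-expressed graph-generically: data live on
an undirected connected mesh graph, which desk-scale lattices, rings and
random graphs stand in for. Per-vertex group contrasts use ordinary least
squares with a shared design matrix. Threshold-free cluster enhancement
(TFCE) integrates component extent and height,
$\mathrm{TFCE}(v) = \sum_h e_v(h)^{E} h^{H} \, dh$, with defaults
`E = 0.5`, `H = 2`, `dh = 0.01` (in t-statistic units; maps are used as raw
t values, without variance smoothing). Negative values are enhanced on the
negated map and returned signed, since directional comparisons are
reported. The implementation processes thresholds in descending order with
an incremental union-find (compiled, since the permutation workload is the
hot loop); an isolated peak of height $h_0$ has the analytic limit
$h_0^3/3$ as $dh \to 0$, which the tests use as an anchor.

Family-wise error control uses the permutation distribution of the maximum
absolute TFCE score across vertices, $p_v = (1 + \#\{b: \max_u
|\mathrm{TFCE}_b(u)| \ge |\mathrm{TFCE}_{obs}(v)|\})/(B + 1)$. Nuisance
covariates are handled by Freedman–Lane residual permutation: reduced-model
residuals are permuted and the reduced fit added back before recomputing
the full-model contrast. This is a documented choice — tools differ in
their permutation schemes for covariate-adjusted contrasts, and no
bit-equivalence with any of them is claimed. For pure two-group designs
whose distinct label assignments number at most `n_perm`, exact enumeration
replaces Monte Carlo sampling, making small-design p values exact.

Longitudinal maps fit, per vertex,
`thickness ~ time + group + covariates + time:group + (1 | subject)` and
report the time-by-group interaction with its Wald normal p value
(mixed-model degrees-of-freedom corrections matter little at the visit
counts simulated here, and the per-vertex loop favours the cheap
approximation); multiplicity is handled by Benjamini–Hochberg FDR.
Non-converged vertices are flagged missing, never zero-filled.
Cross-sectional input to the longitudinal model is a contract violation
and errors out.

## Cognitive trajectories

Domain composites (memory, executive, language; SD-units) are modelled as
`score ~ time + group + age + education + global Tau-MaX + PET interval +
time:group + (1 + time | subject)`, with pairwise slope contrasts via
estimated marginal trends (Satterthwaite degrees of freedom). A singular
random-effects fit triggers a flagged refit with a random intercept only —
a standard, transparent fallback.

The SILA (sampled iterative local approximation) trajectory model estimates
a biomarker-versus-time curve from short longitudinal windows: per subject,
adjacent-visit rates `Δvalue/Δage` are assigned to the midpoint value;
the rate-versus-value relation is smoothed by robust LOESS (symmetric
family, span 0.5, two robustness passes, local-quadratic — a local-linear
fit measurably attenuates the peak of curved rate profiles); smoothed rates
are floored at `min_rate = 1e-4` units/year so the curve is strictly
monotone and invertible; and the rate field is Euler-integrated with
`dt = 0.05` years. Integration runs outward from the positivity threshold
in both directions, which anchors time 0 exactly at the threshold and
bounds the traversal of floored-rate plateau regions; it is equivalent to
integrating up from the minimum observed value and shifting, to the O(dt)
accuracy already implied by Euler's method. Rate construction from adjacent
visits (rather than windowed binning) is chosen for determinism and
small-sample stability; tolerances on anything downstream of the curve
include O(dt) terms.

Time-from-positivity lookups invert the monotone grid by linear
interpolation; values beyond the grid extend linearly at the terminal slope
but are capped at `extrapolation_years` beyond the grid (3 years for tau,
5 for cognition) and flagged. Subject onset ages anchor on the final event
point — the last observation, the natural reading when visits are ordered —
and are optionally truncated to the observed age range of the fitting
sample, again flagged. Cognitive trajectories are modelled on negated
scores (the model associates higher values with greater severity), with the
impairment threshold at 1.5 SD below the CU mean, negated. Anchoring
cognition to estimated tau-onset age is only offered where onsets exist;
requesting it for a group without tau positivity is an explicit error, not
an extrapolation.

## Autopsy validation

The autopsy stage restricts to intermediate/high AD neuropathologic change,
applies the main-cohort cut-offs, excludes the Q2 band, and counts LATE-NC
(TDP-43 stage ≥ 1) by quartile group. The odds ratio is the conditional
maximum-likelihood estimate under Fisher's noncentral hypergeometric model
with the probability-ordering two-sided p value — `stats::fisher.test`'s
conventions, which the tests pin against exhaustive enumeration. ROC
analysis uses the convention that lower adjusted HV is more suspect
(positive = score ≤ threshold), so AUC > 0.5 means enrichment; AUC is
computed by the trapezoid rule over the tie-grouped operating points, which
equals the midrank Wilcoxon identity. The Youden optimum breaks ties toward
the more specific threshold, matching the framework's stated preference for
high-confidence selection over sensitivity.

## The synthetic cohort generator

The generator is first-class, tested code: it produces the statistical
structure the downstream stages assume, with one RNG stream per output
table derived from the master seed so adding a table never perturbs the
others. Defaults reproduce the published cohort structure: group sizes
193/115/20/58 (Aβ−CU, AD+sLATE−, AD−sLATE+, AD+sLATE+), adjusted-HV means
(SD) 3282 (361) / 3194 (241) / 2075 (292) / 2237 (229) mm³, and global
Tau-MaX 0.4 (1.7) / 12.7 (18.6) / 2.5 (3.9) / 30.4 (28.2), with the
temporal meta-ROI analogues. Adjusted-scale HV targets are drawn per group
and mapped to raw hemisphere volumes through planted coefficients
(`beta_age = −25` mm³/year, `beta_icv = 1.5e−3` mm³/mm³ — values in the
range expected for normal aging and head-size scaling), so the CU
regression recovers the planted structure and the adjusted values recover
the configured means. Asymmetry is injected multiplicatively,
`(1 ∓ δ/2)` on a common base with δ half-normal at a group-specific mean
(higher in the suspected-LATE groups); the smaller hemisphere carries the
adjusted-scale target so the minimum-hemisphere convention sees the
configured distribution. Because no group-level asymmetry-index values are
published, the asymmetry scales (3–10%) are conventions chosen to be
anatomically plausible, not calibrated numbers.

Tau-MaX columns are Gamma-distributed with the configured mean and SD —
non-negative and right-skewed, which a truncated normal at a near-zero mean
could not deliver without biasing the mean. Per-ROI tau SUVRs are
two-component mixtures (non-pathologic N(1.0, 0.08); pathologic
N(μ_g, 0.25)) whose pathologic weight increases with the configured group
burden, giving the mixture stage identifiable structure and preserving the
group ordering in the computed measure. Cognitive scores follow
`intercept + slope·t + b0 + b1·t + ε` with per-group intercepts and slopes
chosen to reproduce the qualitative published pattern (suspected-LATE
groups lower and faster-declining, most markedly in memory); the
random-effect SDs (0.30 intercept, 0.06 slope) and residual SD (0.25) are
typical magnitudes for standardized composites. The autopsy arm draws
LATE-NC status from a logistic link on standardized negated adjusted HV
whose intercept and slope are solved numerically (quadrature over the
truncated-normal quartile regions plus root finding, cached) so the
population Q1 versus Q3–Q4 odds ratio equals the configured
`enrichment_odds` (13.8 by default) at a marginal prevalence of 0.48.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: measurement error and scanner/protocol effects on
volumes; informative dropout and irregular visit schedules; non-Gaussian
heavy-tailed cognitive residuals; spatial covariance structure on meshes
beyond graph adjacency; correlation between tau burden and atrophy within
subject; and the selection processes of an observational cohort. Results on
synthetic data demonstrate internal correctness of the machinery, not
clinical validity.

## Numerical choices and degenerate inputs

* Quantiles: type-7 linear interpolation, configurable; boundary ties go to
  the excluded band.
* GMM: `mclust` with deterministic initialisation; degenerate or failed
  fits flagged, posteriors treated as 0 downstream.
* Permutation p values: `(1 + k)/(B + 1)` for Monte Carlo (valid by
  construction), exact enumeration for small two-group designs; `1e-12`
  slack in max-statistic comparisons absorbs floating-point noise in
  recomputed statistics.
* SILA: `min_rate` floor guarantees invertibility; curve grids insert the
  threshold point exactly; empty observation lists, all-singleton subjects,
  and degenerate rate samples are errors, not NaN propagation.
* Mixed models: singular fits refit with intercept-only random effects,
  flagged; non-convergence at a vertex yields missing values.
* Fisher estimates: OR is `Inf`/`0` for zero off-diagonal/diagonal products,
  matching the conditional-MLE limit.
* Missing hemisphere volumes, missing amyloid status on CI subjects, and
  missing LATE-NC stages are explicit, subject-naming errors — the
  stratification never silently falls back.

## Problem sizes

The test-suite and acceptance runs use desk-scale versions of each
analysis, chosen so the whole suite exercises every stage end to end:
meshes of 6–50 vertices, 500 permutations with 100–200 pure-noise
replicates for FWER calibration, SILA with 200 subjects × 4 visits,
mixed-model recovery with 80 subjects × 5 visits, quartile-oracle sweeps
over 1000 random vectors, and autopsy round-trips at n = 2000 × 100
replicates. These sizes give Monte-Carlo error comfortably below the
tolerances being asserted.

## Known limitations

The Tau-MaX construction is a documented stand-in for a measure whose exact
published form is external to this package. The permutation scheme for
covariate-adjusted contrasts (Freedman–Lane) is one of several defensible
choices. Cut-off values are cohort-relative by design; the package
deliberately does not ship "the" thresholds. The two-threshold
indeterminate-zone variant of the classifier is out of scope, as is any
image-level processing (segmentation, registration, SUVR map computation):
all inputs are tabular or mesh-level.
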