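---
title: "Methods: individual-level default mode network failure analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-level default mode network failure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netfailq)
```

# The problem

In Alzheimer's disease, functional disruption of the default mode network
(DMN) is thought to be a feature shared across clinical phenotypes, while
focal neurodegeneration is phenotype-specific: inferior parietal and
parieto-frontal thinning in the dysexecutive presentation, hippocampal and
temporal atrophy in the amnestic one. Quantifying these at the *individual*
level needs (i) a scalar functional biomarker robust enough to compute per
subject, and (ii) an age-normative reference against which a single patient
can be placed.

`netfailq` implements both halves: the **network failure quotient (NFQ)**
computed from resting-state component time courses, and **age-normative
location-scale quantile curves** that convert any biomarker value into an
age-adjusted Z-score and centile rank. Around these sit motion quality
control, structural biomarker derivation, group statistics and causal
mediation analysis, plus a synthetic-cohort generator so that every stage is
testable without restricted cohort data.

# The NFQ

The DMN is decomposed into posterior (pDMN), ventral (vDMN), anterior
ventral (avDMN) and anterior dorsal (adDMN) subsystems, each represented by
one or more spatial components of an atlas. For a cleaned session, the
connectivity of a subsystem pair is the **median Pearson correlation over
all cross pairs** of component time courses. The NFQ is

$$\mathrm{NFQ} = \frac{m(\mathrm{pDMN},\mathrm{avDMN}) +
m(\mathrm{pDMN},\mathrm{adDMN})}{m(\mathrm{pDMN},\mathrm{vDMN})},$$

higher values indicating greater disruption of posterior DMN connectivity
relative to its ventral anchor. A configuration switch
(`computeNFQ(variant = "literal")`) provides the variant with
$m(\mathrm{pDMN},\mathrm{vDMN})$ in the numerator as well; the two differ
only by a constant 1 when the denominator pair is shared. We default to the
avDMN numerator because the atlas explicitly carries an anterior-ventral
subsystem and the literal variant makes the first numerator term cancel
with the denominator; both remain available and the numerator/denominator
pair sets are fully configurable. Ratios with a denominator below
`eps = 1e-6` in absolute value are flagged undefined (`NA`) rather than
propagated.

Medians are taken over component pairs of the static per-session
correlation matrix; no sliding-window aggregation is used. Fisher
transformation before the median is deliberately not applied (median of
r), matching the construct of a median connectivity.

# Per-session processing

For each session the pipeline applies, in order:

1. **Frame trimming** (`trimInitialFrames`, default 10 frames) for signal
   equilibration.
2. **Noise ROI** (`buildNoiseRoi`): union of CSF and WM probability maps
   thresholded at 0.9 (inclusive `>=`: boundary behaviour must be fixed
   somewhere and the deterministic choice is tested), eroded by two
   one-voxel 6-connected passes.
3. **aCompCor noise components** (`noiseComponents`): top six principal
   component time series of the masked voxel-by-time matrix, voxels
   centred over time, ordered by explained variance.
4. **Nuisance matrix** (`buildNuisanceMatrix`): six motion parameters,
   their backward-difference first derivatives (first row zero, a
   length-preserving convention) and the noise components; columns
   centred.
5. **Simultaneous band-pass and nuisance regression**
   (`bandpassAndRegress`): linear detrend, then one zero-phase band-pass
   operator applied identically to data and nuisance, then least-squares
   removal of the filtered nuisance, then per-column variance
   normalization. Filtering both sides identically avoids spectral
   misspecification of the motion artefact; the output is exactly
   orthogonal to every filtered nuisance column.
6. **Smoothing** (volume mode, `smoothVolumes`): separable Gaussian with
   $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in mm, converted by
   voxel size.
7. **Dual (spatial-temporal) regression** (`dualRegression`): each frame's
   voxel vector regressed jointly on all atlas maps (plus intercept; maps
   centred over in-brain voxels). The joint solve matters when maps
   overlap: a per-map univariate projection is contaminated by shared
   support, and the implementation is tested against an explicit
   normal-equations solve.
8. **Subsystem connectivity and NFQ**, then **within-subject averaging**
   across QC-passing sessions (`averageSessions`), recording the number
   of sessions used and never fabricating values for subjects with no
   passing session.

**Filter realization.** The band-pass is a frequency-domain mask on the
discrete Fourier bins within 0.009–0.08 Hz, the realization used by the
standard resting-state band-pass tools. It is exactly zero-phase and
idempotent — re-filtering an already band-limited series is the identity —
which keeps the analysis filter from distorting structure planted by the
synthetic generator in the same band. The contract that matters (and that
the tests pin down) is: an in-band 0.04 Hz sinusoid retains more than 95%
of its variance, a 0.2 Hz sinusoid keeps less than 10%, and data and
regressors pass through the identical operator.

**Session consistency** is summarized by the intra-class correlation
across sessions (`sessionICC`). We use the two-way random-effects,
absolute-agreement, single-measure form ICC(2,1), the standard choice for
agreement of repeated measurements across sessions; a consistency form
ICC(3,1) is an option.

# Motion quality control

Frame-wise displacement is Power-style:
$\mathrm{FD}_t = |\Delta x| + |\Delta y| + |\Delta z| +
r(|\Delta \alpha| + |\Delta \beta| + |\Delta \gamma|)$ with a 50 mm
rotational radius, rotations in radians, and $\mathrm{FD}_1 = 0$. Two
exclusion rules are implemented:

* **FD threshold**: a scan is retained iff its mean FD is strictly below
  0.25 mm. The summary statistic (mean/median/max) is configurable; mean
  is the default. Per-frame censoring is out of scope.
* **Gross motion**: exclusion when any translation exceeds 2 mm
  peak-to-peak or any rotation exceeds 2 degrees peak-to-peak. Rotations
  are compared in degrees — a 2-radian threshold would be physically
  implausible.

An excluded scan carries exactly one triggering rule (FD takes
precedence). The FD filter is monotone in its threshold, and both
boundary conventions are tested.

# Structural biomarkers

`metaRoiThickness` averages bilateral thickness over the six
Alzheimer-signature parcels: entorhinal, inferior temporal, middle
temporal, inferior parietal, fusiform, precuneus (12 values, unweighted).
The signature set is sometimes described with a "medial temporal" region;
the Desikan-Killiany parcellation has no such parcel and the validated
composite uses middle temporal, so that is the default mapping (and it is
overridable via the `regions` argument). `inferiorParietalSum` is the
left + right inferior parietal thickness.

Hippocampal volumes are corrected for intracranial volume with the
**residual method** by default: `adjusted = volume - beta * (icv -
meanICV)` with `beta` fitted by OLS on the *normative* reference only.
This preserves volume units, leaves a subject at the reference mean ICV
unchanged, preserves the reference-cohort mean, and removes the ICV
correlation; the ratio method is available by option since the choice
between the two is a genuinely open one. Patients never enter the
reference fit.

# Normative modelling and scoring

For each biomarker, `fitNormative` models the normative cohort as
$y \mid \mathrm{age} \sim N(\mu(\mathrm{age}), \sigma^2(\mathrm{age}))$
with penalized B-spline curves for $\mu$ and $\log$-type-linked $\sigma$,
fitted by penalized maximum likelihood (REML smoothing) via the `mgcv`
location-scale engine. The penalty orders are chosen so the
infinite-smoothing limit is interpretable: order 2 for the location
(limit: linear trend) and order 1 for the scale (limit: homoscedastic) —
so "smoothing to infinity" recovers ordinary least squares, a property
the tests verify to $10^{-3}$.

Candidate basis dimensions (default `k = 4, 6, 9`, spanning roughly 2–8
effective df per curve) are each scored with the global deviance
($-2\log L$), AIC and the Schwarz Bayesian criterion; the winner is
selected by **SBC** by default, with all three reported, since SBC is the
most conservative of the three for moderate cohort sizes and the
selection criterion is exposed as an option. The family is restricted to
the normal distribution; the scaffolding is extensible but skew/kurtosis
families are out of scope.

Scoring maps a subject to $z = (y - \hat\mu(\mathrm{age})) /
\hat\sigma(\mathrm{age})$ and a centile rank $\Phi(z)$ **rounded to two
decimals** (the unrounded value is kept alongside). The rounding is
load-bearing for threshold counting: "above the 90th centile" means the
rounded rank is `>= 0.90`, so a printed 0.90 counts, and "second centile
or lower" means `<= 0.02`. Ages outside the fitted support are scored
with an `extrapolated` flag rather than refused. Centile curves are
$\hat\mu + \Phi^{-1}(c)\,\hat\sigma$ for the default centile set 0.4, 2,
10, 25, 50, 75, 90, 99, 99.6 per cent.

Diagnostics (`wormDiagnostics`) use quantile residuals (equal to the
Z-scores under the normal family): moments, worm-plot (detrended Q-Q)
coordinates with a pointwise 95% band, and flags when the residual mean
leaves $\pm 0.1$, $|$skewness$| \ge 1$ or kurtosis leaves $3 \pm 1$.
Models serialize to JSON as dense age grids of $\mu$ and $\log\sigma$
plus scores; the reloaded grid backend scores identically to
interpolation accuracy.

# Group statistics and mediation

Simple associations are standardized simple regressions (coefficient =
correlation) with Benjamini–Hochberg FDR over the association family;
markedly skewed reaction-time scores (TMT-B style) use Spearman's rho
with a Fisher-transform CI. The multivariate model is plain OLS with all
predictors, with rank deficiency reported by aliased column names. Group
comparisons use one-way ANOVA with Tukey–Kramer HSD (singleton groups
excluded from the post hoc stage), Cohen's D with a noncentral-t CI
(thresholds 0.3/0.5/0.8 for small/medium/large), and ROC AUC by the rank
statistic with half credit for ties and a DeLong CI (bootstrap option).
A+/T+ classification applies strict thresholds: amyloid SUVR > 1.42, tau
SUVR > 1.23.

`fitMediation` implements the **quasi-Bayesian Monte Carlo**
approximation for the linear no-interaction mediation model: OLS fits of
`M ~ X (+cov)` and `Y ~ X + M (+cov)`, parameter draws from each fit's
asymptotic multivariate normal, and per draw ACME $= a\,b$, ADE $= c'$,
total $=$ ACME $+$ ADE, proportion $=$ ACME/total. Point estimates are
medians of draws (mean optional — with means the additivity
ACME + ADE = total is exact), CIs are percentile intervals, p-values are
two-sided simulation tail probabilities floored at $2/n_{\mathrm{sims}}$.
The description of this estimator mixes "bootstrap" and "quasi-Bayesian"
vocabulary in common usage; we read it as the parametric Monte Carlo
algorithm and provide case-resampling bootstrap as an explicit option.
Draws with a numerically zero total effect are flagged and excluded from
the proportion summary, with the flagged fraction reported. No
exposure–mediator interaction is included by default.

# The synthetic cohort: what it emulates

`generateCohort` draws a normative group plus dysexecutive (dAD),
amnestic (AD) and control groups:

* **Ages**: uniform over 36–100 years for the normative group (no
  published per-year density exists to calibrate against; a sampler hook
  allows any density), and Gaussian ages centred at 59.5 (dAD), 73 (AD)
  and 65 (controls), matching the phenotypes' typical onset ordering.
* **Biomarker values**: true age curves $\mu^*(\mathrm{age})$ (quadratic)
  and $\sigma^*(\mathrm{age})$ (linear) per biomarker; each subject's
  true Z is the group shift plus a unit-SD individual deviation, and the
  value is $\mu^* + z\,\sigma^*$. Patient shifts are specified in
  normative-SD units, which makes planted Z-score tables directly
  comparable to recovered ones. The default shift table is the group-mean
  Z profile of the case-study phenotypes (dAD dominated by inferior
  parietal thinning at $-3.2$ SD with NFQ $+2.21$; AD dominated by
  meta-ROI and hippocampal loss with NFQ $+1.76$).
* **NFQ curves**: location $1.05 + 0.012(\mathrm{age}-35) +
  2\times10^{-5}(\mathrm{age}-35)^2$, scale $0.45 + 0.001(\mathrm{age}-35)$.
  The scale is deliberately large relative to the per-session measurement
  noise of a 478-frame acquisition (see below) so that the four-session
  average retains the high session-to-session consistency reported for
  this class of acquisition, and the slope gives a standardized age
  association in the mid-0.4s under the uniform age density.
* **ICV**: $N(1.45\times10^{6}, 1.3\times10^{5})$ mm³; raw hippocampal
  volumes carry a planted ICV component (slope 0.0025) that the residual
  correction must remove.
* **Cognition and mediation**: left/right hippocampal Z-scores share a
  common factor $h$; the NFQ Z receives $a\,h$ (default $a = -0.25$) and
  the recall total receives $b\,z_{\mathrm{NFQ}} + c'\,h$ (defaults
  $b = -4$, $c' = 5$, noise SD 8), planting a partial mediation
  structure. The TMT-B score is log-normal (right-skewed by
  construction, motivating the Spearman default), MoCA declines mildly
  with age and severely with either patient phenotype, and patient SUVRs
  straddle the positivity thresholds from the correct side.
* **Scans**: `simulateScan` filters white noise through the same
  band-pass operator the analysis uses, whitens the realized covariance,
  and mixes to a target component correlation matrix by its Cholesky
  factor. `subsystemCorrMatrix` maps a subject's true NFQ to such a
  matrix (pDMN–vDMN fixed at 0.3, the two numerator pairs at
  `nfq * 0.3 / 2`, remaining cross pairs 0.1, within-subsystem 0.5, two
  components per subsystem), projecting to the PSD cone and recomputing
  the implied NFQ if necessary, so the stored ground truth always matches
  the matrix actually used; the construction is exactly consistent up to
  NFQ values around 3.9.
* **Motion**: a bounded random walk whose FD stays below the baseline
  amplitude (0.1 mm) at every frame, plus optional exponential-magnitude
  translation spikes at a configurable per-frame rate — giving direct
  control over FD exceedances for QC testing.
* **Volume mode**: Gaussian-blob maps (two per subsystem) on a
  desk-scale grid (default 30×36×30 at 2.9 mm), voxel noise, nuisance
  signals injected into a CSF/WM corner region (from which
  `buildNoiseRoi` derives the noise ROI) and a motion-coupled artefact
  spread over the brain.

**Exact covariance matching.** Band-limited noise at TR 0.8 s carries
only ~54 in-band Fourier degrees of freedom per 478-frame session, so
correlations mixed only "in expectation" would wander by ~0.1 per pair.
The generator therefore whitens the realized covariance before mixing
(the `empirical = TRUE` convention of multivariate normal simulators),
making the planted matrix exact per realization; convergence behaviour
can still be studied with `empirical = FALSE`. When a requested series is
too short for the band to supply enough degrees of freedom, the generator
falls back to expectation-level mixing with a warning.

**What is deliberately not emulated**: haemodynamic response shapes,
scanner artefact physics, spatial autocorrelation of voxel noise,
non-Gaussian biomarker distributions, site effects, and the true age
density of any real cohort. Passing tests therefore demonstrate that the
*pipeline machinery* recovers planted structure under its own
assumptions, not that those assumptions hold in any real dataset.

# Numerical choices and degenerate inputs

* Probability-map thresholding is inclusive (`>=`); erosion treats
  out-of-grid neighbours as background.
* Rank-deficient nuisance matrices drop dependent columns with a warning;
  collinear atlas maps are an error naming the offending components.
* Zero-variance component courses are excluded from connectivity with a
  warning; a subsystem pair with no usable component pair is an error.
* The NFQ denominator guard is $10^{-6}$; undefined sessions are dropped
  from the within-subject average with a warning, and subjects with no
  usable session are reported missing, never imputed.
* Location-scale fitting errors out when there are fewer distinct ages
  than spline degrees of freedom, and warns below 50 normative subjects.
* Zero ICV variance in the reference falls back to the ratio method with
  a warning; references under 10 subjects warn.
* Mediation draws with $|$total$| <$ machine tolerance are excluded from
  the proportion and counted.

# Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make sampling
tolerances meaningful while staying desk-scale: normative-curve recovery
at n = 1000; the dual-regression oracle on the full 30×36×30 grid at 100
frames; NFQ round trips at 2000 post-trim frames; mediation recovery at
n = 5000 with 10,000 draws and coverage at 200 replicates of n = 300; the
end-to-end run at 500 normative + 10 dAD + 8 AD + 5 control subjects with
four 488-frame sessions each in time-course mode. The full-size
volumetric study (724 subjects, four sessions of 30+ mm³ voxel grids) is
not needed to validate any of the implemented operations.

# Known limitations

* Only the normal family is implemented for quantile curves; biomarkers
  with skewed normative distributions would need a transformation first.
* Time-course mode bypasses all volumetric operations; despiking,
  slice-timing, realignment and template registration are upstream of
  this package and are not re-implemented.
* The mediation module estimates the linear no-interaction model only;
  sensitivity analysis for unmeasured confounding is out of scope.
* Cross-sectional only: no longitudinal trajectory modelling.
* The per-session NFQ measurement noise implied by 478-frame sessions is
  substantial; single-session estimates should not be interpreted
  individually, which is why the pipeline averages across sessions and
  reports the number of sessions used.
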