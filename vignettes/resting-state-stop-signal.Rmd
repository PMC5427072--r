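---
title: "Linking resting-state local connectivity to stop-signal inhibition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking resting-state local connectivity to stop-signal inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restingstop)
```

# What this package computes

`restingstop` implements, end to end, an analysis that asks whether local
properties of spontaneous (resting-state) brain activity predict individual
differences in response inhibition. The behavioral side is the stop-signal
task: the participant responds to go stimuli and must withhold the response
when a stop signal sounds after a variable stop-signal delay (SSD). Under the
horse-race model, an independent go process and stop process race; the
response is inhibited iff the stop process finishes first. The latency of the
stop process — the stop-signal reaction time, SSRT — is not observable
directly and is estimated here by the median method:

$$\mathrm{SSRT} = \mathrm{median}(\mathrm{go\ RT}) - \mathrm{median}(\mathrm{SSD}),$$

valid because the adaptive staircase holds stop-success probability near 50%.

The imaging side computes two voxelwise maps of local functional
connectivity from 4-D BOLD-like series:

* **ReHo** (regional homogeneity): Kendall's coefficient of concordance
  $W$ of a voxel's time series with its 26 neighbours (27-voxel cluster),
  computed on band-passed (0.01–0.08 Hz) data. With $K$ series of length
  $n$, rank sums $R_i$ per time point and $\bar R = K(n+1)/2$:
  $$W = \frac{\sum_i R_i^2 - n \bar R^2}{K^2 (n^3 - n)/12}.$$
* **fALFF** (fractional amplitude of low-frequency fluctuations): the sum of
  FFT amplitudes (square root of the power spectrum) over 0.01–0.08 Hz
  divided by the sum over 0.01–0.25 Hz, computed on detrended, *unfiltered*
  data.

Each map is correlated voxelwise with SSRT across subjects — directly, and
partially with age removed — thresholded at the critical $r$ for
$\alpha = 0.005$, cluster-corrected by a Monte-Carlo minimum extent, and
finally combined across the two metrics by a max-$r$ conjunction: at each
voxel the conjunction statistic is $\max(r_{\mathrm{ReHo}},
r_{\mathrm{fALFF}})$, the *weaker* negative evidence, so a voxel survives a
negative threshold only if both maps do. This is the minimum-statistic
conjunction logic adapted to negative correlations.

Because real resting-state acquisitions are outside the package's scope, a
synthetic-cohort generator produces behavioral data and 4-D volumes with
*known* couplings, so every stage of the pipeline can be verified against
ground truth.

# The task engine

Trial layout follows the standard design: five blocks of 140 trials, 40 of
them stop trials, shuffled uniformly within block; inter-stimulus intervals
are uniform on 1300–4800 ms (bookkeeping only — the race model does not use
them). Stop trials alternate strictly between two interleaved staircases
starting at SSD 150 and 350 ms. The interleaving rule is a design choice: the
convention ("one of two interleaved staircases") does not fix the assignment,
and strict alternation is deterministic and testable. After a successful stop
the relevant SSD rises 50 ms, after a failed stop it falls 50 ms, clamped to
0–800 ms; this drives stop success toward 50% regardless of the subject's
parameters.

Go RTs are ex-Gaussian ($\mu$, $\sigma$, $\tau$), the standard parametric
family for RT data; defaults $\mu = 550$, $\sigma = 60$, $\tau = 127$ ms give
a mean go RT of 677 ms. The stop latency is a per-subject constant: the
median-method estimator targets a central latency, and a deterministic stop
process makes recovery tests sharp (an estimate within a few ms of the
constant is unambiguous evidence the estimator works). Go omissions (default
2.07%) produce no response; choice errors (default 11.24%) carry an RT but
are excluded from the go-RT median as incorrect. These defaults reproduce a
go accuracy near 87%.

On a simulated subject the estimator recovers a 250-ms true SSRT to within
20 ms with 200 stop trials, and the staircase's long-run stop-success rate
sits within 2 points of 50%.

# The synthetic cohort

`sample_cohort()` draws ages from a truncated normal (mean 59.38, range
40–77) and true stop latencies with mean 300 ms, between-subject sd 80 ms,
and a configurable age coupling (default population $r = 0.22$). The noise
component of the age–SSRT link is orthogonalized against age within the
sample so the realized correlation equals the configured one rather than
fluctuating with the draw. Each subject is then run through the full task to
obtain an *estimated* SSRT; all downstream couplings are driven by the
estimated score's within-cohort z-score, which keeps the injected
brain–behavior correlation interpretable at face value.

Volumes live on a 24×24×24 grid of 2-mm voxels with 240 time points at
TR = 2 s — small enough that the whole pipeline runs in seconds per subject
while keeping the temporal parameters of a typical acquisition. The in-brain
mask is a central sphere (about 4850 voxels). In-mask background voxels are
unit-variance white noise; out-of-mask voxels are exactly zero. Four
disjoint spherical regions (radius 3 voxels, 123 voxels each) carry the
ground-truth effects:

* **synchrony**: each member voxel is
  $\sqrt{\rho}\,c(t) + \sqrt{1-\rho}\,p_v(t)$ with a region-shared $c$ and
  voxel-private $p_v$. Both components are *broadband white*, so the voxel
  spectrum — hence fALFF — is untouched while ReHo rises with $\rho$. (A
  band-limited shared signal would leak the synchrony effect into the fALFF
  map and break the single-effect design.)
* **amplitude**: $\bigl(p_v(t) + a\,\ell_v(t)\bigr)/\sqrt{1+a^2}$ with
  voxel-private band-limited (0.01–0.08 Hz) $\ell_v$; fALFF rises with $a$
  while local synchrony is untouched.
* **both**: a region-shared *band-limited* component with variance fraction
  $w$ — sharedness raises ReHo and its band concentration raises fALFF, so
  one latent scalar drives both metrics jointly, which is exactly what a
  conjunction analysis should detect.
* **age_only**: the "both" construction driven by the subject's age z-score
  instead of SSRT.

Band-limited components are built by zeroing FFT bins outside the passband
of white noise — simple, and exactly controllable.

## Effect-size calibration

The latent scalar of a region follows an affine link in the driving z-score,
clipped to its valid range:
$\mathrm{latent} = \mathrm{clip}(\mathrm{base} + \mathrm{slope}\cdot
\mathrm{sign}\cdot z + \mathrm{noise\_sd}\cdot\varepsilon)$. The
$\varepsilon$ term is per-subject biological variability unrelated to
behavior, and it is what sets the population brain–behavior correlation: at
240 time points both metrics estimate their voxel value almost noiselessly,
so without $\varepsilon$ any nonzero slope would give $|r| \to 1$. The
defaults use noise-to-slope ratios that put the per-voxel population $|r|$
near 0.5 (peak values around 0.5–0.57 when measured on a 150-subject
cohort), the plausible regime for reported peak correlations of this kind —
post-threshold peak values in small samples are upward-biased, so the
generating correlation is deliberately kept moderate. Region borders are
weaker than region cores in the ReHo map by construction: a border voxel's
27-neighbourhood mixes in background voxels, diluting concordance. The
same moderation means that at $n = 40$ and $\alpha = 0.005$ (critical
$|r| = 0.435$) recovery sits deliberately near the detection boundary —
cohorts at this effect size are *detectable but not trivially so*, which is
the informative regime for a calibration study.

# Preprocessing

The default order follows the convention of smoothing before filtering:
6-mm FWHM isotropic Gaussian smoothing (separable zero-padded convolution,
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$, no mask renormalization), then
frequency-domain band-pass. ReHo is computed on the smoothed, band-passed
series; fALFF on the smoothed, detrended, unfiltered series (its denominator
needs the full 0.01–0.25 Hz range). The ReHo-method literature often
computes Kendall's W on *unsmoothed* data — smoothing mechanically inflates
neighbourhood concordance — so `pipeline_config(reho_on_smoothed = FALSE)`
provides that alternative (ReHo first, smooth the map afterwards); the
default keeps the smoothing-first order. The band-pass is an ideal
(hard-edged) FFT filter: stop-band bins are zeroed exactly, the passband is
untouched, and the DC bin is always removed. That choice makes the spectral
examples exact and is idempotent by construction. Detrending removes the
least-squares line per voxel.

# Statistics

Voxelwise association uses the Pearson correlation across subjects; the
age-adjusted analysis uses the first-order partial correlation
$r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$
with $df = n - 3$ (versus $n - 2$ for the full correlation). The voxel
threshold is the critical $r$ from the $t$ transform,
$r_{\mathrm{crit}} = t / \sqrt{t^2 + df}$ at the upper-tail quantile of
$\alpha/\mathrm{tails}$; the default is two-tailed, the usual convention
even when only negative correlations are reported. For $\alpha = 0.005$,
$df = 70$ this gives 0.327 two-tailed (0.302 one-tailed); analyses of
72-subject samples conventionally quote a rounded 0.31 for this setting, a
figure that matches neither tail convention exactly, so the package always
computes the threshold from $(\alpha, df, \mathrm{tails})$ rather than
hard-coding a printed value.

Cluster-extent correction is a Monte-Carlo estimate in the AlphaSim style:
each iteration fills the mask with white Gaussian noise, smooths at the
analysis FWHM (noise is smoothed with the analysis kernel rather than a
residual-estimated smoothness — the pipeline has no smoothness-estimation
step), standardizes within the mask, applies the two-tailed voxel threshold,
labels clusters, and records the maximum cluster size; $k_{\min}$ is the
smallest extent whose null exceedance probability is at most the corrected
$\alpha$. "p < 0.005 corrected" is read as voxel-level $\alpha = 0.005$ with
extent correction at corrected $\alpha = 0.05$ — the standard reading —
and both knobs are explicit configuration. Connectivity defaults to
26-neighbour (the convention for r-map clustering; it is recorded in every
sidecar). The null is thresholded two-tailed even though results are
reported on the negative side, matching the symmetric null; one-sided
application of a two-tailed $k_{\min}$ is slightly conservative. Voxels with
undefined statistics propagate as undefined and can never survive
thresholding.

The conjunction map takes the voxelwise maximum of the two *unthresholded*
parent r maps (full with full, age-partialled with age-partialled — never
mixed), is thresholded at the same critical $r$ as its parents, and is
extent-corrected with a Monte-Carlo null recomputed on the same mask and
FWHM — with identical inputs and seed this equals the parent-map null, and
the choice is logged. The df of a max-of-r statistic is not that of a single
correlation; by the minimum-statistic argument the parent threshold is
conservative for the conjunction, which is the accepted price of this
design.

# Numerical choices and degenerate inputs

* Ranking uses mid-ranks on ties without Kendall's tie-correction factor,
  matching the original ReHo formulation; synthetic data are continuous, so
  ties have measure zero. A constant series cannot be ranked and raises an
  error in `kcc()`; in `reho_map()` constant or missing neighbours are
  dropped ($K$ reduced), and voxels with usable $K < 2$ become undefined and
  are counted in a warning.
* Mask-edge neighbourhoods are truncated, never padded — padding would
  fabricate data.
* fALFF bins are half-open $[f_{\mathrm{low}}, f_{\mathrm{high}})$ on the
  FFT grid, DC excluded; a zero denominator leaves the voxel undefined.
* Maps are standardized by their within-mask mean before group correlation
  (the common convention; `standardize` toggles it, since either choice is
  defensible).
* `alphasim_kmin()` returns an explicit "unattainable" sentinel when no
  extent can reach the corrected level (e.g. voxel $\alpha = 1$);
  thresholding with an unattainable extent keeps nothing.
* All randomness flows from explicit integer seeds; per-subject volume
  seeds are drawn once in `sample_cohort()` and stored in the cohort table,
  so any volume can be regenerated in isolation.

# What the tests do and do not show

The test suite verifies the statistical primitives against independent
oracles (a first-principles Kendall's W, flood-fill clustering, FFT spectral
ratios, residualization-based partial correlation, a second direct
Monte-Carlo extent simulation) and the pipeline against the generator's
ground truth. The Monte-Carlo studies are sized for minutes-scale runs: the
null-calibration study uses 16 cohorts of 40 subjects on the default
24×24×24 scene, and the recovery studies use 20 seeds (joint-region
recovery, evaluated as the median Dice against truth) and 10 seeds
(age-region removal, with a strongly age-coupled configuration:
age–SSRT $r = 0.8$ and a deterministic age link). These sizes estimate
binomial fractions to roughly ±10 points, which is adequate for the
twice-nominal bounds they are compared against.

Passing these tests shows the chain — generation, preprocessing, maps,
correlation, extent correction, conjunction — is internally correct and
calibrated *on data satisfying the generator's assumptions*: stationary
Gaussian background, effects homogeneous within spherical regions, no head
motion, no physiological (cardiac/respiratory) noise, no scanner drift, and
volumes already aligned on a common grid (registration and slice-timing are
out of scope). Real resting-state data violate all of these to varying
degrees, so the tests validate the machinery, not the neuroscientific
conclusions one might draw from applying it.

# Known limitations

* The race model uses a constant stop latency; an integration-method SSRT
  or a stochastic stop process would be needed to study estimator bias under
  stop-latency variability.
* Correlation-map smoothness in the extent null is approximated by the
  analysis FWHM, not estimated from residuals; with strong intrinsic
  spatial correlation in real data the extent would be anti-conservative.
* The conjunction inherits the parents' critical $r$; no dedicated
  max-statistic null is computed.
* World coordinates use a toy MNI-like affine (origin at the grid centre);
  no atlas lookup is provided, so cluster tables report coordinates only.
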