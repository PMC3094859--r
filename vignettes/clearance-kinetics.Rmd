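---
title: "Quantifying radiolabel clearance from injected myocardium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radiolabel clearance from injected myocardium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectac)
```

## The problem

When radiolabeled cells (or, as a calibration experiment, free
In-111-tropolone) are injected into myocardium, the SPECT signal measured
over the following weeks mixes several processes: physical decay of the
nuclide, early mechanical washout of material that never lodged in the
tissue, slow leakage of label out of viable cells, and clearance of label
that has entered the interstitium (from dead cells or leakage). To use
In-111 activity as a quantitative marker of transplanted-cell viability,
these contributions must be separated. `spectac` implements that
separation end to end: volume-of-interest (VOI) time-activity curves from
dynamic SPECT, decay correction, biexponential washout decomposition,
heart-to-wholebody retention ratios from planar scans, nonparametric group
comparison, and a convolution-based compartment model that isolates the
viable-cell signal.

## Washout model

Decay-corrected myocardial activity after an intramyocardial injection is
described by

$$f(t) = a\,e^{-bt} + c\,e^{-dt}, \qquad b > d > 0,$$

with amplitudes normalized so $a + c = 100$\%. The short component
($T_{1/2}^s = \ln 2 / b$, fractions of an hour to a few hours) captures
the early mechanical loss of injectate through needle tracks and the
ventricular cavity; the long component ($T_{1/2}^l = \ln 2 / d$, hundreds
to thousands of hours) reflects leakage of protein-bound label from viable
tissue. Fitting is constrained nonlinear least squares on log-amplitudes
and log-rates (Levenberg–Marquardt), initialized by classic curve peeling:
the tail beyond 100 h (configurable) sets the long component, the early
residual sets the short one. Log-parametrization enforces positivity
without constrained optimizers, and peeling makes the start point
deterministic, so identical data always give identical fits.

Some injections wash out monoexponentially — the short component is simply
absent. The fitter falls back to a single exponential when any of three
criteria indicates an unsupported short component: the fitted short
fraction is below 1%, the rate ratio $b/d$ is below 5 (components
unresolvable on this schedule), or the delta-method confidence interval of
the short amplitude includes zero. The data only show that the phenomenon
occurs, not which rule produced it; these three express "unsupported" in
decreasing order of directness, and any of them triggering is reported in
the fit's `status`.

Weighting is unweighted by default. The `"poisson"` option applies inverse
counting variance: because decay correction multiplies late frames by
$2^{t/T_{phys}}$, their variance is inflated by the same factor, and the
correct weight is `raw / dc^2` when both columns are present. For TACs
with Poisson noise at realistic count levels this roughly halves the
median error on the rate constants and is the recommended setting for
noisy data.

## Viability model

The kinetic model views a unit of label starting inside viable cells as
flowing through two pools. Intracellular label is lost at rate
$k_{death} + C$, where $k_{death} = \ln 2 / T_{1/2}^{viab}$ is cell death
and $C$ is the leakage coefficient — loss of label from cells that remain
alive. Everything leaving the cells enters the myocardial interstitium,
which clears according to the debris impulse response function (DIRF),
taken as mono-exponential with half-life $T_{1/2}^{DIRF}$; the model
assumes interstitial label clears by DIRF regardless of how it arrived.
The measured signal is the sum:

$$M(t) = e^{-\lambda_i t} +
  \int_0^t \lambda_i e^{-\lambda_i \tau}\,
  e^{-\lambda_d (t - \tau)}\, d\tau,
  \qquad \lambda_i = k_{death} + C,\ \lambda_d = \ln 2 / T_{1/2}^{DIRF}.$$

`forward_model()` evaluates the closed two-exponential form when the rates
are distinct (with the $\lambda_i t\, e^{-\lambda_i t}$ limit at equal
rates) and offers a trapezoidal numeric convolution — FFT-accelerated on a
uniform grid refined 10x beyond the data spacing — both as a cross-check
and to support arbitrary sampled impulse responses. The two routes agree
to better than $10^{-6}$ relative on a 0.01 h grid over 0–100 h, and the
compartments conserve label to $10^{-9}$.

`invert_viability()` recovers $T_{1/2}^{viab}$ from a measured TAC with
$C$ and the DIRF half-life as known inputs. The curve amplitude is
profiled out analytically (the model is linear in initial activity), so
the search is one-dimensional bounded minimization over log half-life —
monotone and well conditioned, no multi-start needed. Estimates are only
meaningful inside a validity window: clearance faster than the DIRF lower
bound (20 h default) is indistinguishable from interstitial clearance, and
slower than the leakage upper bound from leakage itself. Two upper-bound
presets ship, 60 days (default) and 37 days; both figures are in
circulation for this model and the package deliberately surfaces the
choice rather than resolving it. Estimates outside the window, or pinned
at the search boundary (e.g. a flat TAC with $C = 0$), return
`valid = FALSE` with an explicit status.

The DIRF half-life default of 18 h is a configuration value, not model
math: it is the value consistent with a viable-to-debris clearance ratio
near 79 given the combined-group mean long half-life of ~1434 h in the
packaged reference table. Sites with a measured DIRF should pass their own
value.

## VOI analysis and retention ratios

The VOI is defined once, on the first acquired frame, as all voxels at or
above 30% of that frame's maximum (inclusive, matching the usual "≥30%"
convention), then frozen and multiplied into every later frame; mean
in-mask intensity minus a per-frame background estimate gives the TAC.
Background can be a scalar, a per-frame vector, or derived from a
background region; the subtraction order (before masking, as applied
here) is a configuration fact, since reports of this procedure typically
do not state it. Connected-component filtering of the mask is available
but off by default.

Heart:wholebody (H:WB) ratios summarize absolute retention: heart-ROI
counts, background-corrected per pixel area, as a percentage of total
image counts. The packaged reference table stores ordinal session indices
between the 0 h and 5 h scans because the intermediate times were not
recorded. Geometric-mean combination of anterior/posterior views is not
applied (summed counts are used); per-area background scaling is explicit
in the interface.

## Group statistics

Groups are summarized as mean ± SEM (sample SD with the $n-1$ denominator
over $\sqrt n$; this convention reproduces the reference table's 470.25
SEM exactly). Between-group contrasts use the two-sided Mann–Whitney U
test — exact at these sample sizes (combined $n \le 20$, no ties), normal
approximation with tie correction otherwise — with Bonferroni correction
(`min(1, p × family)`); raw and adjusted p-values are always reported side
by side because the appropriate family size depends on how many contrasts
a study reports. The within-group short-vs-long comparison is a Wilcoxon
signed-rank test paired by subject (pairing is natural since both
components come from the same animal), with an unpaired option.

## Synthetic data: what it does and does not emulate

The generators exist so every downstream stage is testable without
scanner data. They emulate: biexponential washout with In-111 physical
decay (half-life 67.32 h, one package constant), Poisson counting noise
(Gaussian optional), a 3-D phantom with a spherical injection focus added
on top of a uniform background (the simplest geometry that exercises the
30% mask), wholebody scans whose heart compartment drains first-order
into liver, kidneys, bladder and remainder — each organ receiving its
rate's share of the efflux, which conserves decay-corrected counts
exactly and makes H:WB strictly decreasing — and cohorts drawn log-normal
around the reference-group means (half-lives are positive and
right-skewed), with heart fractions spread near 50%.

They do not emulate projection/reconstruction physics, collimator
response, scatter, attenuation, partial-volume effects, inter-session
misregistration, or organ-level kinetics beyond the first-order
redistribution above. Passing round-trip tests therefore demonstrates
correctness of the estimators under the model's own assumptions, not
robustness to reconstruction artifacts. Count scales are free parameters
(no published count levels exist for these scans); the defaults — 10^4
peak counts for TACs, background 10 counts/voxel with a 20:1 focus — are
chosen so that relative noise at the late time points is clearly visible
but not dominant, which is the regime where weighting choices matter.

## Problem sizes and numerical choices

The test suite and the acceptance script run the fit round trip on all 19
reference parameter sets on a 14-point schedule (serial 0–5 h plus three
weekly sessions), the closed-vs-numeric comparison on 10^4 grid points,
and viability recovery at five log-spaced half-lives across 30–1200 h
with 100 Poisson replicates each; the full suite completes in well under
a minute. Tie-breaks and degenerate inputs are handled explicitly: equal
forward-model rates switch to the analytic limit, constant TACs return a
flagged zero-rate boundary fit, and empty groups skip comparisons with a
notice rather than failing.

## Limitations

$C$ and the DIRF are inputs here, not estimated — measuring them requires
the dedicated injection experiments. The viability estimate is a lower
bound on surviving cell number when cells proliferate. Printed p-values
from legacy statistical software cannot be regenerated without knowing
the correction family sizes used, so the package reports raw and adjusted
values side by side and asserts neither.
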