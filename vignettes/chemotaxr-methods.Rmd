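---
title: "Methods: quantifying single-cell chemotaxis heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying single-cell chemotaxis heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chemotaxr analyzes how oscillatory kinase signaling, cell morphology, and
nuclear polarization relate to the heterogeneous migration of single cells
in a chemoattractant gradient. This vignette is the package's account of
its models and numerical choices. No empirical claim is made here that the
test suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

Live-cell movies carry three channels: a nuclear marker and two kinase
translocation reporters (KTRs) for Akt and ERK. A KTR leaves the nucleus
when its kinase is active, so activity is read as the log2 ratio of mean
cytoplasmic to mean nuclear reporter intensity (log2 CNR). Morphology is
summarized by the best-fit ellipse of the cell outline: the aspect ratio
(major/minor axis) measures elongation, and nuclear polarization is the
distance from nucleus centroid to cell centroid normalized to the minor
axis length.

Segmentation follows standard practice for this reporter set: local-mean
adaptive thresholding of the nuclear channel (window roughly three times
the expected nucleus diameter; the offset is a fraction of the channel's
robust intensity spread with a 3-MAD noise floor), hole filling, and
minimum-area filtering; then nucleus-seeded region growing over an
adaptive-threshold foreground of the summed KTR channels
(`EBImage::propagate`, a seeded watershed in the CellProfiler style).
Before intensity averaging the cell boundary is eroded and the nucleus
dilated by `erode_px` (default 2 px) so partial-volume edge pixels,
blurred across the membrane by the optics, do not contaminate the ratio.
Ellipse parameters come from second central moments of the region (the
axes of a solid ellipse are four times the square roots of the principal
variances, with a 1/12 px^2 discretization correction).

Tracking links detections between frames by minimum-cost assignment
(Jonker-Volgenant) with cost `(d/d_gate)^2 + w_a |dA| / mean(A)` on
nuclear positions, a 30 um gate per 4-min interval, unmatched cost 1.05,
gap closing up to 2 frames with the gate inflated by sqrt(gap+1), and
post-hoc division resolution: a terminus (or a continuing track that
sheds a new neighbor while halving in area) with one or two nearby
daughters whose combined area matches the parent is called a mitosis, and
the parent's last 3 frames (12 min) are trimmed because signaling and
morphology are unreliable during division.

## Period-band amplitudes

Signals are detrended by subtracting a 200-min centered moving average
(longer than any analyzed band; series shorter than the window fall back
to removing a linear fit and are flagged) and decomposed with a
brick-wall discrete-Fourier filter: frequencies with period inside
[period_low, period_high] are kept, everything else (including DC) is
zeroed, and the series is transformed back, giving exactly zero phase
shift. The two default bands are 28-60 min ("short" waves, the period
range of reported ERK pulses) and 92-124 min ("long" waves, matching the
period range of aspect-ratio oscillations). Per-cell amplitude is defined
as sqrt(2) times the RMS of the filtered series, which equals the peak
amplitude of a single tone; an alternative (mean analytic-signal
envelope) was considered and rejected because the RMS definition is
exactly testable against closed forms and insensitive to isolated
outliers. Leakage at non-integer cycle counts is accepted and bounded in
tests (under 5 percent between the default bands). Cells enter band
analysis only with at least 60 frames (4 h, two cycles of the long band)
and no interior gap beyond 2 frames; longer gaps exclude the cell rather
than impute.

## Heterogeneity statistics

Quantile regression minimizes the pinball loss at tau = 0.2, 0.5, 0.8.
For n up to ~350 the fit is exact: an optimal line for the
intercept-slope model interpolates two observations with distinct x, so
all candidate lines are enumerated. For larger n, candidates from a
deterministic quantile-spread subsample are polished by coordinate
descent in which both one-dimensional subproblems (intercept given slope;
slope given intercept) are solved exactly as weighted quantiles. Standard
errors and 99 percent confidence intervals come from a seeded
case-resampling bootstrap (B = 1000 by default) and the p-value from a
normal approximation on the bootstrap SE; the bootstrap was chosen over
asymptotic sparsity-based SEs because it is distribution-free and
reproducible from the seed.

The earth mover's distance between two per-cell distributions is the 1D
Wasserstein-1 distance, computed as the integral of |F_a - F_b|; in one
dimension this equals the transportation optimum, which the tests verify
against a north-west-corner oracle. The normalized EMD divides the mean
EMD from the test condition to each control replicate by the mean EMD
among control replicates, so a value near 1 means "no larger than
replicate variation". The numerator averages over replicates (rather than
picking one control) to remove an arbitrary choice.

The top-quartile proportion is P(amplitude > Q75 | speed > Q75) with
quartiles by linear interpolation of order statistics and strict
inequality, matching the ">75th percentile" convention.

## Aspect-ratio peak events

Peaks of the 3-frame moving-average aspect ratio with prominence at least
0.1 and separation at least 48 min are each paired with the preceding
minimum; the defaults guarantee one peak per cycle for a single 108-min
tone. Around each peak a window of +/-60 min (about half the long period)
is aligned to time zero. The nearest local minimum of the detrended ERK
series within that window gives the signed lag; because short ERK pulses
would otherwise dominate the minima, the detrended series is smoothed
with a 40-min moving average (roughly the short-wave period) before
minima detection — the choice of detrending before minima detection is
genuinely open, and this one makes the long-wave alignment the tests
target identifiable. ERK and aspect-ratio differences are measured at the
times of the aspect-ratio extrema, not the ERK extrema. Event speed
traces are normalized twice: by the cell's own mean speed, then by the
average of that ratio over non-polarized events, so the non-polarized
stratum has unit mean by construction. Strata are the top and bottom
quartiles of polarization at the peak.

## Weak-form motility inference

Cell populations are treated as continuous density fields rho(x, t)
obeying the advection-diffusion equation d(rho)/dt = D lap(rho) -
v . grad(rho): D is random migration, v directed motion. Density fields
are 2D position histograms on a uniform node grid (spacing h = 25-30 um)
smoothed with a Gaussian of bandwidth 2h and aggregated to 20-min blocks —
at the native 4-min interval, detection noise would dominate the time
derivative. For every interior bilinear nodal test function w and
consecutive frame pair, testing the residual yields
`int w (rho1-rho0)/dt = -D int grad(w).grad(rbar) - v . int w grad(rbar)`
with rbar the midpoint average; integration by parts is applied only to
the diffusion term and advection is kept in non-divergence form (constant
coefficients make them equal), so no boundary flux terms arise. A
one-element boundary band is excluded because the chamber's boundary
conditions are unknown. All integrals reduce to separable 3-point
stencils (bilinear mass, stiffness, and gradient matrices), and the
stacked system is solved by ordinary least squares with condition-number
diagnostics. A negative fitted D is reported with a model-inadequacy
flag, never clamped.

Backward elimination over {diffusion, advection_x, advection_y} drops the
operator whose removal increases the residual sum of squares by the
smallest relative factor while that factor stays at or below `tol`
(default 1.5); an infinite tolerance disables elimination. Drug
conditions are normalized as D_drug / D_control (random migration) and as
the ratio of gradient-aligned velocity fractions v_par/|v| (directed
motion); a control with no meaningful directed motion makes the second
ratio undefined and it is flagged rather than reported.

## The synthetic-data generator

No experimental dataset is distributed with the source material, so the
generator is a first-class, tested module that emulates the statistical
structure every downstream stage assumes, with known ground truth:

- Reporter signals are sums of a long (108 min) and a short (40 min)
  sinusoid with per-cell log-normal amplitudes (measured amplitude
  distributions are right-skewed) and per-cell uniform phases (no
  cross-cell phase structure is claimed by the source analyses). Akt
  shares phases with ERK but draws its amplitudes independently.
  Sinusoidal superposition is an assumption of the generator, not a claim
  about real waveforms.
- The aspect ratio oscillates anti-phased with the long ERK component
  (AR maxima at long-ERK minima) with amplitude `ar_coupling * A_long`.
  The coupling is relative — proportional to the cell's long-wave
  amplitude — because a fixed absolute amplitude would make per-event
  elongation independent of the ERK drop and the documented negative
  d_AR/d_ERK association unobservable.
- Motion follows `x(t+dt) = x(t) + v dt + sqrt(2 D dt) eta`. When a
  per-cell mean speed is prescribed (`speed_coupling`: intercept +
  slope * A_short), the diffusive step lengths are rescaled so the
  realized mean speed matches the target exactly; this deliberately
  breaks the global diffusivity, so diffusivity-recovery studies disable
  the coupling. Adherent cells cannot interpenetrate, so a hard-core
  exclusion (center distance >= 16 um, resolved by symmetric pushes)
  is active by default; it too is disabled (`exclusion_radius = 0`) when
  the pure advection-diffusion law must hold exactly.
- Each aspect-ratio cycle produces one peak event. A peak is "polarized"
  with probability 0.5: polarized peaks carry nuclear polarization
  proportional to `polarization_coupling * A_long` and a raised-cosine
  speed burst (half-width 20 min) peaking `burst_gain` (default 25
  percent) above baseline `burst_lag` (default 20 min) after the peak;
  non-polarized peaks keep a weak (15 percent) polarization coupling and
  no burst. The binary gating is a deliberate simplification: it makes
  the polarized-stratum burst height a designed, testable quantity
  (1 + burst_gain) while the graded residual coupling keeps the
  median-quantile polarization regressions informative.
- The renderer draws cells as filled ellipses whose contested pixels go
  to the nearest cell in the normalized ellipse metric (adherent cells
  exclude area rather than overlap); nuclei are drawn in full and win
  contested pixels. KTR channel intensities are set so that
  log2(cytoplasm/nucleus) equals the tabulated truth exactly before blur
  and noise. For touching cells the tabulated ellipse is the free-cell
  shape while the emitted ground-truth masks record the actual rendered
  partition; mask-level truth is the reference for segmentation quality.

Fixed seeds give bit-identical output; every stochastic stage takes its
seed from the configuration.

What passing tests on this generator do show: the pipeline recovers
amplitudes, phases, lags, couplings, diffusivities and velocities it was
never told, from rendered pixels upward. What they do not show: robustness
to illumination drift, photobleaching, segmentation of irregular
(non-elliptical) cell shapes, dense confluent fields, or waveforms far
from sinusoidal superposition — real data carry all of these.

## Problem sizes and tolerances

The test suite runs entirely on synthetic data at desk scale: movies of
25-150 cells at 4-min sampling over 24 h for signal analyses; a 50-cell,
360-frame rendered movie for the segmentation round trip; 2000-cell
populations (about 100 frames) for motility inference, with recovery
judged by the median over 10 seeds; the acceptance script samples 60 of
the 360 rendered frames and 5 seeds for the motility block. Band
arithmetic is checked to 2 percent (in-band) and 5 percent (leakage),
Parseval partitions to 1e-6 relative, EMD against its transport oracle to
1e-9, quantile fits against a 0.01-resolution grid oracle, weak-form
closed forms to 5-10 percent, and population-level parameter recovery to
15-20 percent — the honest scale of finite-sample inference at these n.

## Known limitations

- Constant-coefficient advection-diffusion only; space-varying D(x),
  v(x) and reaction/proliferation terms are out of scope, as are
  confidence intervals on the PDE parameters (point estimates with
  residual and conditioning diagnostics only).
- The tracker is single-hypothesis; it resolves crossings through the
  morphology term but does not maintain multiple hypotheses.
- Segmentation is classical (threshold + seeded watershed); no learned
  models, no illumination or photobleaching correction.
- Mitosis handling trims tracks; lineage analytics beyond that are out
  of scope.
- EMD is univariate, matching the per-cell scalar comparisons it serves.
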