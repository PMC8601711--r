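---
title: "Stereo thermal videogrammetry and deterrent-response analysis: methods"
author: "stereobat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereo thermal videogrammetry and deterrent-response analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereobat)
```

## What this package models

Ultrasonic acoustic deterrents are used to push bats away from wind
turbines, roads and buildings. Quantifying *how* bats respond requires two
measurement chains: a stereo pair of thermal cameras that reconstructs
three-dimensional flight paths over the treated airspace, and an ultrasonic
recorder whose call sequences are counted into an alternating
control/deterrent block design. This package implements both chains
end-to-end — camera calibration, detection, stereo pairing, trajectory
linking and QC, flight metrics, the deterrent sound-field model, and the
mixed-model statistics — together with a synthetic scene generator that
stands in for field recordings, which are not publicly deposited.

The world frame follows the reporting convention of the field set-up:
`x` lateral along the camera baseline, `y` range from the camera plane
(the viewing direction), `z` height relative to the cameras. File formats
use millimetres and 0-based frame indices; metrics are reported in metres
and m/s.

## The camera chain

**Camera model.** Standard pinhole with per-axis focal lengths, principal
point and optional `k1, k2` radial distortion (applied after perspective
division). The default rig mirrors the field geometry: two 640 x 480
cameras 4 m apart at equal height with parallel horizontal axes and
33-degree lenses. The field notes state the inner field-of-view edges
overlapped at 3.2 m while the side edges were parallel; simple
parallel-axis geometry gives a different crossing distance, so the mounting
convergence is ambiguous and the rig geometry is fully configurable rather
than derived.

**Calibration.** The thermal calibration target is an aluminium cross with
thirty 11 mm tungsten bulbs: three arms of eight and one arm of six bulbs
in three pairs, which breaks the cross's 4-fold symmetry. Bulb spacing is
not recorded, so the arm length defaults to 1 m with even spacing
(configurable). Identification of unlabelled blobs exploits projective
invariants: arms are collinear through the cross centre, the pair pattern
singles out one arm, and per-arm bulb indices are found by a 1D projective
fit anchored at the centre — the anchoring is what makes a shifted
evenly-spaced subset distinguishable from the true one when bulbs are
missing (poses with fewer than 25 of 30 bulbs are rejected). Calibration
itself is the planar-target method: DLT homography per pose, closed-form
zero-skew intrinsics from the homography constraints, per-pose extrinsics,
then full Levenberg–Marquardt reprojection refinement per camera; the
left-right transform is averaged over poses. A rank-deficient constraint
system (e.g. all frontal-parallel poses) is reported as a degenerate pose
set via the condition number of the intrinsics system measured against its
second-smallest singular value (the smallest is the solution space itself).
On noiseless 24-pose simulations the recovery is exact to machine
precision; with 0.5 px pixel noise the RMS reprojection error stays below
1 px.

**Triangulation.** Midpoint of the shortest segment between the two
back-projected rays, with the mean reprojection error over both cameras as
the residual. Near-parallel rays (below 0.05 degrees) are refused rather
than returning an unstable depth.

## Detection and tracking

Frames are background-subtracted either against the adjacent frame (the
mode used on the field footage; a moving target leaves blobs at its old and
new positions) or against a per-pixel temporal median, the robust default
for synthetic scenes. Blobs are connected components above a pixel
threshold, area-filtered (default minimum 2 px, rejecting single-pixel
noise) with intensity-weighted sub-pixel centroids; centroid error on
noiseless synthetic blobs is below 0.1 px. Because the field protocol chose
its pixel threshold empirically per night, `select_threshold()` replays the
full detect–pair–link–QC chain over a candidate grid and scores each
candidate as (QC-passing trajectories) − λ · (discarded localisations).
The noise term of that trade-off is not quantified in the protocol, so the
weight λ (default 0.1) is an explicit modelling choice; ties resolve to the
higher threshold.

Stereo pairing triangulates every cross-camera candidate pair per frame and
keeps a global one-to-one minimum-cost assignment on reprojection residual,
dropping pairs above 2 px (this operationalises "comparing x and y
coordinates from both cameras"). Linking is greedy over frames with a
global per-frame assignment between active tracks and new localisations
(cost = 3D gap distance; ties broken by smaller frame gap then smaller
residual) under the published gates: maximum speed 15 m/s, maximum frame
gap 15, maximum step 1000 mm, minimum length 6 localisations. No installed
linear-assignment solver is available, so the per-frame assignment is an
exact branch-and-bound (problems are a handful of targets wide; a greedy
fallback guards pathological sizes). An independent exhaustive
branch-and-bound linker over whole scenes is kept as a test oracle and
agrees with the greedy linker and with ground truth on well-separated
synthetic scenes.

QC follows the published rules: trajectories sharing more than three
localisations are removed; a difference above 3 m/s between subsequent
instantaneous speeds fails a trajectory; isolated erroneous localisations
are removed only while the edit stays below 10% of the trajectory,
otherwise the whole trajectory is rejected.

The frame interval defaults to 0.032 s, the value used in the reported
speed calculations; the nominal frame rate of 32 frames/s implies
1/32 = 0.03125 s, and both are supported through the `dt` parameter.

## Flight metrics

Instantaneous speed is segment length over gap-scaled frame time; mean
trajectory speed is the arithmetic mean of instantaneous speeds. Total
length is the sum of straight-line segments (segments spanning frame gaps
contribute their straight-line length — the protocol is silent on gaps);
net displacement is first-to-last distance; the tortuosity value is
(total/net)/10, exactly 0.1 for a straight path and undefined (excluded,
with a message) at zero net displacement. Tortuosity values above 1
(path ratio > 10) are retained in the metrics output but excluded from the
(0, 1)-domain beta model with a logged count. Distance from the deterrent
is mean `y` plus the 15 m speaker offset behind the cameras; mean `y` and
the offset are reported separately because the reported per-trajectory
"distances from the deterrents" (13.84/15.49 m) are numerically consistent
with mean `y` alone, not with mean `y` + 15, and emitting both lets either
convention be reproduced. An observed tortuosity minimum of 0.03 is also
below the formula's floor of 0.1; that discrepancy cannot be resolved from
the protocol text and is not emulated.

## The deterrent sound field

SPL is modelled as spherical spreading from the 1 m reference plus ISO
9613-1 pure-tone atmospheric absorption (oxygen and nitrogen relaxation
plus classical losses), applied over `d − 1` so the 98 dB reference at 1 m
is exact:

`L(d) = 98 − 20 log10(d) − α (d − 1)`,  α = 1.591 dB/m at 50 kHz, 14 °C,
90% RH, 101.325 kPa.

This reproduces the printed 52 dB at 15 m and falls below 3 dB past 40 m
(2.10 dB at 41 m). The printed 21 dB at 30 m is ~1.3 dB below this model's
22.3 dB; the exact absorption computation behind the printed figure is
unknown, so only the robust printed values are used as checks. Speakers are
modelled as isotropic points (the transducer beam pattern is documented
only in a datasheet); multiple sources use a nearest-source approximation
with no incoherent summation.

## The synthetic study

**Flights** are 3D correlated random walks: Gamma step lengths (mean
`mean_speed · dt`), wrapped-normal turning angles with regime-specific
concentration, Gaussian vertical increments. Regime defaults follow the
reported per-trajectory kinematics — commuting 4.86 ± 0.92 m/s, foraging
4.54 ± 0.99 m/s. No turning-rate data exist for these bats, so the turn
concentrations (60 commuting, 6 foraging) are assumptions chosen to give
straight commuting tracks and visibly convoluted foraging tracks with mean
tortuosity near the reported 0.11–0.12; they are free parameters of the
generator. Deterrent response is modelled as the minimal mechanism
consistent with the three observed effects (speed up, tortuosity down,
distance up): where local SPL crosses a threshold, the bat switches (with a
configurable probability) to the commuting regime with its heading biased
away from the source, and the remainder of the path is re-simulated.

**Rendering** places one Gaussian blob per in-view projected bat position
over Gaussian background noise, plus Poisson-rate clutter blobs standing in
for insects, at 640 x 480 in [0, 1] image units (written as 16-bit
grayscale multi-page TIFF). A caveat discovered during development and
worth keeping in mind with real footage: a target moving mostly down-range
barely moves in pixel space, so a temporal-median background model absorbs
it; the adjacent-frame mode or lateral motion avoids this.

**Counts** follow the field design exactly: 3 sites × 3 nights × 12
five-minute blocks alternating control/deterrent starting with control.
Counts are negative binomial with log-scale site/night/block random
intercepts and a multiplicative treatment rate ratio. Baselines (e.g. 46.5
passes per control block for the dominant species) were chosen so the
simulated totals and composition are of the same order as the reported
5440 passes with 79% from *P. pygmaeus*; rate ratios default to the
reported reductions (0.70 overall, 0.73 for *P. pygmaeus* passes, 0.62 for
feeding buzzes, 0.32 for the *Nyctalus*/*Eptesicus* group). Random-effect
s.d.s (0.35/0.25/0.20 on the log scale) and NB size 8 are generator
assumptions representing night-to-night and block-to-block variability a
riparian site plausibly shows; they are documented here once and not tuned.

**Call parameters** are Gaussian records for a 55 kHz *Pipistrellus*-type
call, three calls per pass, with nested
site/night/block-pair/time-block/sequence random intercepts. The deterrent
shifts bandwidth (−5.79 kHz) and start frequency (−5.68 kHz) only — the
reported effects — and the start-frequency shift is realised through the
bandwidth and end-frequency components so that bandwidth = start − end
holds exactly in every record. An extra bat in a pass widens bandwidth
(+1.5 kHz, an assumption consistent with the reported direction). The
time-block random s.d. (0.3 kHz) is deliberately small relative to the
residual (4 kHz): the treatment contrast is estimated from five block
pairs, and this is the level that controls recovery precision at the
field's sample size of 150 passes per arm.

What the generator does *not* emulate: species mixtures within a single
thermal blob, wing-beat intensity modulation, weather-driven background
drift, microphone directionality, or observer error in manual call
measurement. Passing recovery tests therefore demonstrates that the
algorithms are correct on data satisfying the model assumptions, not that
the field measurement chain is unbiased.

## Statistical analysis

Count responses use Poisson GLMMs unless the marginal variance/mean ratio
exceeds 1.5 (the protocol says only "depending on the distribution"), in
which case a negative binomial GLMM is fitted via `glmmTMB`; when the NB
size is unidentified on borderline data (non-positive-definite Hessian,
the NB drifting to its Poisson limit) the Poisson fit is used. Species
groups with fewer than 20 passes per night for the majority of nights are
refused, mirroring the published exclusion. Trajectory responses: speed
and distance as Gaussian LMMs; height Box–Cox transformed (λ by profile
maximum likelihood on the marginal response, then fixed and reported; the
response is shifted positive first if needed); length log-transformed;
tortuosity as a beta-family GLMM with cloglog link — the protocol's "beta
binomial" on a continuous proportion is interpreted as the beta family,
since beta-binomial requires integer trials which tortuosity lacks. Fixed
effects are treatment, block order, distance and treatment × distance
(distance model: treatment and block order only); random intercepts are
block nested in night nested in site throughout. Call-parameter LMMs use
treatment, block order and number of bats with fully nested
site/night/block-pair/time-block/sequence intercepts (the exact nesting
syntax is not spelled out in the protocol; the fully nested reading is
implemented), and Bonferroni correction with m = 6.

AICc (`−2ℓ + 2k + 2k(k+1)/(n−k−1)`, with n = response rows, not groups),
likelihood-ratio tests (χ² = 2Δℓ against the χ² upper tail), the >2 AICc
selection rule, the dispersion rule, Bonferroni and the raw/model-based
percent reductions are implemented in-package; only the numerical mixed-
model optimisation is delegated (lme4, glmmTMB). Percent reductions are
emitted both as raw totals (100·(1 − treated/control)) and model-based
(100·(1 − exp(β))) because the protocol does not say which convention its
printed percentages use.

## Problem sizes and numerical choices

The packaged test-and-verification runs use: 24-pose calibration
sequences; rendered scenes of 2–6 bats at 640 × 480 (quarter-resolution
rigs in fast tests) over 8–48 frames; 10⁴ random points for the
triangulation round trip (worst-case error < 10⁻⁶ mm); 100 simulation
replicates for rate-ratio recovery and 500 for the null size of the
treatment LRT (nominal 0.05 within two Monte-Carlo standard errors); and
150 passes per arm for call-parameter recovery, matching the field sample
size. The trajectory-linking oracle runs on scenes up to 3 bats × 10
frames, where its exhaustive search is exact.

Tie-breaking and degeneracy rules that matter in practice: equal-cost link
extensions prefer the smaller frame gap, then the smaller pairing residual;
equal threshold-selection scores prefer the higher threshold; zero net
displacement excludes a trajectory from tortuosity; behind-camera points,
near-parallel rays, degenerate calibration pose sets, all-identical
tortuosity responses and non-converged fits raise errors rather than
returning numbers.

## Known limitations

- The pairing stage resolves stereo ghosts by residual-gated one-to-one
  assignment; two bats at the same height crossing the same epipolar line
  can still swap in principle. The field protocol's shared-point QC rule is
  the backstop, and the identity audit in the tests covers the separated
  case only.
- The rig is assumed synchronized and rigid per night, as in the field
  protocol; no rolling shutter, clock drift or thermal drift is modelled.
- The sound field is isotropic; directional transducers would steepen the
  off-axis roll-off, making the modelled field an upper bound off-axis.
- Box–Cox for height is estimated marginally, not profiled within the
  mixed model.
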