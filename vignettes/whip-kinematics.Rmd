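---
title: "Kinematic analysis of targeted whip manipulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic analysis of targeted whip manipulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

whipkin analyses three-dimensional motion-capture recordings of a targeted
bullwhip task: a participant holds a 0.24 m rigid handle attached to a
1.6 m flexible, tapered thong and tries to strike a sprung target about
2.2 m away, either in a *discrete* style (individual throws from the floor,
separated by pauses) or in a *rhythmic* style (continuous self-paced
cycles). The pipeline turns labelled marker trajectories — one hand marker,
ten whip markers `w1` (tip) to `w10` (thong base), two handle markers and
three target markers, sampled at 500 Hz — into per-trial performance and
whip-shape metrics, ensemble speed profiles, and mixed-effects estimates of
style and practice effects. A scripted kinematic scene generator produces
synthetic recordings with exact ground truth, so every stage can be
validated in closed loop without any real recordings.

## Preprocessing

Marker trajectories are low-pass filtered with a zero-lag FIR filter:
Kaiser-window design with passband and stopband edges 1 Hz below and above
the cutoff, 60 dB stopband attenuation and a 0.1 passband-deviation bound.
Cutoffs are 20 Hz for the hand (body) marker and 40 Hz for whip, handle and
target markers. The Kaiser order estimate is taken as the automatic minimum
and increased (in steps of two) if the realized response misses the
stopband spec; coefficients are normalised to exact unit DC gain. Because
the filter is symmetric (exactly linear phase), the zero-lag realization is
a single pass with integer group-delay compensation — numerically identical
to forward-backward filtering — with odd-reflection padding at span edges
so constant and linear trends pass through unchanged.

Gaps shorter than 50 frames (0.1 s) are bridged by linear interpolation
before filtering; longer gaps split the series into independently filtered
spans. This differs in order from a filter-first approach, but for the
50-frame limit the difference is confined to the bridged samples, which the
exclusion rules already treat with caution. Differentiation uses
second-order central differences with one-sided stencils at span
boundaries, and tangential speed is the per-frame Euclidean norm of the
velocity.

## Segmentation and landmarks

A trial ends at a *minimum-distance event*: a local minimum of the
instantaneous distance between the distal whip polyline (w1–w3) and the
target segment (t1–t2), detected with a 0.3 s refractory period and a 1 m
ceiling (approach minima are well below 1 m; handling or backswing wiggles
are not). Discrete trials start at the last upward crossing of hand speed
through 0.5 m/s within 1.0 s before the whip lifts off the floor (all of
w1–w3 above 2 cm, debounced for 50 ms); a lift without a preceding crossing
flags the trial instead of silently dropping it. Rhythmic trials tile the
spans between consecutive events.

Within each trial, three landmarks are located: throw onset (maximum
hand-to-target distance), peak hand speed (maximum hand tangential speed;
with the characteristic two-peak hand profile this is always the second,
higher peak), and minimum distance (the trial end). Ties break to the
earliest frame, and the ordering onset <= peak <= minimum distance is
enforced; violations mark the trial excluded with a diagnostic. Trials with
more than five simultaneously missing markers at any frame are excluded
from all analyses; a single gap longer than 200 frames (0.4 s) excludes a
trial from profile averaging only.

The labelling of the "distal" whip markers is internally inconsistent in
the source material (w10/w9/w8 in one place, w1–w3 in another, with the
tip marker illustrated as w1). This package treats w1–w3 as the distal,
tip-side markers everywhere and flags the alternative wording as a likely
labelling slip rather than silently reconciling the two.

## Trial metrics

*Error* is the minimum distance between the whip and the target: the
polyline through w1–w3 against the segment through t1–t2, minimised over
the throw interval (onset to minimum distance). The distance itself is the
exact continuous minimum between the interpolated polylines — the limit of
the pairwise-distance computation as the interpolation step shrinks — via
the standard clamped closest-point algorithm for segment pairs; a
dense-sampling brute force at 0.1 mm serves as the independent oracle in
the tests. The whole-trial variant is reported as a secondary column: in
the rhythmic style a whole-trial minimum would always collapse onto the
previous strike at the trial's first frame, so the throw interval is the
primary span.

*Hits* are detected from oscillations of the sprung target: the t1
trajectory is demeaned per valid span, band-passed (2nd-order Butterworth)
around the spring's free frequency (default 4 +/- 2 Hz), and a hit is
declared when the post-trial envelope within 1 s exceeds a 5 mm threshold
above the pre-trial baseline; a still-oscillating baseline flags the trial
ambiguous. The band, threshold and windows are configuration parameters
calibrated on synthetic target oscillations.

*Whip extension* is the Euclidean distance from the distal handle marker
h1 to the tip w1 at the peak-hand-speed landmark (metres, with the ratio
to the 1.6 m arc length); the tip-to-base variant (w1–w10) is reported as
an alternative column, since both definitions appear in the source
material and the primary results are stated in metres against 1.6 m.
*Whip azimuth* is the first principal direction (SVD) of the eleven
markers h1, w10..w1, oriented handle-to-tip, projected to the horizontal
plane and measured against the target direction; *hand azimuth* is the
analogous angle of the hand-handle body axis (mean of w10 and h1 versus
mean of h2 and the hand marker). The lab frame puts x from the
participant toward the target and z up; azimuth 0 deg points straight
backward from the target and positive angles turn toward the
participant's right, so a whip cocked slightly left of straight-back
reads about -11 deg and one pointing back-right reads about +28 deg. If a
needed marker is gapped at the landmark the nearest valid frame within
+/-5 frames (10 ms) is used.

*Peak hand speed* is the trial maximum of hand tangential speed; *peak tip
speed* is the w2 maximum over the throw interval (w2 stands in for the
tip, whose own marker is too noisy to differentiate; the throw interval is
the span over which whip speeds are analysed, and in the rhythmic style a
trial-wide maximum would instead pick up the backswing). *Rhythmicity* is
the coefficient of variation of start-to-start inter-trial intervals,
using the sample SD (n-1) because per-block trial counts are small; the
printed 0.4330 for intervals {1, 1, 2} s reflects that convention.

## Speed profiles

Per-trial speed series are linearly resampled onto a fixed 500-sample grid
whose final sample is the minimum-distance landmark: whip markers over the
throw interval, the hand over the full trial. A fixed grid is equivalent
to normalising each trial to the mean span duration up to a relabelling of
the time axis, and makes cross-trial means and sample SDs immediate.
Trials flagged for profiles, trials with missing samples in the span, and
spans under 10 frames are skipped with a log entry. The proximal-to-distal
*cascade* — per-marker peak times strictly increasing from w10 to w1 — is
summarised by `cascade_peak_times()`.

## Mixed-effects stage

Each metric is modelled as `Y ~ S * B` with style coded discrete = 0,
rhythmic = 1 (a positive style coefficient means larger in the rhythmic
style), block numeric 1–5, and per-participant random intercepts and
style/block slopes; hit/miss uses a binomial GLMM with logit link
(bobyqa optimizer), everything else a Gaussian LMM. Final estimates use
REML with Satterthwaite p-values (lmerTest); likelihood-ratio comparisons
refit with ML. Singular random-effect fits step down a declared ladder of
simpler structures, recorded in the result's trace. The error-covariate
models regress error on style, a covariate (extension, azimuth, peak
speeds) and their interaction with random covariate slopes; the per-style
slopes are the covariate coefficient (discrete) and its sum with the
interaction (rhythmic). `select_style_block_model()` implements the
iterative selection: forward LRT over the fixed terms at alpha = 0.05 on a
random-intercept base, then an LRT for the random slopes, with every
comparison kept in the trace — the sequence is made explicit rather than
guessed. Skewed metrics (error, extension) are modelled untransformed, as
the reported slopes are on the raw scale; medians and IQRs appear only in
summaries.

## The synthetic scene generator

The generator is kinematic, not dynamic: marker trajectories are scripted
configurations of an exact-length chain (0.26 m hand-to-thong-base, then
ten segments of 2, 19 x 8 and 6 cm), so planted quantities are realized by
construction and a dynamics model is deliberately out of scope — the
analysis needs controlled ground truth, not physical fidelity.

The hand follows a two-peak signed velocity profile (Gaussian strokes: a
backward cast, the forward throw whose amplitude is the planted peak hand
speed, and a small balancing return), so throw onset is the sharp reversal
between cast and throw. The cocked-back pose at peak hand speed is a
zig-zag about the planted azimuth whose half-angle is solved so the
h1-to-w1 distance equals the planted extension, then rotated so the SVD
line fit recovers the planted azimuth exactly; the handle direction is
solved the same way for the planted hand azimuth. The strike geometry
offsets the tip from the target marker along the common normal of the whip
and target lines, so the planted error is the true minimum distance,
realized at the tip at the minimum-distance frame; hits trigger a damped
4 Hz oscillation of the sprung target marker.

The unfolding cascade combines two mechanisms. Proximal markers (w10–w5)
ride the hand's translation, so their own peaks come from a travelling
pitch wave: short transient elevation bumps per link, staggered in time,
whose vertical velocity adds in quadrature to the horizontal base — the
amplitudes are calibrated (through the same 40 Hz filter the pipeline
uses, since the study's printed speeds are filtered measurements) to a
ladder rising just above the hand peak. Distal segments sweep azimuthally
through the strike direction in staggered windows that all end at minimum
distance, accumulating speed toward the tip; the w2 window width is
calibrated to the planted tip speed (the tip-to-hand gain defaults to the
reported 29.7/6.1 and 24.1/4.5 m/s ratios). Windows scale per trial with
the drawn hand peak and with each segment's sweep relative to the
calibrated pose, so the per-marker peak ratios survive trial-to-trial
variation. Under the style-canonical conditions the cascade ordering is
strict in every tested seed; participants drawn far from the calibration
point can compress one adjacent mid-thong pair by a frame or two — a
deliberate reflection of the fact that individual deviations from the
segment-wise pattern also occur in real recordings.

Per-trial draws plant realistic variation: lognormal errors (median 0.10 m,
log-SD 0.5, capped at 0.42 m — above that the post-strike recovery path
would undercut the plant), Gaussian azimuth (SD 10 deg), extension
(SD 4 cm) and hand-peak (SD 0.3 m/s) jitter. Inter-trial intervals realize
the planted CoV *exactly* as the sample CoV of the drawn series (affine
standardization of lognormal draws), so the closed loop on rhythmicity is
sharp; block defaults are 5.4 s / CoV 0.12 (discrete, 33 throws in 180 s)
and 1.2 s / CoV 0.06 (rhythmic, ~32 cycles in 40 s). Marker noise is
isotropic Gaussian (default 0.3 mm, a typical calibrated residual), with
gaps applied after noise from an explicit schedule. Style-level defaults
are the study's reported values: extension 1.45/1.43 m, whip azimuth
-10.9/+28.4 deg, hand azimuth 24.3/36.1 deg, hand peaks 6.1/4.5 m/s.
`simulate_study()` adds participant-level draws of skill and style
parameters, clamped to the envelope in which the generator's guarantees
were validated.

What passing closed-loop tests show — and what they do not: the pipeline
recovers exactly the structures the generator scripts (clean landmarks,
rigid-chain geometry, a single contact per throw, stationary noise).
Real recordings add soft-tissue and marker-mount artefacts, non-stationary
noise, labelling errors, occlusions far longer than the gap schedule, and
genuinely three-dimensional whip waves; agreement on synthetic scenes
bounds implementation error, not measurement error.

## Numerical choices and degenerate inputs

Distance ties at event detection and landmark plateaus break to the
earliest frame. Line fits with a near-zero leading singular value, or
clouds with fewer than three valid markers, return NA with a diagnostic
instead of a number. A stationary hand (constant speed) is a landmark
error; a covariate with zero variance is a model error; a single
participant drops the random effects with a warning. Single-block tables
drop the unidentifiable block terms, recorded in the trace. The interval
standardization guards against non-positive draws by flooring at 55% of
the mean interval.

## Problem sizes

The test-suite and acceptance runs use one 180 s discrete block (33
throws) and one 40 s rhythmic block (~32 cycles) per check, 100 random
scenes for the geometry oracle, 60–80 replicates for the noisy shape
recoveries, and 200 simulated cohorts at the study scale (16 participants,
5 blocks x ~33 trials per style) for confidence-interval coverage and
likelihood-ratio calibration. The workflow under `analysis/` runs a
three-participant study with 60 s discrete and 40 s rhythmic blocks —
enough to exercise every stage end to end while keeping a full run within
a few minutes.

## Known limitations

The wide-TSV dialect is the only supported input; C3D exports must be
converted first. The generator does not model whip dynamics (tension
waves, drag), multi-contact trials, or target misses that still graze the
spring; hit detection on real data would need its band and threshold
re-calibrated against the actual target hardware. The discrete-style
backswing is scripted over the right side of the body for a right-handed
thrower; left-handed scenes would need mirrored conventions.
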