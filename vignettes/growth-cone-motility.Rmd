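---
title: "Quantifying growth-cone motility and force: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying growth-cone motility and force: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcmotility)
```

# The problem

Developing neurons explore their surroundings with growth cones whose
lamellipodia undergo cyclic protrusion and retraction while filopodia probe
ahead. Three families of measurements characterize this motility:

* **Kymograph analysis** of phase-contrast movies taken at the coverslip
  plane: the leading-edge position along a sampling line gives the cycle
  period $T$, the persistence length $dl$ (the maximal protrusion after
  which retraction starts), and the retrograde flow rate $dx/dt$ read off
  the slope of dark streaks that move rearward during retraction.
* **Defocus-based height analysis** of the same recordings acquired as
  Z-stacks (planes at 0–6 µm above the coverslip): a pixel is taken to be
  *in focus* at the plane where its intensity equalises with the background
  — thin phase objects are invisible at focus and gain contrast with
  defocus — so the per-plane fraction of in-focus pixels tracks the
  vertical position of the lamellipodium, which lifts around maximal
  retraction.
* **Optical-trap force measurements**: a bead held in a calibrated trap
  (lateral stiffness $k_{xy}$ = 0.10 pN/nm, axial $k_z$ = 0.08 pN/nm) is
  displaced by the lamellipodium or a filopodium; force is
  $F = k\,\delta$ with $\delta$ the bead deflection reported by a quadrant
  photodiode (QPD). Because the QPD is linear only within ~200 nm, a
  nanopositioner stage recenters the bead whenever its lateral displacement
  $r=\sqrt{x^2+y^2}$ exceeds that threshold; splicing the stage motion back
  into the QPD trace recovers the full *compensated* bead path, whose
  rising-phase slope is the lamellipodial protrusion rate.

No primary recordings are publicly available, so the package is validated
end-to-end by **parameter recovery**: a synthetic-data module generates
image stacks and bead traces with known ground truth, the estimators are
run on them, and the recovered values are compared with what was put in.

# The synthetic world

## Leading-edge kinematics

The edge position along the protrusion axis follows an asymmetric sawtooth:
advance at $v_p$ until the excursion reaches $dl$, then retract at the
retrograde rate $v_r$. The three user-facing parameters $T$, $dl$, $v_r$
determine $v_p$ through $T = dl/v_p + dl/v_r$; supplying an inconsistent
$v_p$ is an error. For the control condition the defaults are
$T = 86.5$ s, $dl = 1.48$ µm, $v_r = 0.08$ µm/s, which give
$v_p \approx 0.022$ µm/s — the slow-protrusion / fast-retraction shape seen
in real kymographs. Recordings start at cycle phase 0.25 (mid-protrusion):
real acquisitions do not begin exactly at a cycle minimum, and an interior
minimum at both ends of the movie is what lets the estimators refine
extremum times below the frame interval.

The vertical lift is a function of cycle phase: a circular Gaussian bump
(`lift_profile_bump()`) peaking at phase 0.9 — late retraction — with
height 5 µm, returning to the substrate early in the next protrusion.
Evaluating the bump on the circular phase distance keeps the height
continuous across the cycle wrap.

## Rendering model

Rendering follows the background-equalization principle that the height
analysis relies on: a structure contributes **zero** contrast in the plane
at its own height, and contrast that grows as
$1-\exp(-(\Delta z/0.7\,\mu m)^2)$ with defocus distance, saturating beyond
about 1 µm. Defocus also blurs the image with a Gaussian of
$\sigma = 0.6\,\mathrm{px}/\mu m \times |\Delta z|$. The blur constant is
deliberately gentle: the height-0 movie must remain analyzable while the
edge lifts through the full 0–5 µm range, as it evidently is in the
recordings this generator emulates; a physically aggressive blur would
contradict the world it is meant to model.

Within the cell the intensity deviation is a smooth positive 1-D texture
(correlation length 0.7 µm — the micron scale of ruffles and bundles that
form retrograde-moving phase features) that translates rearward at $v_r$
during retraction and is stationary during protrusion, producing the dark
kymograph streaks. The outer ~1 µm of the lamellipodium is an
organelle-free rim rendered at 25 % of the interior contrast; besides being
what thin lamellipodial rims look like, this keeps the interior's blurred
shoulder from biasing the edge localization. A thin bright halo
(the phase halo of real cell edges) marks the boundary at every plane.
The cell baseline sits at 35 % of the field width so that the plane median
always reads the background. Camera noise is additive Gaussian
(sd 2 intensity units against a background of 100 and cell contrast of up
to 40). All generators are bit-reproducible under a fixed seed.

## Bead traces and filopodia

Bead traces are sampled at 10 Hz. Between scheduled events the bead
fluctuates about the trap centre with a thermal sd whose default, 6.4 nm,
is the equipartition value $\sqrt{k_BT/k_{xy}}$ at room temperature for
$k_{xy} = 0.10$ pN/nm. During an event the bead is driven at the scheduled
speed along one axis. Feedback recenters the stage at the sample after the
lateral QPD displacement exceeded the 200 nm threshold; the axial direction
is never recentered. The stored ground-truth force is stiffness times the
noise-free deflection, exactly.

Filopodia are straight bright rods (half-width 0.1 µm) elongating from
fixed bases at a constant rate until a maximum length, rendered with
anti-aliasing so tip positions are meaningful below the pixel.

# Algorithm I: kymograph analysis

**Edge extraction** uses a difference-of-Gaussians band-pass
(`sigma_small` = 1 px, `sigma_large` = 3 px) thresholded at $k = 2$
standard deviations of the response. The per-frame threshold makes every
downstream measurement invariant to global intensity offset and gain.

**Edge localization.** Along the sampling line the leading edge is the
outermost run (≥ 2 samples) of *positive* supra-threshold response,
localized at the run's peak with parabolic sub-pixel refinement. The sign
matters: a bright rim gives a positive band-pass response at the edge,
while the filter's negative side-lobe just outside the cell would pull an
unsigned "outermost pixel" rule outward by several pixels. Frames with no
qualifying run are filled by linear interpolation and flagged; more than
10 % gaps is recorded as a warning, no edge anywhere is an error.

**Cycle delimitation.** Cycles are bounded by local minima of the 3-frame
smoothed profile, kept greedily by depth subject to a minimal separation
(20 s). Because the true reversal almost always falls *between* frames, the
sampled extrema understate the sawtooth: at a 5 s frame interval the raw
period is quantized to multiples of 5 s and the raw persistence is biased
low by ~6 %. Each extremum is therefore refined by fitting the two sawtooth
legs on either side (breakpoint searched within two frames of the sampled
extremum, legs fitted disjointly, the split with the least residual wins; a
point is dropped from a leg only if it is both a MAD outlier and more than
one pixel off) and intersecting the two lines. The period is the mean
spacing of refined minima; the persistence length is, per cycle, the
refined peak minus the refined cycle-start minimum.

**Retrograde flow.** Within each retraction window (from one frame after
the sampled protrusion maximum to one frame before the sampled minimum —
a one-frame inset absorbs the corner uncertainty) the streak slope is found
by an exhaustive scan over a signed slope grid (step 0.0025 µm/s, bound
0.3 µm/s, candidates ordered by magnitude so ties resolve to the slowest
slope — a static scene scores zero). For each candidate the window's
columns are sheared by $v\,t$ and scored by the **mean pairwise correlation**
of the aligned columns. Correlation discriminates both streak texture and
the moving edge step and is offset/gain invariant; a variance-of-average
score is insensitive to the alignment of a step whose plateaus dominate the
variance. Rows are restricted to the region from the cell body out to the
farthest edge position in the window (plus a halo margin): everything in
that band moves at the retrograde rate during retraction, while the
background beyond it is static and would otherwise dominate the score.
Because a retraction lasts $dl/v_r \approx 18$ s, flow is best measured at
the faster end of the 0.1–1 Hz acquisition range; the workflow samples flow
movies at 0.5 Hz, giving ~9 kymograph columns per retraction instead of ~4.

# Algorithm II: fractional height

The background of a plane is the exact median of its intensities. A pixel
is in focus iff its intensity lies within a tolerance of the background and
it belongs to the lamellipodium ROI. Per frame and height, in-focus pixels
are counted and normalized by the total across heights; zero-total frames
are emitted as all-zero columns and flagged.

Two declared decisions deserve explanation:

* **Tolerance.** "Equalises with the background" is degenerate under
  noise. The default band is 1.5 robust standard deviations (1.4826·MAD)
  of the plane's *background* (non-ROI) pixels. Estimating the scale from
  the background, rather than the whole plane, keeps the tolerance equal
  across planes; a whole-plane MAD inflates wherever the cell shows strong
  defocus contrast and that skew alone can invert the height readout.
* **ROI.** The region of interest is the union over the frame's planes of
  the cleaned DoG edge maps (components under 10 px are noise and dropped
  per plane), dilated by 2 px and morphologically closed (radius 4 px) to
  fill the holes a band-pass detector leaves inside smooth texture. The
  union over heights is essential: a structure is invisible in the very
  plane where it is in focus — the premise of the method — so the height-0
  map alone misses an adherent lamellipodium. Finally, pixels that stay
  within twice the tolerance of the background at *every* height carry no
  height information (they are background swept in by the dilation) and
  are removed; without this the background pedestal flattens the fractions.

The maximal reached height of a frame is the highest plane whose fraction
is at least 0.1. The method's axial resolution is set by the ~1 µm defocus
scale over which phase contrast develops: an adherent sheet can read as
1–2 µm, so differences smaller than one plane spacing are not meaningful.

# Force analysis

Deflections convert to force componentwise, $F_{x,y} = k_{xy}\,\delta_{x,y}$
and $F_z = k_z\,\delta_z$. The compensated lateral path is
`qpd + (stage - stage[1])`, with the stage axis oriented so each
recentering jump equals the bead displacement it cancelled; with a frozen
stage the compensated path is identically the raw QPD trace, and stage
jumps without a prior threshold crossing are flagged. Events are maximal
intervals with total force magnitude ≥ 1 pN lasting ≥ 2 s, merged across
gaps < 1 s. A window is vertical if its peak $|F_z|$ exceeds its peak
lateral magnitude, and a push if the dominant deflection moves the bead
away from the cell (up = away for the vertical axis; the away-from-cell
unit vector is part of the recording's configuration). The event force is
the peak of $|F_z|$ (vertical) or $\sqrt{F_x^2+F_y^2}$ (lateral). Note that
the peak of a noisy trace reads high by roughly 2.5 thermal force sd; that
bias is a property of any measured maximum, not of the pipeline.

For the protrusion rate, each compensated path is reduced to
$r(t)=\sqrt{x^2+y^2}$; a rising phase is a sustained local slope of at
least 5 nm/s over 3 s, trimmed by a relative threshold (half the run's
median slope) so the detected run does not spill past the ramp corners.
Traces without a rising phase are excluded and logged. The remaining traces
are aligned by maximizing cross-correlation with the first trace over
integer-sample lags, averaged over the common support, and the rate is the
least-squares slope of the averaged rising phase.

# Filopodium tracking

Frames are thresholded midway between the background median and the
maximum, thinned to a one-pixel skeleton (Zhang–Suen), and each tip
advances to the skeleton endpoint nearest its previous position within
10 px; losing the endpoint truncates the track and is recorded. The tip is
then refined below the pixel: the intensity profile along the base-to-tip
ray crosses half-maximum a little beyond the true tip, by exactly the
rod's own half-width at the same relative level, so the length is the
axial half-maximum crossing minus the half-width measured from
cross-sections (the minimum over three stations, robust to crossings with
other rods). Length is the straight base-to-tip distance — the fixtures
are straight rods, and this is the natural reading of a maximum length
measured on near-straight filopodia. The growth rate is the least-squares
slope of length versus time from the start of the track until the length
first comes within one pixel of its maximum (so a plateau after growth is
excluded); fewer than three such frames, or a non-positive slope, is a
"no growth phase" failure.

# Statistics

Groups are summarized as mean ± SEM (flagged undefined at $n=1$). Group
comparisons use Welch's two-sample, two-sided $t$ test — the unequal
variance form is the safe default when only "Student t-test" is specified.
Normality is checked with a chi-square goodness-of-fit against a fitted
normal: equal-probability bins (count by Sturges' rule), statistic referred
to $\mathrm{bins}-3$ degrees of freedom. The normal parameters are
estimated by minimizing the grouped chi-square itself (started at the
sample moments): with plain moment estimates the statistic is
stochastically larger than $\chi^2_{\mathrm{bins}-3}$ (the
Chernoff–Lehmann effect) and the test rejects at ~6–7 % instead of 5 %.
Under the null the implemented check rejects at 5.4 % (measured over 3000
draws at $n=500$); the calibration test estimates the rate over 1000 draws
because the binomial noise of 200 draws (sd ≈ 1.6 %) is comparable to the
±2 % band being verified.

# What a green test does and does not establish

The recovery tests establish that each estimator, run end-to-end on
recordings with the statistical structure the analysis assumes, returns
the generating parameters within stated tolerances — period and
persistence within 5 %, flow within 0.005 µm/s, forces to rounding in the
noiseless case, filopodium length within a pixel. They do not establish
performance on real phase-contrast data: the synthetic world has a single
lamellipodium with a flat front perpendicular to the sampling line, a
separable defocus model rather than real phase optics, additive Gaussian
noise, no drift, no neighbouring cells, and filopodia that are straight
and never retract. Brownian dynamics with hydrodynamic coupling, QPD
volts-to-nm calibration and trap physics are out of scope; bead deflection
is taken as given.

# Degenerate inputs and tie-breaks

Constant images give empty edge maps (not an error). Monotone or flat edge
profiles fail with "no cycles". Flat kymograph windows are skipped; if all
windows are skipped the flow measurement fails. In the slope scan, ties
resolve toward zero slope. Zero-total fractional-height frames are emitted
as zeros and flagged. Zero-variance groups fail both the $t$ test and the
normality check with explicit messages. The feedback simulator rejects
overlapping events and negative speeds or durations; the imaging
configuration rejects frame intervals outside the stated 0.1–1 Hz
acquisition range.
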