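---
title: "Self-gated radial flow imaging and QA-method pulse-wave velocity: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-gated radial flow imaging and QA-method pulse-wave velocity: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
acquisition and reconstruction model, the self-gating chain, the flow-area
(QA) estimator, what the synthetic phantom does and does not emulate, and
the design decisions taken where the method description left choices open.

## 1. Acquisition model

The sequence model is a motion-compensated radial FLASH with through-plane
velocity encoding: three sequential velocity-encoding steps with reduced
first gradient moments `m1 = gamma*M1/2pi` of 0 and ±0.3 s/m, so that a
spin moving at velocity `v` acquires phase `2*pi*m1*v` and the maximum
encoding velocity is `VENC = 1/(2*max|m1|) = 1.67 m/s` (printed as 1.7).
Geometry and timing are pure configuration (`acq_config()`): TR 3 ms, TE
1.2 ms, 90 readout points at 75.8 kHz with the gradient echo at 10 % of the
readout, 160 reconstruction matrix over a 24 mm field of view, 16000
projections per encoding and 15 s pauses between encodings (total 2.9 min).
Gradient waveforms themselves are not simulated; a per-axis gradient delay
enters as a first-order translation of each projection in k-space
(`apply_gradient_delays()`), with `correct_gradient_delays()` as its exact
inverse — mirroring the dephase-area correction applied on a scanner.
Because the scanner correction acts *before* the data are sampled, the
pipeline default assumes compensated delays; simulating uncorrected delays
is still possible and shows the classic radial self-gating failure mode,
where the off-centre echo sample turns the sublist ordering into a
quasi-periodic navigator interference near the heart rate.

Projection angles follow the golden-angle increment `180/phi = 111.246°`
over the full circle (the asymmetric echo makes θ and θ+180° inequivalent),
re-sorted into `N = round(T_RR_est/TR)` interleaved sublists of
`K = floor(n_proj/N)` (`sublist_plan()`). Projections acquired one estimated
heartbeat apart are then consecutive golden-angle indices, so a
retrospectively selected frame inherits a near-uniform angle set. When `N`
does not divide `n_proj`, the remaining acquisitions continue the interleave
cycle and the first sublists carry one extra member; the permutation remains
a bijection. This remainder rule and the rounding of `N` are package
decisions — the ordering is only specified "approximately" — chosen to keep
sublist sizes within one of each other.

## 2. The digital phantom and its forward model

`phantom_config()` defines a pulsating lumen inside a tissue ellipse. The
study conditions are the defaults: true PWV 2.3 m/s, diastolic area
0.61 mm² rising to 0.73 mm², an 8 ms early-systolic upstroke, cardiac
intervals 107.2 ± 4.1 ms (i.i.d. Gaussian, truncated at ±4 s.d.), 150 ms
respiratory bursts every 800 ms with a 0.3 mm in-plane shift, and a local
off-resonance blob at the vessel.

Design choices worth knowing:

* **QA construction.** During the upstroke `Q = PWV_true*(A - A_dia)`
  exactly, so the ground-truth QA slope *is* the configured PWV. The
  upstroke is linear in time (constant dQ/dt, the usual reflection-free
  early-systole idealization); area and flow decay afterwards with
  different time constants (30 vs 15 ms), giving the physiological QA
  hysteresis loop outside the fit window. Beats are realized with a fixed
  absolute systole duration — diastole absorbs the RR variability — which
  is both physiological and necessary for trigger timing to be meaningful
  at millisecond scale.
* **Velocity profile** is parabolic (Poiseuille), giving the analytic link
  `v_max = 2*Q/A` used in tests. Pulsatile aortic flow at Womersley number
  ≈ 2 is in truth somewhat blunted; the profile shape turned out to be
  irrelevant for the estimator's accuracy (flux is integrated), so the
  simpler model was kept.
* **Blood/tissue contrast.** At TR 3 ms static tissue is strongly
  saturated while through-plane flow refreshes the blood; the lumen is
  modelled at twice the tissue signal plus an inflow term
  `(1 + beta*vbar/VENC)` with `beta = 1`. These are free morphology knobs:
  they were set so the navigator shows the published morphology (clear
  cardiac oscillation with sparse breathing bumps) and the cine shows a
  clearly delineated vessel, and tests do not depend on their exact values
  beyond trigger detection succeeding.
* **Respiration** is a rigid translation plus a 1 % through-slice signal
  modulation during each burst. A pure translation would be invisible to
  the k-centre navigator (the DC sample is translation invariant), so the
  signal term is what makes navigator-based respiratory gating physically
  possible; the translation still corrupts the projections that the gating
  is supposed to discard.
* **Off-resonance** defaults to a mild 100 Hz post-shim residual so the
  mapping/correction chain is exercised end to end; `b0_peak = 600`
  reproduces the severe unshimmed regime in which the vessel is unusable
  without conjugate-phase correction (used by the correction-benefit
  tests).
* **Forward model.** The image is rasterized (anti-aliased coverage) at
  256²; the static background is transformed by a fast type-2 NUFFT and
  the dynamic box around the vessel (lumen + off-resonance blob) by an
  exact phase-recurrence non-uniform DFT, with off-resonance phase accruing
  from excitation at every sample. The vessel state is quantized to 200
  cardiac-phase bins (0.5 ms at the default RR). Noise is circular complex
  Gaussian with s.d. expressed as a fraction (4e-4) of the tissue k-centre
  magnitude, which puts the fully sampled image SNR at the order expected
  for high-field CMR microscopy. Everything is reproducible bit-for-bit
  from the seed.

## 3. Self-gating

The navigator is the echo (k-centre) sample of every projection; the first
1.5 s (500 projections at TR 3 ms) are discarded while the signal approaches
steady state. Magnitude, real and imaginary channels are compared by
cardiac-band (5–15 Hz) power after detrending and the strongest is kept,
with the tie-break magnitude > real > imaginary.

Filtering is a zero-phase Butterworth low-pass followed by the Gaussian
high-pass `w(f) = 1 − exp(−(f/σ)²)`, σ = 6 Hz. The low-pass is applied in
the frequency domain with the squared analytic Butterworth magnitude, which
is numerically identical to forward–backward filtering at any order. The
band edges default to pass 10 Hz / stop 20 Hz — the widest transition inside
the stated 10–13 / 15–20 Hz ranges — because the minimal-order design at
(13, 15) is order ≈ 33 and its long ringing couples neighbouring heartbeats,
adding trigger jitter under RR variability; (10, 20) gives order 7.

Triggers: the filtered navigator is linearly interpolated to TR/10, local
maxima are found with a 50 ms refractory period (well under the ~107 ms
cycle; larger peaks win), and each trigger is the first interpolated sample
of that cycle above 90 % of its local maximum. Two non-obvious points:

* **Polarity.** Depending on the off-resonant phase of the blood pool and
  the velocity encoding, the k-centre flow event can be a dip rather than a
  bump, and the near-sinusoidal filtered signal locks triggers stably onto
  either lobe — half a cycle apart, and possibly differently per encoding,
  which would misalign the encodings' frames. `orient_triggers()` resolves
  this per encoding by locating the peak of the phase-locked
  |raw-navigator deviation| profile: if it falls mid-cycle rather than just
  after the trigger, the signal is negated and triggers are re-detected.
* **Timing floor.** A navigator band-limited at 10–13 Hz cannot localize
  9.3 Hz beats to sub-millisecond precision under 4.1 ms RR variability:
  the HRV sidebands of the pulse train are partly filtered away and the
  detected intervals regress toward the mean. The measured floor is
  ~1.5–2 ms mean absolute interval error in the breath-free, noise-free
  case, independent of the band-edge choice; this is a property of the
  published filtering chain, not of the implementation.

Respiratory gating thresholds the low-frequency residual (the component
removed by the high-pass) against a running median at 4 MADs, dilated by a
±30 ms guard. Projections inside these windows are set to relative position
−1, and — because triggers derived from breath-corrupted navigator segments
are wrong, not merely noisy — whole cycles bounded by such a trigger are
gated out too. Remaining projections get `rel = (t − T_i)/(T_{i+1} − T_i)`,
and the ±0.5 ms sliding window assigns them to 100 equidistant frames
(temporal distance measured in absolute milliseconds within each
projection's own cycle; one projection may serve several frames).

## 4. Reconstruction

Each frame/encoding subset is density-compensated with Pipe's fixed-point
iteration `w ← w/(w ⊛ C)` (15 iterations, convergence logged), recomputed
per frame because every frame has its own angle subset. Gridding uses a
width-4 Kaiser–Bessel kernel on a 2× oversampled grid with the standard
minimum-aliasing β and analytic deapodization; images are cropped to 160²
and zero-filled to 256² by symmetric k-space padding (93.75 µm pixels).

Off-resonance handling follows the conjugate-phase model: the field map is
the phase of the conjugate product of two echoes 0.5 ms apart,
`Δω0 = ΔΦ/ΔTE`, masked by magnitude and unwrapped with a quality-guided
2-D region growth when neighbouring jumps exceed π. The corrected image
`ρ(r) = Σ_j w_j s_j exp(−iΔω0(r) t_j) exp(2πi k_j·r)` is evaluated by time
segmentation: 8 segment centres across the readout, least-squares
interpolation coefficients computed against the histogram of map values
(via an SVD pseudo-inverse, so single-valued maps are handled exactly), and
one gridded adjoint per segment. Sample times run from excitation with the
echo at TE. A zero map short-circuits to the plain adjoint, and an exact
per-pixel evaluator is kept as the test oracle; accuracy increases
monotonically with the segment count on the test problems.

## 5. Flow quantification

Velocities come from a least-squares line through the origin of the
unwrapped phase (relative to the flow-compensated encoding) versus
`2*pi*m1`. Segmentation is automated in two passes: an Otsu threshold on
the time-mean region of interest bootstraps the vessel centroid and radius,
then each frame is thresholded at the midpoint of its lumen level (core
mean) and tissue level (outer-ring median) — for a blurred edge this
crossing sits at the geometric boundary regardless of the inflow-driven
brightness, which plain per-frame Otsu (noisy) and any fixed threshold
(brightness-biased) both fail to achieve on the ~2 px/frame area signal.
Area is the mask count times the pixel area; flow integrates the velocity
map over the mask dilated by one resolution element (2 px at 93.75 µm), the
usual phase-contrast practice for catching the point-spread-spread flux just
outside the boundary (without it the flux is ~30 % low at this vessel size).

Both curves are smoothed by a centred 5-frame moving average. The upstroke
detector walks back from the flow peak to the last frame within 10 % of the
baseline-to-peak range and fits from the next frame until the curve reaches
60 % of the peak (at most 8, at least 5 points; it never crosses the peak,
and the search is circular because retrospective triggering can place the
upstroke across the frame 99→0 boundary). Mixing diastolic samples into
early-upstroke frames is harmless by construction — diastole lies on the
same QA line — which is what makes the fit robust to the trigger-timing
floor. The PWV is the ordinary least-squares slope of Q on A over that
range, in m/s with SI inputs, reported with its standard error and R².

## 6. What passing tests do and do not show

The phantom emulates the features the method must survive — cardiac
variability, breaths, inflow-locked navigator, off-resonance, delays,
noise — but not everything about real data: no T1/T2 relaxation dynamics,
no eddy-current phase errors, a rigid (not deforming) respiratory motion, a
single receive channel, and a circular lumen. Parameter recovery on the
phantom therefore demonstrates the correctness and calibration of the
chain, not in-vivo accuracy.

Two quantitative limits are worth stating because the test suite reports
them honestly:

* **Trigger intervals** match the simulated beats to ~2 ms (breath-free),
  not better, for the band-limitation reason above; beat counts match on
  breath-free segments.
* **PWV recovery** at the full protocol (16000 projections, ~80 usable
  spokes per frame after gating) has median relative error around 10–15 %
  over seeds, limited by residual partial-volume flux and streak-induced
  velocity dilution. At a 4-fold reduced train (4000 projections, ~20
  spokes per frame) the adjoint-gridding reconstruction loses a further
  ~25 % of the lumen flux to undersampling streaks and the area waveform
  becomes threshold-noise dominated, so recovery degrades to tens of
  percent — a physical property of non-iterative reconstruction at 20–25×
  undersampling (iterative reconstruction is deliberately out of scope).

Problem sizes used by the test suite reflect these regimes: oracle
comparisons run at 32²–64² with a few hundred samples, gating properties at
3000–4000 projections, and the end-to-end recovery checks at 4000 and 16000
projections per encoding.

## 7. Degenerate inputs and numerical conventions

k-space is measured in cycles per field of view (unit grid spacing), image
coordinates in FOV units with the DC pixel at index n/2, forward transforms
use `exp(−2πi k·x)`. Even matrix sizes are assumed throughout. Pipe
iterations clamp non-positive denominators with a warning; empty cine
frames are filled from the nearest populated frame and flagged; flat
segmentation ROIs, missing lumen contrast, all-zero navigators, fewer than
two triggers, constant-area fit ranges and sub-5-point upstrokes raise
classed errors (`radialpwv_config_error`, `_gating_error`,
`_segmentation_error`, `_resolution_error`) that the command-line wrapper
maps to exit codes 2/3/4.
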