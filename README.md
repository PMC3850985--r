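# radialpwv

Retrospectively self-gated radial phase-contrast cine MRI and local
pulse-wave velocity (PWV) estimation for small pulsating vessels, together
with a dynamic digital phantom that makes the whole chain testable without a
scanner.

## The problem

Aortic PWV — the propagation speed of the systolic pressure/flow pulse — is
a standard marker of arterial stiffness, and mouse models make it an
important preclinical readout. Prospectively triggered CMR measurements of
PWV need ECG or pressure-balloon probes, which are fragile at high field and
awkward inside small-bore coils. The alternative implemented here is fully
retrospective: a motion-compensated radial FLASH sequence with a short TR
(3 ms) and a highly asymmetric echo (10 % of the readout) acquires a long
untriggered train of projections per velocity encoding; because every radial
projection samples the k-space centre, the centre signal itself is a
navigator that carries cardiac and respiratory modulation. After the scan
the navigator is filtered, cardiac trigger points are detected, every
projection gets a relative position in its heart cycle (respiration is gated
out), and 100 cine frames are reconstructed by non-uniform FFT gridding.

The local PWV then follows from the flow–area (QA) method: during the
reflection-free early systole,

    PWV = dQ / dA,

the slope of volume flow Q(t) against lumen cross-sectional area A(t), both
measured per cine frame from the velocity maps (three-point phase-contrast
encoding, VENC 1.7 m/s) and an automated segmentation of the vessel.

Key ingredients, each its own module:

* **trajectory** — modified golden-angle ordering (increment 180°/φ ≈
  111.246°) sorted into N ≈ T_RR/TR heartbeat-interleaved sublists, so the
  projections retrospectively binned into one frame are themselves
  golden-angle distributed; asymmetric radial sample positions; a linear
  gradient-delay model with its inverse correction.
* **phantom** — a pulsating-lumen digital phantom with known PWV (the
  upstroke is constructed so that Q = PWV·(A − A_dia) holds exactly),
  cardiac-interval variability, respiratory bursts, inflow enhancement,
  a local off-resonance field, and complex Gaussian noise, driven through an
  exact MR forward model.
* **selfgating** — navigator extraction and channel selection, zero-phase
  Butterworth low-pass plus Gaussian high-pass `w(f) = 1 − exp(−(f/σ)²)`,
  trigger detection at 90 % of each local maximum on a 10× interpolated
  grid, respiratory gate-out, and ±0.5 ms sliding-window frame selection.
* **recon** — Pipe's iterative density compensation, Kaiser–Bessel gridding
  (2× oversampled, width-4 kernel), two-echo B0 mapping (ΔTE = 0.5 ms) with
  quality-guided phase unwrapping, and time-segmented conjugate-phase
  off-resonance correction with an exact slow evaluator as oracle.
* **flowquant** — per-pixel phase-vs-moment velocity fit, automated
  midlevel vessel segmentation, Q/A curves with moving-average smoothing,
  early-upstroke detection, and the linear QA fit.
* **pipeline** — configuration (YAML), orchestration, container I/O and
  CSV/JSON/NIfTI export; a thin command-line wrapper lives in `inst/cli`.

## Worked example

```r
library(radialpwv)

run <- run_pipeline(run_config(seed = 1))
#> simulate: 3 encodings x 16000 projections, 36 sublists, scan 174.0 s (2.9 min)
#> gate enc 1: channel magnitude, 383 triggers (RR 121.4 +/- 28.8 ms), 81 members/frame
#> gate enc 2: channel real, 400 triggers (RR 116.1 +/- 20.7 ms), 75 members/frame
#> gate enc 3: channel real, 389 triggers (RR 119.5 +/- 26.8 ms), 79 members/frame
#> b0 map: -28..101 Hz
#> pwv: 2.03 +/- 0.13 m/s (R^2 0.987, 5 points)

round(run$summary, 4)
#>   mean_rr_s sd_rr_s n_triggers frame_rate_fps mean_members_per_frame
#> 1    0.1086   0.008       1172            921                78.2567
#>   gated_out_fraction temporal_blur_ms peak_csa_mm2 peak_flow_cm3s pwv_m_s
#> 1              0.458           0.2863       0.7453         0.2515  2.0268
```

The phantom's true PWV is 2.3 m/s with a peak lumen area of 0.73 mm² and a
peak flow of 0.276 cm³/s; the run above recovers the area and flow scales
directly and the PWV within roughly 10–15 %. `autoplot(run$fit)` draws the
Q(A) loop with the fitted early-systolic line, `plot_navigator()` and
`plot_qa_curves()` show the gating signal and the per-frame curves, and
`write_run_outputs(run, "out/")` exports navigator CSVs, cine NIfTI volumes,
the Q/A table and the PWV JSON.

Individual stages compose in the usual way, e.g.

```r
sim <- simulate_acquisition(phantom_config(), acq_config(n_proj = 4000))
nav <- extract_navigator(sim, encoding = 1) |> select_channel() |> filter_navigator()
trig <- detect_triggers(nav)
```

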