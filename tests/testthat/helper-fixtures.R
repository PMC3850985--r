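# Shared fixtures: small acquisition/phantom configurations and synthetic
# navigator/trigger constructors. Everything is generated in code.

small_acq <- function(n_proj = 600, ...) {
  acq_config(n_proj = n_proj, ...)
}

# phantom without the stochastic/confounding components: no respiration, no
# off-resonance, no steady-state transient
quiet_phantom <- function(b0_peak = 0, ...) {
  phantom_config(resp_shift = 0, resp_signal_frac = 0, b0_peak = b0_peak,
                 transient_frac = 0, ...)
}

# a nearly static phantom: the area waveform collapses to its diastolic value
static_phantom <- function(...) {
  quiet_phantom(a_peak = 0.61e-6 * (1 + 1e-9), ...)
}

mk_nav <- function(value, tr = 3e-3, t0 = 0) {
  n <- length(value)
  out <- tibble::tibble(projection = seq_len(n),
                        time = t0 + (seq_len(n) - 1) * tr,
                        value = value)
  structure(out, class = c("navigator", class(out)),
            tr = tr, n_discarded = 0L, channel = "magnitude")
}

mk_triggers <- function(times) {
  out <- tibble::tibble(time = times)
  structure(out, class = c("trigger_set", class(out)),
            intervals = diff(times), interpolation_factor = 10)
}

# uniform full-circle asymmetric radial sampling (echo at 10 %)
uniform_radial <- function(n_spokes, n_readout = 90, idx_echo = 9) {
  ang <- seq(0, 360, length.out = n_spokes + 1)[seq_len(n_spokes)]
  cc <- (0:(n_readout - 1)) - idx_echo
  list(kx = as.vector(outer(cc, cos(ang * pi / 180))),
       ky = as.vector(outer(cc, sin(ang * pi / 180))),
       angles = ang, c = cc)
}

nrmse <- function(x, ref) sqrt(mean(Mod(x - ref)^2)) / sqrt(mean(Mod(ref)^2))

# least-squares magnitude scale match before image comparison
scale_match <- function(x, ref) {
  a <- sum(x * ref) / sum(x * x)
  x * a
}

expect_config_error <- function(expr) {
  expect_error(expr, class = "radialpwv_config_error")
}
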