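# Run configuration, orchestration of the full chain (simulate -> gate ->
# reconstruct -> quantify), container I/O and result export.

default_run_config <- function() {
  list(seed = 1L,
       outdir = ".",
       phantom = list(),
       acquisition = list(),
       filter = list(),
       delays = list(t_x = 0, t_y = 0),
       gating = list(t_rr_est = 107.2e-3, n_frames = 100,
                     window_halfwidth = 0.5e-3, interpolation_factor = 10,
                     refractory = 0.05, k_resp = 4, guard = 0.03),
       recon = list(b0_correction = TRUE, n_segments = 8, zero_fill = 256,
                    os = 2, width = 4, n_iterations = 15,
                    b0_probe_spokes = 600, delta_te = 0.5e-3),
       flowquant = list(smoothing_window = 5, n_points_max = 8,
                        roi_halfwidth = 12, seed_point = NULL))
}

merge_block <- function(defaults, user, block) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    abort_config(sprintf("unknown key(s) in '%s': %s", block,
                         paste(unknown, collapse = ", ")))
  for (nm in names(user)) defaults[nm] <- list(user[[nm]])   # keeps NULLs
  defaults
}

#' Build a run configuration
#'
#' Nested configuration of a full pipeline run. Every block mirrors the
#' corresponding constructor ([phantom_config()], [acq_config()],
#' [filter_spec()]); unknown keys are rejected. The defaults reproduce the
#' retrospective protocol and phantom study conditions.
#'
#' @param ... named blocks / scalars overriding the defaults: `seed`,
#'   `outdir`, `phantom`, `acquisition`, `filter`, `delays`, `gating`,
#'   `recon`, `flowquant`.
#' @return an object of class `run_config` (nested list).
#' @export
run_config <- function(...) {
  user <- list(...)
  def <- default_run_config()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    abort_config(sprintf("unknown configuration block(s): %s",
                         paste(unknown, collapse = ", ")))
  cfg <- def
  for (nm in names(user)) {
    if (nm %in% c("seed", "outdir")) {
      cfg[[nm]] <- user[[nm]]
    } else if (nm %in% c("phantom", "acquisition", "filter")) {
      # validated by the constructors at run time; check key names here
      ctor <- switch(nm, phantom = phantom_config, acquisition = acq_config,
                     filter = filter_spec)
      unknown <- setdiff(names(user[[nm]]), names(formals(ctor)))
      if (length(unknown))
        abort_config(sprintf("unknown key(s) in '%s': %s", nm,
                             paste(unknown, collapse = ", ")))
      cfg[[nm]] <- modifyList(cfg[[nm]], user[[nm]])
    } else {
      cfg[[nm]] <- merge_block(def[[nm]], user[[nm]], nm)
    }
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The YAML file holds the same nested blocks as [run_config()]; unknown
#' keys are rejected on read, and numeric values round-trip at full
#' precision.
#'
#' @param path file path.
#' @param cfg a `run_config`.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  writeLines(yaml::as.yaml(unclass(cfg), precision = 15), path)
  invisible(path)
}

# ---- k-space container ------------------------------------------------------

#' Write / read the k-space container
#'
#' Single-file container for a (simulated or converted) radial flow
#' acquisition: complex k-space per velocity encoding, the trajectory
#' (positions in cycles/FOV, per-sample times), the acquisition metadata,
#' and optionally the ground-truth group. Stored as an RDS file with a
#' versioned schema (`radialpwv-kspace-v1`); complex data are R complex
#' vectors (paired doubles, native byte order as documented by RDS).
#'
#' @param projset a `projection_set`.
#' @param path output file.
#' @param ground_truth include the ground-truth group.
#' @return `write_kspace_container()` returns `path` invisibly;
#'   `read_kspace_container()` returns a `projection_set`.
#' @export
write_kspace_container <- function(projset, path, ground_truth = TRUE) {
  obj <- list(schema = "radialpwv-kspace-v1",
              kspace = projset$kspace,
              trajectory = projset$traj[c("angles", "kx", "ky", "t_read",
                                          "t_proj", "delays")],
              meta = list(acq = unclass(projset$acq),
                          phantom = if (!is.null(projset$phantom))
                            unclass(projset$phantom),
                          venc = projset$venc, seed = projset$seed,
                          enc_starts = projset$enc_starts),
              proj_times = projset$proj_times,
              ground_truth = if (ground_truth) projset$ground_truth)
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' @rdname write_kspace_container
#' @export
read_kspace_container <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "radialpwv-kspace-v1"))
    abort_config("not a radialpwv k-space container")
  acq <- structure(obj$meta$acq, class = "acq_config")
  traj <- structure(c(obj$trajectory, list(acq = acq)),
                    class = "radial_trajectory")
  structure(list(kspace = obj$kspace, traj = traj, acq = acq,
                 phantom = if (!is.null(obj$meta$phantom))
                   structure(obj$meta$phantom, class = "phantom_config"),
                 venc = obj$meta$venc, enc_starts = obj$meta$enc_starts,
                 proj_times = obj$proj_times, seed = obj$meta$seed,
                 ground_truth = obj$ground_truth),
            class = "projection_set")
}

# ---- pipeline stages --------------------------------------------------------

build_configs <- function(cfg) {
  list(phantom = do.call(phantom_config, cfg$phantom),
       acq = do.call(acq_config, cfg$acquisition),
       fspec = do.call(filter_spec, cfg$filter))
}

#' Simulate an acquisition from a run configuration
#'
#' Builds the sublist-sorted golden-angle trajectory (using the gating
#' block's interval estimate), applies the configured gradient delays, and
#' runs the MR forward model.
#'
#' @param cfg a [run_config()].
#' @param verbose log one line per stage.
#' @return a `projection_set`.
#' @export
simulate_run <- function(cfg, verbose = TRUE) {
  cc <- build_configs(cfg)
  plan <- sublist_plan(cc$acq$n_proj, cc$acq$tr, cfg$gating$t_rr_est)
  traj <- radial_trajectory(cc$acq, plan = plan)
  if (cfg$delays$t_x != 0 || cfg$delays$t_y != 0)
    traj <- apply_gradient_delays(traj, cfg$delays$t_x, cfg$delays$t_y)
  sim <- simulate_acquisition(cc$phantom, cc$acq, traj, seed = cfg$seed)
  if (verbose)
    message(sprintf(
      "simulate: %d encodings x %d projections, %d sublists, scan %.1f s (%.1f min)",
      cc$acq$n_encodings, cc$acq$n_proj, plan$n_sublists,
      scan_duration(cc$acq), scan_duration(cc$acq) / 60))
  sim
}

#' Self-gate one projection set
#'
#' Runs navigator extraction, channel selection, filtering, trigger
#' detection, phase assignment with respiratory gate-out and frame selection
#' independently for every velocity encoding.
#'
#' @param sim a `projection_set`.
#' @param cfg a [run_config()].
#' @param verbose log one line per encoding.
#' @return list with per-encoding `navigators`, `triggers`, `phase_maps`,
#'   `frames`.
#' @export
gate_run <- function(sim, cfg, verbose = TRUE) {
  cc <- build_configs(cfg)
  ne <- length(sim$kspace)
  navs <- trigs <- pms <- frs <- vector("list", ne)
  for (e in seq_len(ne)) {
    nav <- filter_navigator(select_channel(extract_navigator(sim, e)), cc$fspec)
    ot <- orient_triggers(nav, cfg$gating$interpolation_factor,
                          refractory = cfg$gating$refractory)
    nav <- ot$nav
    tg <- ot$triggers
    pm <- assign_cardiac_phase(nav, tg, times = sim$proj_times[, e],
                               projections = seq_len(sim$acq$n_proj),
                               k_resp = cfg$gating$k_resp,
                               guard = cfg$gating$guard)
    fr <- suppressWarnings(
      select_frames(pm, cfg$gating$n_frames, cfg$gating$window_halfwidth))
    navs[[e]] <- nav; trigs[[e]] <- tg; pms[[e]] <- pm; frs[[e]] <- fr
    if (verbose) {
      g <- glance.frame_selection(fr)
      message(sprintf(
        "gate enc %d: channel %s, %d triggers (RR %.1f +/- %.1f ms), %.0f members/frame",
        e, attr(nav, "channel"), nrow(tg),
        mean(attr(tg, "intervals")) * 1e3, sd(attr(tg, "intervals")) * 1e3,
        g$mean_members))
    }
  }
  list(navigators = navs, triggers = trigs, phase_maps = pms, frames = frs)
}

#' Measure the off-resonance map for a run
#'
#' Simulates the two-echo probe pair, reconstructs both echoes with Pipe
#' density compensation and the gridded adjoint, and derives the field map.
#'
#' @param sim a `projection_set` (supplies phantom and acquisition).
#' @param cfg a [run_config()].
#' @param verbose log the result.
#' @return a [b0_map()] at the reconstruction matrix size.
#' @export
measure_b0_run <- function(sim, cfg, verbose = TRUE) {
  probe <- simulate_b0_probe(sim$phantom, sim$acq,
                             n_spokes = cfg$recon$b0_probe_spokes,
                             delta_te = cfg$recon$delta_te,
                             delays = c(cfg$delays$t_x, cfg$delays$t_y),
                             seed = sim$seed + 77L)
  kx <- as.vector(probe$traj$kx); ky <- as.vector(probe$traj$ky)
  dcf <- pipe_dcf(kx, ky, sim$acq$matrix, cfg$recon$os, cfg$recon$width,
                  n_iterations = cfg$recon$n_iterations)
  i1 <- gridded_adjoint(as.vector(probe$s1), kx, ky, dcf, sim$acq$matrix,
                        cfg$recon$os, cfg$recon$width)
  i2 <- gridded_adjoint(as.vector(probe$s2), kx, ky, dcf, sim$acq$matrix,
                        cfg$recon$os, cfg$recon$width)
  omap <- b0_map(i1, i2, probe$delta_te)
  if (verbose)
    message(sprintf("b0 map: %.0f..%.0f Hz%s", min(omap$hz), max(omap$hz),
                    if (omap$unwrapped) " (unwrapped)" else ""))
  omap
}

#' Run the complete pipeline
#'
#' simulate -> self-gate -> (optional) field mapping -> cine reconstruction
#' -> velocity mapping -> segmentation -> Q/A curves -> PWV fit.
#'
#' @param cfg a [run_config()].
#' @param verbose log one line per stage.
#' @return an object of class `pwv_run` holding all intermediate results,
#'   the [fit_pwv()] result (`$fit`) and a one-row summary tibble
#'   (`$summary`, see [summarize_run()]).
#' @export
run_pipeline <- function(cfg = run_config(), verbose = TRUE) {
  sim <- simulate_run(cfg, verbose)
  gat <- gate_run(sim, cfg, verbose)
  omap <- NULL
  if (isTRUE(cfg$recon$b0_correction) && sim$phantom$b0_peak != 0)
    omap <- measure_b0_run(sim, cfg, verbose)
  cine <- reconstruct_cine(sim, gat$frames, omap = omap,
                           n_segments = cfg$recon$n_segments,
                           zero_fill_matrix = cfg$recon$zero_fill,
                           os = cfg$recon$os, width = cfg$recon$width,
                           n_iterations = cfg$recon$n_iterations)
  vcine <- velocity_cine(cine)
  seed_point <- cfg$flowquant$seed_point
  if (is.null(seed_point)) {
    nz <- cine$zero_fill_matrix
    seed_point <- round(sim$phantom$vessel_center / sim$acq$fov * nz) +
      nz / 2 + 1
  }
  mag <- cine_magnitude(cine)
  masks <- segment_cine(mag, seed_point, cfg$flowquant$roi_halfwidth)
  curves <- qa_curves(vcine, masks,
                      smoothing_window = cfg$flowquant$smoothing_window)
  fit <- fit_pwv(curves, n_points_max = cfg$flowquant$n_points_max)
  run <- structure(list(config = cfg, sim = sim, gating = gat, b0 = omap,
                        cine = cine, vcine = vcine, masks = masks,
                        curves = curves, fit = fit,
                        seed_point = seed_point),
                   class = "pwv_run")
  run$summary <- summarize_run(run)
  if (verbose)
    message(sprintf("pwv: %.2f +/- %.2f m/s (R^2 %.3f, %d points)",
                    fit$pwv, fit$slope_stderr, fit$r_squared,
                    fit$n_fit_points))
  run
}

#' Summarize a pipeline run
#'
#' Pools the per-encoding trigger intervals (as done when reporting the
#' interval histogram) and reports mean/SD RR, the achieved frame rate
#' `n_frames / mean RR` (integer-rounded), mean projections per frame, the
#' respiratory gated-out fraction, the temporal blur of the frames, peak
#' area and flow, and the fitted PWV.
#'
#' @param run a [run_pipeline()] result.
#' @return one-row tibble.
#' @export
summarize_run <- function(run) {
  iv <- unlist(lapply(run$gating$triggers, function(t) attr(t, "intervals")))
  # robust centre/width, matching the Gaussian fit used for the interval
  # histogram (breath-corrupted triggers leave heavy outliers)
  mean_rr <- median(iv)
  n_frames <- run$cine$n_frames
  members <- vapply(run$gating$frames, function(f)
    glance.frame_selection(f)$mean_members, numeric(1))
  blur <- vapply(run$gating$frames, function(f)
    glance.frame_selection(f)$temporal_blur_s, numeric(1))
  # gated-out fraction among projections inside the triggered window
  gated <- vapply(seq_along(run$gating$phase_maps), function(e) {
    pm <- run$gating$phase_maps[[e]]
    tg <- attr(pm, "triggers")
    inw <- pm$time >= tg[1] & pm$time <= tg[length(tg)]
    mean(pm$rel_position[inw] == -1)
  }, numeric(1))
  tibble(mean_rr_s = mean_rr, sd_rr_s = mad(iv),
         n_triggers = sum(vapply(run$gating$triggers, nrow, numeric(1))),
         frame_rate_fps = round(n_frames / mean_rr),
         mean_members_per_frame = mean(members),
         gated_out_fraction = mean(gated),
         temporal_blur_ms = mean(blur) * 1e3,
         peak_csa_mm2 = max(run$curves$a_smooth) * 1e6,
         peak_flow_cm3s = max(run$curves$q_smooth) * 1e6,
         pwv_m_s = run$fit$pwv, pwv_stderr_m_s = run$fit$slope_stderr,
         r_squared = run$fit$r_squared,
         n_fit_points = run$fit$n_fit_points)
}

#' @export
print.pwv_run <- function(x, ...) {
  cat("<pwv_run>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Write the result bundle of a run
#'
#' Navigator CSV (time, raw, filtered, relative position), trigger summary
#' JSON, cine and field-map NIfTI volumes, Q/A curves CSV, PWV JSON, and a
#' run log (seed, package version, summary).
#'
#' @param run a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return the output directory, invisibly.
#' @export
write_run_outputs <- function(run, outdir = run$config$outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (e in seq_along(run$gating$navigators)) {
    nav <- run$gating$navigators[[e]]
    pm <- run$gating$phase_maps[[e]]
    rel <- pm$rel_position[match(nav$projection, pm$projection)]
    write.csv(data.frame(time = nav$time, raw = nav$raw,
                         filtered = nav$value, rel_position = rel),
              file.path(outdir, sprintf("navigator_enc%d.csv", e)),
              row.names = FALSE)
  }
  trig_sum <- lapply(run$gating$triggers, function(t) {
    iv <- attr(t, "intervals")
    list(n_triggers = nrow(t), mean_rr_s = mean(iv), sd_rr_s = sd(iv))
  })
  jsonlite::write_json(trig_sum, file.path(outdir, "triggers.json"),
                       auto_unbox = TRUE, digits = NA)
  write_cine_nifti(run$cine, file.path(outdir, "cine"))
  if (!is.null(run$b0))
    write_b0_nifti(run$b0, file.path(outdir, "b0_map.nii.gz"),
                   run$sim$acq$fov / run$sim$acq$matrix)
  cv <- run$curves
  write.csv(data.frame(frame = cv$frame, a_mm2 = cv$a * 1e6,
                       q_cm3s = cv$q * 1e6, a_smooth_mm2 = cv$a_smooth * 1e6,
                       q_smooth_cm3s = cv$q_smooth * 1e6),
            file.path(outdir, "qa_curves.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(pwv_m_s = run$fit$pwv, slope_stderr_m_s = run$fit$slope_stderr,
         r_squared = run$fit$r_squared, n_fit_points = run$fit$n_fit_points,
         fit_frames = run$fit$fit_indices),
    file.path(outdir, "pwv.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = "radialpwv",
         version = as.character(utils::packageVersion("radialpwv")),
         seed = run$config$seed,
         summary = as.list(run$summary)),
    file.path(outdir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
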