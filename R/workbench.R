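#' Run configuration
#'
#' Fully serializable parameter set for an end-to-end synthetic run:
#' simulation scenario (scalar parameters only, so YAML round trips are the
#' identity), schedule, camera, and every stage parameter. The default
#' configuration is a compact two-source / two-detector block-design
#' scenario with flow (rDB-1) and absorption (dOD) modulation planted on
#' source 1, sized to run end-to-end in seconds.
#'
#' @param ... named overrides of the defaults listed below.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    method = "gamma",
    # schedule / camera
    n_sources = 2L, slot_ms = 10, on_ms = 5.2, exposure_ms = 4,
    gain = 0.5, black_level = 25, bit_depth = 10L, read_noise_e = 2.1,
    # scenario
    n_detectors = 2L, rows = 28L, cols = 28L,
    beta = 0.16, tau_c = 1e-3, mean_flux = 50,
    active_source = 1L, flow_amplitude = 0.5, absorption_amplitude = 0.98,
    initial_rest = 20, n_blocks = 4L, stim_duration = 5, block_period = 20,
    # stage parameters
    window = 7L, n_dark_frames = 200L, ksp = "none",
    flux_threshold = 4, motion_z = 5,
    lowpass_cutoff = 1.0, lowpass_order = 5,
    baseline_interval = c(0, 18),
    epoch_window = c(-2, 10), epoch_baseline = c(-2, 0),
    stats_window = c(1, 4.5), alpha = 0.05,
    events_file = NULL, manual_mask_file = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Serialize-parse-serialize is the identity.
#'
#' @param config a [run_config()].
#' @param path YAML path.
#' @return `path` (write) or a [run_config()] (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

cfg_schedule <- function(cfg)
  multiplex_schedule(cfg$n_sources, cfg$slot_ms, cfg$on_ms, cfg$exposure_ms)

cfg_camera <- function(cfg)
  camera_spec(cfg$gain, cfg$black_level, cfg$bit_depth, cfg$read_noise_e)

cfg_design <- function(cfg) {
  onsets <- cfg$initial_rest + (seq_len(cfg$n_blocks) - 1) * cfg$block_period
  block_design(onsets, cfg$stim_duration, "task", cfg$epoch_window)
}

# boxcar modulation over the stimulus blocks
cfg_boxcar <- function(cfg, amplitude) {
  des <- cfg_design(cfg)
  function(t) {
    on <- rep(FALSE, length(t))
    for (b in seq_along(des$onsets))
      on <- on | (t >= des$onsets[b] & t < des$onsets[b] + des$durations[b])
    ifelse(on, amplitude, 1)
  }
}

# minimal probe layout matching the demo's S/D labels (near-class geometry)
cfg_layout <- function(cfg) {
  probe_layout(sources = rbind(c(0, 0), c(38, 0)),
               detectors = rbind(c(19, 0), c(0, 19)))
}

#' Run the full synthetic pipeline
#'
#' simulate -> preprocess -> contrast -> analyze -> reconstruct, writing
#' each stage's artifacts plus a machine-readable QC report and a manifest
#' echoing every effective parameter under one run directory. Deterministic
#' given the config seed.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created; stage subfolders inside).
#' @return invisibly, a list with the channel series (`kf2`, `intensity`,
#'   `dod`, `rdb`), epoched data, the block-level `stats`, the
#'   reconstruction, the `qc` report and the planted-channel names.
#' @export
run_pipeline <- function(config, out_dir = tempfile("scos_run_")) {
  for (f in c(config$events_file, config$manual_mask_file))
    if (!is.null(f) && !file.exists(f))
      stop("input file not found before any computation: ", f)
  stages <- c("simulate", "preprocess", "contrast", "analyze", "recon")
  for (s in stages) dir.create(file.path(out_dir, s), recursive = TRUE,
                               showWarnings = FALSE)
  sched <- cfg_schedule(config)
  cam <- cfg_camera(config)
  design <- if (is.null(config$events_file)) cfg_design(config)
            else read_block_design(config$events_file, config$epoch_window)
  duration <- config$initial_rest + config$n_blocks * config$block_period
  truth <- speckle_truth(beta = config$beta, tau_c = config$tau_c,
                         mean_flux = config$mean_flux)
  qc <- list(frames_repaired = 0L, windows_invalid = 0L,
             channels_pruned = 0L, blocks_masked = 0L,
             subjects_excluded = 0L)

  kf2_list <- list(); int_list <- list()
  for (d in seq_len(config$n_detectors)) {
    scen <- sim_scenario(
      truth,
      flow_timecourse = cfg_boxcar(config, config$flow_amplitude),
      absorption_timecourse = cfg_boxcar(config, config$absorption_amplitude),
      active_sources = config$active_source,
      seed = config$seed + d, method = config$method)
    stack <- simulate_frames(scen, sched, cam,
                             shape = c(config$rows, config$cols), duration)
    dark <- simulate_dark_frames(cam, config$n_dark_frames,
                                 c(config$rows, config$cols),
                                 seed = config$seed + 1000L + d)
    rep_stack <- repair_frames(stack, sched)
    qc$frames_repaired <- qc$frames_repaired +
      attr(rep_stack, "repair_report")$n_inserted
    dstats <- compute_dark_stats(dark, config$window)
    ds <- subtract_dark(rep_stack, dstats)
    ws <- window_statistics(ds, config$window)
    cc <- contrast_components(ws, dstats, cam, ksp = config$ksp)
    qc$windows_invalid <- qc$windows_invalid + sum(!cc$valid)
    wk <- weighted_kf2(cc, ws)
    kf2_list[[d]] <- per_source_series(wk, "kf2", detector = d)
    int_list[[d]] <- per_source_series(wk, "intensity", detector = d)
  }
  bind_series <- function(lst, kind) {
    channel_series(lst[[1]]$time,
                   do.call(cbind, lapply(lst, function(s) s$values)),
                   kind = kind,
                   channels = unlist(lapply(lst, function(s) s$channels)))
  }
  kf2 <- bind_series(kf2_list, "kf2")
  intensity <- bind_series(int_list, "intensity")
  write_channel_series(kf2, file.path(out_dir, "contrast", "kf2.csv"))
  write_channel_series(intensity,
                       file.path(out_dir, "contrast", "intensity.csv"))

  pr <- prune_low_flux(intensity, config$flux_threshold)
  qc$channels_pruned <- sum(!pr$keep)
  sel <- function(ser) channel_series(ser$time,
                                      ser$values[, pr$keep, drop = FALSE],
                                      ser$kind, ser$channels[pr$keep])
  kf2 <- sel(kf2); intensity <- sel(intensity)

  dod <- delta_od(intensity, config$baseline_interval)
  rdb <- rdb_minus_one(kf2, config$baseline_interval)
  manual <- if (is.null(config$manual_mask_file)) NULL
            else as.logical(utils::read.csv(config$manual_mask_file)$valid)
  mot <- detect_motion_blocks(dod, design, z_threshold = config$motion_z,
                              manual_mask = manual)
  qc$blocks_masked <- mot$n_masked
  qc$subjects_excluded <- as.integer(mot$subject_excluded)

  dod_f <- lowpass(dod, config$lowpass_cutoff, config$lowpass_order)
  rdb_f <- lowpass(rdb, config$lowpass_cutoff, config$lowpass_order)
  ep_dod <- block_average(dod_f, design, mot$valid, config$epoch_baseline)
  ep_rdb <- block_average(rdb_f, design, mot$valid, config$epoch_baseline)

  blocks_as_units <- function(ep) {
    ok <- which(ep$valid)
    aperm(ep$data[, ok, , drop = FALSE], c(2, 1, 3))
  }
  bl <- blocks_as_units(ep_rdb)
  dimnames(bl)[[3]] <- ep_rdb$channels
  stats <- group_stats(bl, rep(1, dim(bl)[1]), ep_rdb$time,
                       window = config$stats_window)
  utils::write.csv(stats$table,
                   file.path(out_dir, "analyze", "block_stats_rdb.csv"),
                   row.names = FALSE)
  bl_od <- blocks_as_units(ep_dod)
  dimnames(bl_od)[[3]] <- ep_dod$channels
  stats_od <- group_stats(bl_od, rep(1, dim(bl_od)[1]), ep_dod$time,
                          window = config$stats_window)
  utils::write.csv(stats_od$table,
                   file.path(out_dir, "analyze", "block_stats_dod.csv"),
                   row.names = FALSE)

  layout <- cfg_layout(config)
  chans <- enumerate_channels(layout)
  chans <- chans[chans$sds_class == "near", ]
  ids <- paste0("S", chans$source, "D", chans$detector)
  y <- stats$table$window_mean[match(ids, stats$table$channel)]
  sens <- toy_sensitivity(layout, chans)
  img <- tikhonov_reconstruct(y, sens, config$alpha)
  write_recon_image(img, file.path(out_dir, "recon", "rdb_image.csv"))

  jsonlite::write_json(qc, file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- c(unclass(config),
                list(package_version = as.character(
                  utils::packageVersion("scosr"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  planted <- grep(paste0("^S", config$active_source, "D"),
                  stats$table$channel, value = TRUE)
  invisible(list(kf2 = kf2, intensity = intensity, dod = dod_f, rdb = rdb_f,
                 epochs_rdb = ep_rdb, epochs_dod = ep_dod,
                 stats = stats, stats_dod = stats_od, image = img,
                 qc = qc, planted_channels = planted, out_dir = out_dir))
}
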