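# Lightweight aeration-profile view of one row of profile_sequence(),
# sufficient for compute_rd().
profile_from_row <- function(row) {
  structure(list(
    compartments = data.frame(
      compartment = "non",
      voxel_count = NA_integer_,
      volume_ml = row$non_ml,
      weight_g = row$non_g,
      stringsAsFactors = FALSE),
    lung_volume_ml = row$lung_volume_ml,
    tissue_weight_g = row$tissue_weight_g,
    gas_volume_ml = row$gas_volume_ml,
    timestamp = row$timestamp
  ), class = "aeration_profile")
}

# Analyze one PEEP step: per-breath mechanics, CT synchronization, frame
# pairing and per-breath R/D.  Shared by the full (in-memory) and
# analyze-from-files paths.
analyze_step <- function(waves, seq, peep, direction,
                         settle_time = 5, rd_denominator = "total",
                         frame_method = "nearest", r2_min = 0.8,
                         min_tv = 0.01, end_exp_frac = 0.25) {
  if (is.null(waves$volume) || !length(waves$volume)) {
    waves$volume <- integrate_volume(waves$flow, fs = waves$fs)
  }
  bt <- analyze_waveforms(waves, settle_time = settle_time,
                          r2_min = r2_min, min_tv = min_tv,
                          end_exp_frac = end_exp_frac)
  if (nrow(bt)) { bt$peep <- peep; bt$direction <- direction }
  rd <- NULL
  sync <- NULL
  if (!is.null(seq) && nrow(bt)) {
    gas <- ct_gas_series(seq)
    sync <- synchronize(gas, waves)
    kept <- bt[bt$kept, , drop = FALSE]
    pairs <- select_breath_frames(sync, kept, seq, method = frame_method)
    if (nrow(pairs)) {
      prof <- profile_sequence(seq)
      rd <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
        pr <- pairs[k, ]
        compute_rd(profile_from_row(prof[pr$ee_frame_idx, ]),
                   profile_from_row(prof[pr$ei_frame_idx, ]),
                   breath = pr$breath, peep = peep, direction = direction,
                   denominator = rd_denominator)
      }))
    }
  }
  list(breaths = bt, rd = rd, sync = sync)
}

#' Run the full synthetic PEEP-ramp study
#'
#' Simulates breathing and dynamic CT at every protocol step (one phantom
#' lung reused throughout, region states carried across steps so the
#' descending limb sees the hysteresis of the ascending one), analyzes
#' each step (breath detection, mechanics fits, resistive-corrected
#' maximal transpulmonary pressure, EAdi statistics, CT synchronization,
#' frame pairing, per-breath R/D), aggregates R/D by PEEP and ramp
#' direction, and runs the Q1-Q5 statistical battery.
#'
#' @param sim_cfg A [sim_config()].
#' @param pcfg A [phantom_config()].
#' @param seed Master seed (per-step seeds are derived from it);
#'   defaults to `sim_cfg$seed`.
#' @param out_dir Optional directory for the result tables
#'   (`breaths.csv`, `rd.csv`, `aggregate_*.csv`, `report.json`,
#'   `provenance.json`).
#' @param settle_time Breaths starting earlier than this (s) are treated
#'   as settling and excluded.
#' @param rd_denominator `%eeLV` denominator: `"total"` or `"gas"`.
#' @param frame_method Frame selection: `"nearest"` or `"extremal"`.
#' @param alpha Significance level of the statistical battery.
#' @return An object of class `rd_study`: `protocol`, `breaths`, `rd`,
#'   `aggregates`, `report` (a `q_report`), `sync` (per-step offset and
#'   quality), `provenance`.
#' @export
run_study <- function(sim_cfg = sim_config(), pcfg = phantom_config(),
                      seed = NULL, out_dir = NULL, settle_time = 5,
                      rd_denominator = "total", frame_method = "nearest",
                      alpha = 0.05) {
  seed <- as.integer(seed %||% sim_cfg$seed)
  protocol <- tag_protocol(sim_cfg$peep_sequence)
  lung <- build_phantom_lung(pcfg)
  state <- NULL
  all_b <- list(); all_rd <- list(); sync_rows <- list()
  wave_duration <- pcfg$duration + pcfg$ct_lag + 2
  for (i in seq_len(nrow(protocol))) {
    peep <- protocol$peep[i]; direction <- protocol$direction[i]
    step_seed <- seed + 137L * i
    sim <- simulate_breathing(sim_cfg, peep, wave_duration, seed = step_seed)
    ct <- simulate_ct_sequence(pcfg, sim, lung = lung, init_state = state)
    state <- ct$gt$final_state
    res <- analyze_step(sim$waves, ct$seq, peep, direction,
                        settle_time = settle_time,
                        rd_denominator = rd_denominator,
                        frame_method = frame_method)
    if (nrow(res$breaths)) {
      res$breaths$step <- i
      all_b[[i]] <- res$breaths
    }
    if (!is.null(res$rd)) { res$rd$step <- i; all_rd[[i]] <- res$rd }
    if (!is.null(res$sync)) {
      sync_rows[[i]] <- data.frame(step = i, peep = peep,
                                   direction = direction,
                                   offset = res$sync$offset,
                                   quality = res$sync$quality)
    }
  }
  assemble_study(protocol, all_b, all_rd, sync_rows,
                 list(sim = unclass(sim_cfg), phantom = unclass(pcfg),
                      seed = seed, settle_time = settle_time,
                      rd_denominator = rd_denominator,
                      frame_method = frame_method, alpha = alpha),
                 out_dir, alpha)
}

# Direction tags for an arbitrary PEEP sequence: ascending limb up to and
# including the peak, descending afterwards.
tag_protocol <- function(peep_sequence) {
  peak <- which.max(peep_sequence)
  data.frame(step = seq_along(peep_sequence),
             peep = peep_sequence,
             direction = ifelse(seq_along(peep_sequence) <= peak,
                                "up", "down"),
             stringsAsFactors = FALSE)
}

assemble_study <- function(protocol, all_b, all_rd, sync_rows, opts,
                           out_dir, alpha) {
  breaths <- if (length(all_b)) do.call(rbind, all_b) else NULL
  rd <- if (length(all_rd)) do.call(rbind, all_rd) else NULL
  sync <- if (length(sync_rows)) do.call(rbind, sync_rows) else NULL
  aggregates <- if (!is.null(rd) && nrow(rd)) aggregate_by_peep(rd) else NULL
  report <- run_q_battery(breaths, rd, alpha = alpha)
  provenance <- list(
    package = "tidalRD",
    version = as.character(utils::packageVersion("tidalRD")),
    options = opts,
    n_breaths = if (is.null(breaths)) 0L else nrow(breaths),
    n_breaths_kept = if (is.null(breaths)) 0L else sum(breaths$kept),
    n_rd = if (is.null(rd)) 0L else nrow(rd)
  )
  study <- structure(list(protocol = protocol, breaths = breaths, rd = rd,
                          aggregates = aggregates, report = report,
                          sync = sync, provenance = provenance),
                     class = "rd_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(study$breaths))
    utils::write.csv(study$breaths, file.path(out_dir, "breaths.csv"),
                     row.names = FALSE)
  if (!is.null(study$rd))
    utils::write.csv(study$rd, file.path(out_dir, "rd.csv"),
                     row.names = FALSE)
  if (!is.null(study$aggregates)) {
    utils::write.csv(study$aggregates$pooled,
                     file.path(out_dir, "aggregate_pooled.csv"),
                     row.names = FALSE)
    utils::write.csv(study$aggregates$by_peep_direction,
                     file.path(out_dir, "aggregate_by_peep_direction.csv"),
                     row.names = FALSE)
  }
  if (!is.null(study$sync))
    utils::write.csv(study$sync, file.path(out_dir, "sync.csv"),
                     row.names = FALSE)
  jsonlite::write_json(report_to_list(study$report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(study$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

report_to_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, "regression_fit") || inherits(x, "dispersion_test"))
      return(unclass(x))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  strip(unclass(report))
}

#' @export
print.rd_study <- function(x, ...) {
  cat(sprintf("<rd_study> %d protocol steps, %d breaths (%d kept), %d R/D measures\n",
              nrow(x$protocol),
              x$provenance$n_breaths, x$provenance$n_breaths_kept,
              x$provenance$n_rd))
  if (!is.null(x$aggregates)) {
    p <- x$aggregates$pooled
    cat("  pooled R/D %eeLV by PEEP:\n")
    print(p[, c("peep", "rd_pct_eelv_mean", "rd_pct_eelv_sd", "n")],
          row.names = FALSE)
  }
  print(x$report)
  invisible(x)
}

#' Simulate the study and write raw data to disk
#'
#' Generates the same synthetic study as [run_study()] but writes the raw
#' acquisition files (waveform and EAdi CSVs, multi-page 16-bit TIFF
#' frames, mask, YAML sidecars, ground-truth JSON) into one subdirectory
#' per protocol step, for later [analyze_study()].
#'
#' @inheritParams run_study
#' @param out_dir Root output directory.
#' @return `out_dir`, invisibly.
#' @export
simulate_study <- function(sim_cfg = sim_config(), pcfg = phantom_config(),
                           out_dir, seed = NULL) {
  seed <- as.integer(seed %||% sim_cfg$seed)
  protocol <- tag_protocol(sim_cfg$peep_sequence)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(steps = nrow(protocol)),
                   file.path(out_dir, "protocol.yaml"))
  lung <- build_phantom_lung(pcfg)
  state <- NULL
  wave_duration <- pcfg$duration + pcfg$ct_lag + 2
  for (i in seq_len(nrow(protocol))) {
    peep <- protocol$peep[i]
    step_seed <- seed + 137L * i
    sim <- simulate_breathing(sim_cfg, peep, wave_duration, seed = step_seed)
    ct <- simulate_ct_sequence(pcfg, sim, lung = lung, init_state = state)
    state <- ct$gt$final_state
    sdir <- file.path(out_dir, sprintf("step_%02d", i))
    write_waveforms(sim$waves, sdir)
    write_ct_sequence(ct$seq, sdir)
    yaml::write_yaml(list(step = i, peep = peep,
                          direction = protocol$direction[i]),
                     file.path(sdir, "step.yaml"))
    jsonlite::write_json(
      list(breaths = sim$gt$breaths,
           non_aerated_ml = ct$gt$non_aerated_ml,
           gas_volume_ml = ct$gt$gas_volume_ml,
           rd_breaths = ct$gt$rd_breaths,
           ct_lag = ct$gt$ct_lag),
      file.path(sdir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Analyze a study from raw data on disk
#'
#' Reads the per-step raw files written by [simulate_study()] (or
#' equivalently formatted real acquisitions) and runs the same analysis
#' chain as [run_study()].  Missing EAdi files degrade gracefully: the
#' EAdi columns stay `NA` and a warning is raised.
#'
#' @param in_dir Root directory with `step_*` subdirectories.
#' @inheritParams run_study
#' @return An `rd_study`.
#' @export
analyze_study <- function(in_dir, out_dir = NULL, settle_time = 5,
                          rd_denominator = "total",
                          frame_method = "nearest", alpha = 0.05) {
  step_dirs <- sort(list.dirs(in_dir, recursive = FALSE))
  step_dirs <- step_dirs[grepl("step_\\d+$", step_dirs)]
  stop_if_not(length(step_dirs) >= 1L, "no step_* directories found")
  all_b <- list(); all_rd <- list(); sync_rows <- list()
  proto_rows <- list()
  for (i in seq_along(step_dirs)) {
    sdir <- step_dirs[i]
    meta <- yaml::read_yaml(file.path(sdir, "step.yaml"))
    waves <- read_waveforms(sdir)
    seq <- read_ct_sequence(sdir)
    res <- analyze_step(waves, seq, meta$peep, meta$direction,
                        settle_time = settle_time,
                        rd_denominator = rd_denominator,
                        frame_method = frame_method)
    proto_rows[[i]] <- data.frame(step = meta$step, peep = meta$peep,
                                  direction = meta$direction)
    if (nrow(res$breaths)) { res$breaths$step <- meta$step
                             all_b[[i]] <- res$breaths }
    if (!is.null(res$rd)) { res$rd$step <- meta$step; all_rd[[i]] <- res$rd }
    if (!is.null(res$sync)) {
      sync_rows[[i]] <- data.frame(step = meta$step, peep = meta$peep,
                                   direction = meta$direction,
                                   offset = res$sync$offset,
                                   quality = res$sync$quality)
    }
  }
  assemble_study(do.call(rbind, proto_rows), all_b, all_rd, sync_rows,
                 list(mode = "analyze", in_dir = in_dir,
                      settle_time = settle_time,
                      rd_denominator = rd_denominator,
                      frame_method = frame_method, alpha = alpha),
                 out_dir, alpha)
}
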