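# Lognormal parameters from a target mean and sd on the natural scale.
lognormal_pars <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Build the static structure of the dynamic CT lung phantom
#'
#' Draws, once per phantom, the lung mask, the partition of lung pixels
#' into spatially coherent regions, the recruitable pixel set (exactly
#' `round(recruitable_fraction * n_lung_pixels)` pixels, whole regions
#' where possible), per-region opening/closing pressures (closing
#' lognormal; opening = closing + truncated-Gaussian gap) and per-pixel
#' baseline gas fractions.  Reusing one lung across the PEEP protocol
#' models a single animal's lung observed under different pressures.
#'
#' @param pcfg A [phantom_config()].
#' @return An object of class `phantom_lung`.
#' @export
build_phantom_lung <- function(pcfg) {
  validate_phantom_config(pcfg)
  nr <- pcfg$grid_shape[1]; nc <- pcfg$grid_shape[2]
  mask <- matrix(FALSE, nr, nc)
  if (pcfg$mask_shape == "ellipse") {
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    ry <- (nr - 1) / 2; rx <- (nc - 1) / 2
    rows <- row(mask); cols <- col(mask)
    mask <- ((rows - cy) / ry)^2 + ((cols - cx) / rx)^2 <= 1
  } else {
    mask[] <- TRUE
  }
  px_index <- which(mask)
  npx <- length(px_index)
  px_row <- ((px_index - 1L) %% nr) + 1L
  px_col <- ((px_index - 1L) %/% nr) + 1L

  with_seed(pcfg$seed, {
    nreg <- min(pcfg$n_regions, npx)
    seeds <- sample.int(npx, nreg)
    # nearest-seed assignment -> spatially coherent patches
    d2 <- outer(px_row, px_row[seeds], "-")^2 +
          outer(px_col, px_col[seeds], "-")^2
    region_id <- max.col(-d2, ties.method = "first")

    target <- round(pcfg$recruitable_fraction * npx)
    recruitable <- logical(npx)
    if (target > 0) {
      ord <- sample.int(nreg)
      got <- 0L
      for (r in ord) {
        px_r <- which(region_id == r)
        take <- min(length(px_r), target - got)
        if (take > 0) recruitable[px_r[seq_len(take)]] <- TRUE
        got <- got + take
        if (got >= target) break
      }
    }

    lp <- lognormal_pars(pcfg$closing_pressure_mean, pcfg$closing_pressure_sd)
    p_close <- stats::rlnorm(nreg, lp$meanlog, lp$sdlog)
    gap <- pmax(0.5, stats::rnorm(nreg, pcfg$opening_offset_mean,
                                  pcfg$opening_offset_sd))
    p_open <- p_close + gap

    f_base <- stats::runif(npx, pcfg$gas_frac_range[1], pcfg$gas_frac_range[2])

    structure(list(
      mask = mask, px_index = px_index, npx = npx,
      region_id = region_id, n_regions = nreg,
      recruitable = recruitable,
      p_open = p_open, p_close = p_close,
      f_base = f_base,
      voxel_volume_ml = prod(pcfg$pixel_size) * pcfg$slice_thickness / 1000
    ), class = "phantom_lung")
  })
}

# Resolve the driving channels for the phantom: prefer the simulator's
# clean (noise-free) traces when a full simulate_breathing() result is
# given; fall back to the recorded channels of a bare waveform_set.
phantom_drive <- function(sim) {
  if (is.list(sim) && !is.null(sim$waves) && !is.null(sim$gt)) {
    list(t = sim$waves$t, pao = sim$gt$clean$pao,
         volume = sim$gt$clean$volume, fs = sim$waves$fs,
         breaths = sim$gt$breaths)
  } else if (inherits(sim, "waveform_set")) {
    list(t = sim$t, pao = sim$pao, volume = sim$volume, fs = sim$fs,
         breaths = NULL)
  } else {
    stop("`sim` must be a simulate_breathing() result or a waveform_set",
         call. = FALSE)
  }
}

#' Simulate a dynamic CT slice sequence of the lung phantom
#'
#' Drives the phantom's recruitable regions with the airway pressure of a
#' simulated breathing run.  A region opens when pressure reaches its
#' opening pressure and closes when pressure falls to its closing pressure
#' (hysteresis); its pixels then take the attenuation of collapsed tissue.
#' Aerated pixels track instantaneous gas content on the linear HU mixing
#' scale.  Frames are generated on the breathing clock and stamped with a
#' constant clock lag (`pcfg$ct_lag`) for the synchronization stage to
#' recover.
#'
#' @param pcfg A [phantom_config()].
#' @param sim Result of [simulate_breathing()] (preferred; the phantom then
#'   responds to the clean pressure) or a bare `waveform_set`.
#' @param lung Optional [build_phantom_lung()] result to reuse across PEEP
#'   steps; built from `pcfg` when `NULL`.
#' @param init_state Optional logical vector (one per region): initial open
#'   state; defaults to all recruitable regions closed.
#' @return A list: `seq` (class `ct_sequence`: integer in-mask HU matrix
#'   `hu` of dimension n_pixels x n_frames, emitted `timestamps` including
#'   the clock lag, geometry), `mask`, and `gt` (per-frame non-aerated
#'   volume and gas volume in ml on the true clock, per-breath true tidal
#'   R/D when breath ground truth is available, the lung, final region
#'   state, and the applied `ct_lag`).
#' @export
simulate_ct_sequence <- function(pcfg, sim, lung = NULL, init_state = NULL) {
  validate_phantom_config(pcfg)
  drv <- phantom_drive(sim)
  dur_w <- drv$t[length(drv$t)]
  if (dur_w < pcfg$duration) {
    stop(sprintf("waveform duration (%.2f s) shorter than CT duration (%.2f s)",
                 dur_w, pcfg$duration), call. = FALSE)
  }
  if (is.null(lung)) lung <- build_phantom_lung(pcfg)

  nf <- as.integer(round(pcfg$frame_rate * pcfg$duration))
  tf <- (seq_len(nf) - 1L) / pcfg$frame_rate

  vv <- lung$voxel_volume_ml
  nreg <- lung$n_regions
  # pixels per recruitable region (0 for non-recruitable regions)
  reg_npx <- tabulate(lung$region_id[lung$recruitable], nbins = nreg)

  open <- if (is.null(init_state)) rep(FALSE, nreg) else as.logical(init_state)
  stop_if_not(length(open) == nreg, "`init_state` length must equal n_regions")

  # Evolve region states at the waveform rate.  Opening is instantaneous
  # when pressure reaches the opening pressure; closure requires pressure
  # to stay at or below the closing pressure for `close_dwell` seconds
  # (airspace collapse has a finite time constant, so the brief pressure
  # minimum at the inspiratory-expiratory transition does not derecruit).
  # Closed pixel counts are recorded per sample (ground truth readable at
  # arbitrary times) and region states at each frame's sample.
  ns <- length(drv$t)
  h <- 1 / drv$fs
  fidx <- pmin(ns, as.integer(round(tf * drv$fs)) + 1L)
  closed_px_sample <- integer(ns)
  state_frames <- matrix(FALSE, nreg, nf)
  p <- drv$pao
  po <- lung$p_open; pc <- lung$p_close
  t_below <- numeric(nreg)
  j <- 1L
  for (i in seq_len(ns)) {
    pi_ <- p[i]
    below <- pi_ <= pc
    t_below <- (t_below + h) * below
    open <- (open & !(t_below >= pcfg$close_dwell)) | (pi_ >= po)
    closed_px_sample[i] <- sum(reg_npx[!open])
    while (j <= nf && fidx[j] == i) {
      state_frames[, j] <- open
      j <- j + 1L
    }
  }
  closed_frame_px <- closed_px_sample[fidx]
  v_frame <- drv$volume[fidx]

  # Assemble frames: aerated pixels by linear gas mixing, closed pixels at
  # the collapsed-tissue attenuation.  Integer HU, CT-like.
  hu <- matrix(0L, lung$npx, nf)
  rec <- lung$recruitable
  rec_region <- lung$region_id[rec]
  gpl <- pcfg$gas_frac_per_l
  for (jf in seq_len(nf)) {
    f <- clamp(lung$f_base + gpl * v_frame[jf], 0.12, 0.98)
    col <- as.integer(round(-pcfg$hu_gas_gain * f))
    closed_here <- !state_frames[rec_region, jf]
    col[rec][closed_here] <- as.integer(round(pcfg$hu_nonaerated))
    hu[, jf] <- col
  }

  gas_ml <- colSums(pmax(-hu, 0L)) / 1000 * vv

  seq_obj <- structure(list(
    hu = hu, mask = lung$mask, px_index = lung$px_index,
    timestamps = tf + pcfg$ct_lag,
    pixel_size = pcfg$pixel_size, slice_thickness = pcfg$slice_thickness,
    frame_rate = pcfg$frame_rate,
    voxel_volume_ml = vv
  ), class = "ct_sequence")

  rd_breaths <- NULL
  if (!is.null(drv$breaths)) {
    b <- drv$breaths
    b <- b[b$t_end <= dur_w + 1e-9 & b$t_end <= pcfg$duration, , drop = FALSE]
    if (nrow(b)) {
      at_sample <- function(tt) pmin(ns, as.integer(round(tt * drv$fs)) + 1L)
      ee <- closed_px_sample[at_sample(b$t_end)]
      ei <- closed_px_sample[at_sample(b$t_insp_end)]
      rd_breaths <- data.frame(breath = b$breath,
                               t_insp_end = b$t_insp_end, t_end = b$t_end,
                               rd_ml = (ee - ei) * vv,
                               closed_ee_ml = ee * vv, closed_ei_ml = ei * vv)
    }
  }

  gt <- list(
    frame_time_true = tf,
    non_aerated_ml = closed_frame_px * vv,
    gas_volume_ml = gas_ml,
    closed_px_sample = closed_px_sample,
    rd_breaths = rd_breaths,
    lung = lung,
    final_state = open,
    ct_lag = pcfg$ct_lag
  )
  list(seq = seq_obj, mask = lung$mask, gt = gt)
}

#' Extract one frame of a CT sequence as a full-grid `ct_frame`
#'
#' Off-mask pixels are filled with soft-tissue attenuation (+40 HU); they
#' are excluded by the mask in all analyses.
#'
#' @param seq A `ct_sequence`.
#' @param i Frame index.
#' @return A [ct_frame()].
#' @export
get_frame <- function(seq, i) {
  stop_if_not(i >= 1 && i <= ncol(seq$hu), "frame index out of range")
  att <- matrix(40, nrow(seq$mask), ncol(seq$mask))
  att[seq$px_index] <- seq$hu[, i]
  ct_frame(att, pixel_size = seq$pixel_size,
           slice_thickness = seq$slice_thickness,
           timestamp = seq$timestamps[i])
}

#' @export
print.ct_sequence <- function(x, ...) {
  cat(sprintf("<ct_sequence> %d frames, %d lung pixels, %g Hz\n",
              ncol(x$hu), nrow(x$hu), x$frame_rate))
  invisible(x)
}
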