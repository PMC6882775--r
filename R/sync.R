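#' Gas-volume time series of a dynamic CT sequence
#'
#' Computes the in-mask gas volume (ml) of every frame from its aeration
#' profile, at the sequence's emitted timestamps.
#'
#' @param seq A `ct_sequence` (or a list of [ct_frame()]s plus a `mask`).
#' @param mask Binary lung mask; required only for a list of frames.
#' @return A data.frame: `timestamp` (s), `gas_ml`.
#' @export
ct_gas_series <- function(seq, mask = NULL) {
  if (inherits(seq, "ct_sequence")) {
    stop_if_not(ncol(seq$hu) >= 2L, "need at least 2 frames")
    prof <- profile_sequence(seq)
    return(data.frame(timestamp = prof$timestamp, gas_ml = prof$gas_volume_ml))
  }
  stop_if_not(is.list(seq) && length(seq) >= 2L, "need at least 2 frames")
  stop_if_not(!is.null(mask), "`mask` is required for a list of frames")
  gas <- vapply(seq, function(fr) {
    compute_aeration_profile(fr, mask)$gas_volume_ml
  }, numeric(1))
  ts <- vapply(seq, function(fr) fr$timestamp, numeric(1))
  data.frame(timestamp = ts, gas_ml = gas)
}

#' Align the CT frame clock with the spirometry clock
#'
#' Finds the constant offset that, added to the CT timestamps, best aligns
#' the CT gas-volume series with the spirometric volume channel.  The gas
#' series is linearly interpolated onto the 200 Hz waveform grid and the
#' normalized cross-correlation is maximized over a grid of candidate
#' offsets at waveform-sample resolution.
#'
#' @param gas_series Data.frame from [ct_gas_series()] (`timestamp`,
#'   `gas_ml`).
#' @param waves A `waveform_set` supplying `t`, `volume` and `fs`.
#' @param max_lag Largest absolute offset searched, s.
#' @param quality_min Peak correlations below this raise a low-quality
#'   warning flag.
#' @return An object of class `sync_map`: `offset` (s; add to CT
#'   timestamps to land on the spirometry timebase), `quality` (peak
#'   normalized cross-correlation), `flagged`.
#' @export
synchronize <- function(gas_series, waves, max_lag = 2, quality_min = 0.5) {
  g <- gas_series$gas_ml
  tg <- gas_series$timestamp
  stop_if_not(length(g) >= 2L, "need at least 2 frames")
  if (stats::sd(g) == 0 || stats::sd(waves$volume) == 0) {
    stop("degenerate (constant) series: cannot synchronize", call. = FALSE)
  }
  span_ct <- diff(range(tg))
  h <- 1 / waves$fs
  # the recovered offset may not exceed half the acquisition duration
  L <- min(max_lag, span_ct / 2)
  lags <- seq(-L, L, by = h)
  v <- waves$volume
  tv <- waves$t
  best <- -Inf; best_lag <- 0
  for (lag in lags) {
    # candidate offset: CT timestamps + lag land on the waveform clock
    ti <- tg + lag
    keep <- ti >= tv[1] & ti <= tv[length(tv)]
    if (sum(keep) < max(4L, length(g) / 4L)) next
    gi <- g[keep]
    vi <- stats::approx(tv, v, xout = ti[keep])$y
    if (stats::sd(gi) == 0 || stats::sd(vi) == 0) next
    r <- stats::cor(gi, vi)
    if (r > best) { best <- r; best_lag <- lag }
  }
  stop_if_not(is.finite(best), "no overlapping window found")
  flagged <- best < quality_min
  if (flagged) {
    warning(sprintf("low synchronization quality (r = %.2f)", best))
  }
  structure(list(offset = best_lag, quality = best, flagged = flagged),
            class = "sync_map")
}

#' Select the end-expiratory and end-inspiratory frame of each breath
#'
#' For every breath, picks the CT frame whose offset-corrected timestamp
#' is nearest the breath's inspiratory end (end-inspiratory frame) and the
#' frame nearest the breath's end (end-expiratory frame).  Breaths without
#' both frames inside the acquisition window, or whose two frames
#' coincide, are skipped.  Alternatively (`method = "extremal"`), frames
#' are chosen by extremal gas content within the breath window, for
#' sensitivity analysis.
#'
#' @param sync A [synchronize()] result (or a list with `offset`).
#' @param breaths A [detect_breaths()] table.
#' @param seq A `ct_sequence`.
#' @param method `"nearest"` (default) or `"extremal"`.
#' @return A data.frame of class `breath_frame_pairs`: `breath`,
#'   `ee_frame_idx`, `ei_frame_idx`, `t_ee`, `t_ei` (offset-corrected
#'   frame times, s).
#' @export
select_breath_frames <- function(sync, breaths, seq,
                                 method = c("nearest", "extremal")) {
  method <- match.arg(method)
  tf <- seq$timestamps + sync$offset
  nf <- length(tf)
  half_frame <- if (nf > 1) stats::median(diff(tf)) / 2 else Inf
  gas <- if (method == "extremal") {
    profile_sequence(seq)$gas_volume_ml
  } else NULL
  out <- vector("list", nrow(breaths))
  for (k in seq_len(nrow(breaths))) {
    b <- breaths[k, ]
    in_breath <- which(tf >= b$t_start & tf <= b$t_end)
    if (length(in_breath) < 2L) next
    if (method == "nearest") {
      ei <- which.min(abs(tf - b$t_insp_end))
      ee <- which.min(abs(tf - b$t_end))
      # both landmarks must actually be covered by the acquisition
      if (abs(tf[ei] - b$t_insp_end) > half_frame + 1e-9) next
      if (abs(tf[ee] - b$t_end) > half_frame + 1e-9) next
    } else {
      ei <- in_breath[which.max(gas[in_breath])]
      ee <- in_breath[which.min(gas[in_breath])]
    }
    if (ee == ei) next
    out[[k]] <- data.frame(breath = b$breath,
                           ee_frame_idx = ee, ei_frame_idx = ei,
                           t_ee = tf[ee], t_ei = tf[ei])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(breath = integer(), ee_frame_idx = integer(),
               ei_frame_idx = integer(), t_ee = numeric(), t_ei = numeric())
  class(pairs) <- c("breath_frame_pairs", "data.frame")
  pairs
}
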