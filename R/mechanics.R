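#' Integrate flow into volume
#'
#' Trapezoidal integration of a uniformly sampled flow signal (L/s) into
#' volume (L).  When a breath table is supplied, a per-breath linear drift
#' correction is applied so that volume returns to zero at each breath end
#' (compensating integration drift from sensor offset and gas exchange).
#'
#' @param flow Numeric flow series, L/s (inspiration positive).
#' @param fs Sampling rate, Hz (give either `fs` or `t`).
#' @param t Time vector, s; must be a uniform grid.
#' @param breaths Optional breath table from [detect_breaths()].
#' @return Volume series, L (same length as `flow`).
#' @export
integrate_volume <- function(flow, fs = NULL, t = NULL, breaths = NULL) {
  if (is.null(fs)) {
    stop_if_not(!is.null(t), "supply `fs` or `t`")
    stop_if_not(is_uniform_grid(t), "time grid is not uniform")
    fs <- 1 / stats::median(diff(t))
  } else if (!is.null(t)) {
    stop_if_not(is_uniform_grid(t), "time grid is not uniform")
  }
  h <- 1 / fs
  n <- length(flow)
  v <- c(0, cumsum((flow[-1] + flow[-n]) / 2) * h)
  if (!is.null(breaths) && nrow(breaths)) {
    for (k in seq_len(nrow(breaths))) {
      i0 <- breaths$start_idx[k]; i1 <- breaths$end_idx[k]
      seg <- i0:i1
      base <- v[i0]
      slope <- (v[i1] - v[i0]) / (i1 - i0)
      v[seg] <- v[seg] - base - slope * (seg - i0)
    }
  }
  v
}

#' Detect breaths from the flow channel
#'
#' Breath boundaries are placed at expiratory-to-inspiratory zero
#' crossings of flow, using a hysteresis band (flow must exceed
#' `+hysteresis` after having been below `-hysteresis`) to reject noise
#' around zero.  The inspiratory end of each breath is the following
#' inspiratory-to-expiratory crossing.  Breaths with tidal volume below
#' `min_tv` are flagged (`kept = FALSE`) and excluded from downstream
#' statistics.
#'
#' @param waves A `waveform_set` (or any list with `t`, `flow`, `fs`).
#' @param hysteresis Half-width of the zero-crossing hysteresis band, L/s.
#' @param min_tv Minimum tidal volume for a breath to be kept, L.
#' @return A data.frame of class `breath_table`: `breath`, `start_idx`,
#'   `insp_end_idx`, `end_idx`, `t_start`, `t_insp_end`, `t_end`, `tv`
#'   (L, drift-corrected), `peak_flow` (L/s), `rr_local` (breaths/min),
#'   `kept`.  Zero rows when no crossings are found.
#' @export
detect_breaths <- function(waves, hysteresis = 0.02, min_tv = 0.01) {
  flow <- waves$flow
  t <- waves$t
  n <- length(flow)
  empty <- data.frame(breath = integer(), start_idx = integer(),
                      insp_end_idx = integer(), end_idx = integer(),
                      t_start = numeric(), t_insp_end = numeric(),
                      t_end = numeric(), tv = numeric(),
                      peak_flow = numeric(), rr_local = numeric(),
                      kept = logical())
  class(empty) <- c("breath_table", "data.frame")
  if (n < 3L) return(empty)

  s <- integer(n)
  s[flow > hysteresis] <- 1L
  s[flow < -hysteresis] <- -1L
  nz <- which(s != 0L)
  if (!length(nz)) return(empty)
  sv <- s[nz]
  trans_in <- nz[which(sv == 1L & c(0L, sv[-length(sv)]) == -1L)]
  # a record beginning in the expiratory/zero phase: the first inspiratory
  # rise is a valid breath onset even without a preceding expiration
  if (sv[1L] == 1L) trans_in <- c(nz[1L], trans_in)
  # zero crossing: first sample with flow >= 0 in the rise before the
  # +hysteresis crossing
  starts <- vapply(trans_in, function(i) {
    j <- i
    while (j > 1L && flow[j - 1L] >= 0) j <- j - 1L
    j
  }, integer(1))
  if (length(starts) < 2L) return(empty)

  v_raw <- integrate_volume(flow, fs = waves$fs)

  # Merge segments whose inspired volume is below `min_tv` into the
  # preceding breath: noise can cross the hysteresis band during a long
  # expiration, and such spurious boundaries would otherwise truncate the
  # breath period (biasing rr_local upward).
  if (length(starts) > 2L) {
    seg_tv <- vapply(seq_len(length(starts) - 1L), function(k) {
      seg <- starts[k]:starts[k + 1L]
      max(v_raw[seg]) - v_raw[seg[1L]]
    }, numeric(1))
    keep_start <- c(TRUE, seg_tv[-1L] >= min_tv)
    starts <- starts[c(keep_start, TRUE)]
    if (length(starts) < 2L) return(empty)
  }

  # a trailing boundary with no real inspiration after it (noise crossing
  # near the record end) would truncate the last breath's period: drop it
  # and with it the breath whose end it would have marked
  while (length(starts) >= 2L) {
    s_last <- starts[length(starts)]
    tail_tv <- max(v_raw[s_last:n]) - v_raw[s_last]
    if (tail_tv >= min_tv) break
    starts <- starts[-length(starts)]
  }
  if (length(starts) < 2L) return(empty)

  out <- vector("list", length(starts) - 1L)
  for (k in seq_len(length(starts) - 1L)) {
    i0 <- starts[k]; i2 <- starts[k + 1L]
    # inspiratory -> expiratory crossing inside the breath
    neg <- nz[nz > i0 & nz < i2]
    neg <- neg[s[neg] == -1L]
    if (!length(neg)) next
    i1 <- neg[1L]
    while (i1 > i0 + 1L && flow[i1 - 1L] <= 0) i1 <- i1 - 1L
    if (i1 <= i0 || i1 >= i2) next
    slope <- (v_raw[i2] - v_raw[i0]) / (i2 - i0)
    tv <- (v_raw[i1] - v_raw[i0]) - slope * (i1 - i0)
    pf <- max(flow[i0:i1])
    out[[k]] <- data.frame(
      start_idx = i0, insp_end_idx = i1, end_idx = i2,
      t_start = t[i0], t_insp_end = t[i1], t_end = t[i2],
      tv = tv, peak_flow = pf,
      rr_local = 60 / (t[i2] - t[i0])
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  b <- do.call(rbind, out)
  b <- cbind(breath = seq_len(nrow(b)), b)
  b$kept <- b$tv >= min_tv & b$peak_flow > 0
  class(b) <- c("breath_table", "data.frame")
  b
}

#' Fit the single-compartment equation of motion over one breath
#'
#' Multiple linear regression of a pressure channel on flow and volume
#' over all samples of a breath:
#' `p(t) = p0 + rrs * flow(t) + ers * volume(t)`, with volume the raw
#' trapezoidal integral of flow referenced to the breath start.  During
#' assisted spontaneous breathing the airway pressure alone does not obey
#' the equation of motion (muscle pressure is an unmeasured forcing term),
#' so the default pressure channel is transpulmonary (`pao - peso`), which
#' isolates the lung and recovers lung elastance and resistance; the
#' airway channel is available for passive (relaxed) recordings.
#'
#' @param waves A `waveform_set`.
#' @param breath One row of a [detect_breaths()] table.
#' @param pressure `"transpulmonary"` (default) or `"airway"`.
#' @param r2_min Fits with coefficient of determination below this are
#'   flagged unreliable.
#' @return An object of class `mech_fit`: `rrs` (cmH2O s/L), `ers`
#'   (cmH2O/L), `p0` (cmH2O), `r2`, `rms_residual` (cmH2O), `reliable`,
#'   `pressure`, `n`.
#' @export
fit_multilinear <- function(waves, breath,
                            pressure = c("transpulmonary", "airway"),
                            r2_min = 0.8) {
  pressure <- match.arg(pressure)
  i0 <- breath$start_idx; i2 <- breath$end_idx
  stop_if_not(length(i0) == 1L && length(i2) == 1L,
              "`breath` must be a single breath row")
  seg <- i0:i2
  stop_if_not(length(seg) >= 20L, "breath has fewer than 20 samples")
  f <- waves$flow[seg]
  stop_if_not(any(f != 0), "flow is identically zero over the breath")
  h <- 1 / waves$fs
  v <- c(0, cumsum((f[-1] + f[-length(f)]) / 2) * h)
  p <- switch(pressure,
              transpulmonary = waves$pao[seg] - waves$peso[seg],
              airway = waves$pao[seg])
  X <- cbind(1, f, v)
  qrX <- qr(X)
  if (qrX$rank < 3L) {
    stop("indeterminate fit: flow and volume are collinear or constant over the breath",
         call. = FALSE)
  }
  beta <- qr.coef(qrX, p)
  res <- p - X %*% beta
  sst <- sum((p - mean(p))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 0
  r2 <- clamp(r2, 0, 1)
  structure(list(rrs = unname(beta[2]), ers = unname(beta[3]),
                 p0 = unname(beta[1]), r2 = r2,
                 rms_residual = sqrt(mean(res^2)),
                 reliable = r2 >= r2_min,
                 pressure = pressure, n = length(seg)),
            class = "mech_fit")
}

#' @export
print.mech_fit <- function(x, ...) {
  cat(sprintf(
    "<mech_fit %s> Rrs %.2f cmH2O.s/L, Ers %.2f cmH2O/L, P0 %.2f, R2 %.4f%s\n",
    x$pressure, x$rrs, x$ers, x$p0, x$r2,
    if (x$reliable) "" else " [unreliable]"))
  invisible(x)
}

#' Resistive-corrected maximal transpulmonary pressure of one breath
#'
#' The preliminary maximum is the largest airway-minus-esophageal pressure
#' difference during the breath, which during continuous flow contains a
#' resistive component; that component, resistance times the breath's peak
#' inspiratory flow, is subtracted:
#' `ptp_max = (pao - peso)_max - rrs * f_peak`.
#'
#' @param waves A `waveform_set`.
#' @param breath One row of a [detect_breaths()] table.
#' @param fit A [fit_multilinear()] result for the same breath.
#' @return An object of class `ptp_result`: `ptp_max_prel` (cmH2O),
#'   `ptp_max` (cmH2O), `peak_idx` (sample index of the preliminary
#'   maximum), `peak_flow` (L/s).
#' @export
compute_ptp_max <- function(waves, breath, fit) {
  stop_if_not(inherits(fit, "mech_fit"), "`fit` must be a mech_fit")
  i0 <- breath$start_idx; i1 <- breath$insp_end_idx; i2 <- breath$end_idx
  seg <- i0:i2
  d <- waves$pao[seg] - waves$peso[seg]
  k <- which.max(d)
  fpeak <- max(waves$flow[i0:i1])
  structure(list(ptp_max_prel = d[k],
                 ptp_max = d[k] - fit$rrs * fpeak,
                 peak_idx = seg[k],
                 peak_flow = fpeak),
            class = "ptp_result")
}

#' Per-breath EAdi statistics
#'
#' Samples the diaphragm electrical activity over one breath: `eadi_max`
#' is the peak over the whole breath; `eadi_min` is the minimum over the
#' end-expiratory window, the final `end_exp_frac` of expiratory time.
#'
#' @param waves A `waveform_set` carrying `eadi_t`/`eadi` on their own
#'   timebase.
#' @param breath One row of a [detect_breaths()] table.
#' @param end_exp_frac Fraction of expiratory time (inspiratory end to
#'   breath end) forming the end-expiratory window.
#' @param offset Seconds to add to the EAdi timebase to land on the
#'   pressure/flow timebase (0 when recorded on a shared clock).
#' @return A list: `eadi_max`, `eadi_min` (uV).
#' @export
extract_eadi_stats <- function(waves, breath, end_exp_frac = 0.25,
                               offset = 0) {
  te <- waves$eadi_t + offset
  in_breath <- te >= breath$t_start & te <= breath$t_end
  stop_if_not(any(in_breath), "no EAdi samples cover the breath window")
  w0 <- breath$t_end - end_exp_frac * (breath$t_end - breath$t_insp_end)
  in_win <- te >= w0 & te <= breath$t_end
  stop_if_not(any(in_win), "end-expiratory EAdi window is empty")
  list(eadi_max = max(waves$eadi[in_breath]),
       eadi_min = min(waves$eadi[in_win]))
}

#' Per-breath mechanics table for one recording
#'
#' Runs breath detection, equation-of-motion fitting, resistive-corrected
#' maximal transpulmonary pressure and EAdi statistics over a waveform
#' set, returning one row per detected breath.  Breaths failing the tidal
#' volume filter or the fit reliability threshold are retained with
#' `kept = FALSE`.
#'
#' @param waves A `waveform_set`.
#' @param settle_time Breaths starting before this time (s) are flagged as
#'   settling and not kept.
#' @param pressure Pressure channel for [fit_multilinear()].
#' @param r2_min Reliability threshold on the fit.
#' @param min_tv,hysteresis Passed to [detect_breaths()].
#' @param end_exp_frac Passed to [extract_eadi_stats()].
#' @return A data.frame with one row per breath: timing, `tv`,
#'   `peak_flow`, `rr_local`, `rrs`, `ers`, `r2`, `ptp_max_prel`,
#'   `ptp_max`, `eadi_max`, `eadi_min`, `kept`.
#' @export
analyze_waveforms <- function(waves, settle_time = 0,
                              pressure = "transpulmonary",
                              r2_min = 0.8, min_tv = 0.01,
                              hysteresis = 0.02, end_exp_frac = 0.25) {
  b <- detect_breaths(waves, hysteresis = hysteresis, min_tv = min_tv)
  if (!nrow(b)) return(b)
  b$rrs <- NA_real_; b$ers <- NA_real_; b$r2 <- NA_real_
  b$ptp_max_prel <- NA_real_; b$ptp_max <- NA_real_
  b$eadi_max <- NA_real_; b$eadi_min <- NA_real_
  has_eadi <- !is.null(waves$eadi) && length(waves$eadi) > 0
  for (k in seq_len(nrow(b))) {
    br <- b[k, ]
    fit <- tryCatch(fit_multilinear(waves, br, pressure = pressure,
                                    r2_min = r2_min),
                    error = function(e) NULL)
    if (is.null(fit)) { b$kept[k] <- FALSE; next }
    b$rrs[k] <- fit$rrs; b$ers[k] <- fit$ers; b$r2[k] <- fit$r2
    if (!fit$reliable) b$kept[k] <- FALSE
    ptp <- compute_ptp_max(waves, br, fit)
    b$ptp_max_prel[k] <- ptp$ptp_max_prel
    b$ptp_max[k] <- ptp$ptp_max
    if (has_eadi) {
      es <- tryCatch(extract_eadi_stats(waves, br,
                                        end_exp_frac = end_exp_frac),
                     error = function(e) NULL)
      if (!is.null(es)) { b$eadi_max[k] <- es$eadi_max
                          b$eadi_min[k] <- es$eadi_min }
    }
  }
  b$kept <- b$kept & b$t_start >= settle_time
  b
}
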