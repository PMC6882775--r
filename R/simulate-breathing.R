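# Evaluate the seeded expression with a locally scoped RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Muscle-pressure envelope: raised half-sine over the inspiratory time of
# each breath, zero in expiration (passive exhalation).
pmus_at <- function(t, starts, amps, ti) {
  p <- numeric(length(t))
  for (k in seq_along(starts)) {
    idx <- which(t >= starts[k] & t < starts[k] + ti)
    if (length(idx)) p[idx] <- amps[k] * sin(pi * (t[idx] - starts[k]) / ti)
  }
  p
}

# Integrate R*V' = u(t) - E*V with the implicit trapezoidal rule so that a
# trapezoidal re-integration of the emitted flow reproduces the emitted
# volume exactly and the equation of motion holds exactly at every sample.
trap_integrate_eom <- function(u, h, R, E, v0 = 0) {
  n <- length(u)
  f <- numeric(n)
  v <- numeric(n)
  v[1] <- v0
  f[1] <- (u[1] - E * v0) / R
  denom <- 1 + h * E / (2 * R)
  for (i in 2:n) {
    f[i] <- ((u[i] - E * (v[i - 1] + h / 2 * f[i - 1])) / R) / denom
    v[i] <- v[i - 1] + h / 2 * (f[i - 1] + f[i])
  }
  list(flow = f, volume = v)
}

#' Simulate assisted spontaneous breathing at one PEEP level
#'
#' Generates synchronized airway pressure, esophageal pressure, gastric
#' pressure, flow and volume channels (at `cfg$fs_wave`) plus a diaphragm
#' electrical activity channel (at `cfg$fs_eadi`) for a single-compartment
#' respiratory system breathing spontaneously under proportional
#' (EAdi-driven) assist at the given PEEP.  Respiratory rate and tidal
#' volume follow the linear PEEP drive models in `cfg`; the inspiratory
#' effort amplitude is calibrated so the realized tidal volume matches the
#' drive model, with optional breath-to-breath jitter.
#'
#' The emitted channels satisfy the transpulmonary equation of motion
#' `pao - peso = (peep - peso_baseline) + ers * V + rrs * V'` exactly at
#' every sample before noise injection.
#'
#' @param cfg A [sim_config()].
#' @param peep Applied PEEP, cmH2O.
#' @param duration Length of the recording, s; must cover at least one
#'   breath period at the drive model's rate.
#' @param seed Optional integer overriding `cfg$seed`.
#' @return A list with components `waves` (class `waveform_set`: fields
#'   `t`, `pao`, `peso`, `pga`, `flow`, `volume`, `fs`, `peep`, `eadi_t`,
#'   `eadi`, `fs_eadi`) and `gt` (ground truth: per-breath table with true
#'   timing, tidal volume, effort amplitude and EAdi extrema; clean
#'   channels; the true transpulmonary pressure trace and its per-breath
#'   maxima; the realized respiratory rate).
#' @export
simulate_breathing <- function(cfg, peep, duration, seed = NULL) {
  validate_sim_config(cfg)
  stop_if_not(peep >= 0, "`peep` must be >= 0")
  seed <- as.integer(seed %||% cfg$seed)

  rr <- cfg$rr_intercept + cfg$rr_slope * peep
  if (rr < 1) {
    warning(sprintf("drive model gives RR = %.2f /min at PEEP %g; clipped to 1",
                    rr, peep))
    rr <- 1
  }
  period <- 60 / rr
  stop_if_not(duration >= period,
              "`duration` must cover at least one breath period")
  ti <- cfg$ti_frac * period
  tv_target <- cfg$tv_intercept + cfg$tv_slope * peep
  E <- cfg$ers + cfg$ecw
  g <- cfg$nava_level / cfg$k_eadi   # assist pressure per unit Pmus

  h <- 1 / cfg$fs_wave
  n <- as.integer(round(duration * cfg$fs_wave)) + 1L
  t <- (seq_len(n) - 1L) * h

  # Amplitude calibration: the system is linear, so the steady-cycle tidal
  # volume is proportional to the effort amplitude.  Run a short
  # jitter-free rehearsal at unit amplitude and scale.
  ncal <- 8L
  cal_starts <- (seq_len(ncal) - 1L) * period
  tcal <- seq(0, ncal * period, by = h)
  ucal <- (1 + g) * pmus_at(tcal, cal_starts, rep(1, ncal), ti)
  cal <- trap_integrate_eom(ucal, h, cfg$rrs, E)
  last <- tcal >= (ncal - 1L) * period
  tv_unit <- max(cal$volume[last]) - cal$volume[which(last)[1L]]
  amp0 <- tv_target / tv_unit

  starts <- seq(0, duration, by = period)
  nb <- length(starts)
  amps <- with_seed(seed, {
    jit <- if (cfg$tv_jitter_frac > 0)
      pmax(0.2, 1 + cfg$tv_jitter_frac * stats::rnorm(nb)) else rep(1, nb)
    amp0 * jit
  })

  pmus <- pmus_at(t, starts, amps, ti)
  u <- (1 + g) * pmus
  sol <- trap_integrate_eom(u, h, cfg$rrs, E)
  v <- sol$volume
  flow <- sol$flow

  pao <- peep + g * pmus
  peso <- cfg$peso_baseline + cfg$ecw * v - pmus
  pga <- 8 + 0.2 * pmus

  n_e <- as.integer(round(duration * cfg$fs_eadi)) + 1L
  t_e <- (seq_len(n_e) - 1L) / cfg$fs_eadi
  eadi <- pmus_at(t_e, starts, amps, ti) / cfg$k_eadi + cfg$eadi_tonic

  ptp_prel <- pao - peso                      # transpulmonary trace
  ptp_elastic <- ptp_prel - cfg$rrs * flow    # = (peep - peso0) + ers * v

  # Per-breath ground truth on the true clock.
  gt_b <- data.frame(
    breath = seq_len(nb),
    t_start = starts,
    t_insp_end = starts + ti,
    t_end = starts + period,
    pmus_amp = amps,
    rr = rr
  )
  gt_b$tv <- vapply(seq_len(nb), function(k) {
    idx <- t >= starts[k] & t < starts[k] + period
    if (!any(idx)) return(NA_real_)
    max(v[idx]) - v[which(idx)[1L]]
  }, numeric(1))
  # Ground-truth resistive-corrected maximal transpulmonary pressure of
  # each breath: the clean (pao - peso) maximum minus true resistance
  # times the clean peak inspiratory flow; the purely elastic maximum
  # (peep - peso0 + ers * Vmax) is kept alongside for reference.
  gt_b$ptp_max <- vapply(seq_len(nb), function(k) {
    idx <- t >= starts[k] & t < starts[k] + period
    if (!any(idx)) return(NA_real_)
    insp <- idx & t < starts[k] + ti
    fpk <- if (any(insp)) max(flow[insp]) else max(flow[idx])
    max(ptp_prel[idx]) - cfg$rrs * fpk
  }, numeric(1))
  gt_b$ptp_elastic_max <- vapply(seq_len(nb), function(k) {
    idx <- t >= starts[k] & t < starts[k] + period
    if (!any(idx)) return(NA_real_)
    max(ptp_elastic[idx])
  }, numeric(1))
  gt_b$eadi_max <- amps / cfg$k_eadi + cfg$eadi_tonic
  gt_b$eadi_min <- cfg$eadi_tonic
  gt_b <- gt_b[gt_b$t_end <= duration + 1e-9, , drop = FALSE]

  clean <- list(pao = pao, peso = peso, pga = pga, flow = flow,
                volume = v, eadi = eadi, ptp = ptp_prel,
                ptp_elastic = ptp_elastic)

  if (cfg$noise_sd_frac > 0) {
    noisy <- with_seed(seed + 1000L, {
      add_noise <- function(x, frac) {
        rng <- diff(range(x))
        if (rng <= 0) return(x)
        x + stats::rnorm(length(x), sd = frac * rng)
      }
      list(pao = add_noise(pao, cfg$noise_sd_frac),
           peso = add_noise(peso, cfg$noise_sd_frac),
           pga = add_noise(pga, cfg$noise_sd_frac),
           flow = add_noise(flow, cfg$noise_sd_frac),
           eadi = pmax(0, add_noise(eadi, cfg$noise_sd_frac)))
    })
    pao <- noisy$pao; peso <- noisy$peso; pga <- noisy$pga
    flow <- noisy$flow; eadi <- noisy$eadi
  }

  waves <- structure(list(
    t = t, pao = pao, peso = peso, pga = pga, flow = flow, volume = v,
    fs = cfg$fs_wave, peep = peep,
    eadi_t = t_e, eadi = eadi, fs_eadi = cfg$fs_eadi
  ), class = "waveform_set")

  gt <- list(breaths = gt_b, clean = clean, rr = rr, period = period,
             ti = ti, tv_target = tv_target, peep = peep,
             peso_baseline = cfg$peso_baseline)
  list(waves = waves, gt = gt)
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf(
    "<waveform_set> %.1f s at %g Hz (EAdi %g Hz), PEEP %g cmH2O\n",
    max(x$t), x$fs, x$fs_eadi, x$peep))
  invisible(x)
}
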