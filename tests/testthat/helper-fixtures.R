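# Shared fixtures: small, fast study conditions for unit tests.  The
# physiological defaults themselves are exercised in test-acceptance.R.

quiet_cfg <- function(...) {
  sim_config(noise_sd_frac = 0, tv_jitter_frac = 0, ...)
}

small_phantom <- function(duration = 10, ...) {
  phantom_config(grid_shape = c(32L, 32L), duration = duration,
                 n_regions = 200L, ...)
}

# A deterministic phantom in which every recruitable region toggles once
# per breath: closing pressures just above PEEP (sustained through
# expiration), opening pressures below the tidal pressure peak.
toggling_phantom <- function(peep, frac = 0.05, grid = c(40L, 50L),
                             duration = 10, ...) {
  phantom_config(grid_shape = grid, mask_shape = "full",
                 recruitable_fraction = frac,
                 n_regions = prod(grid),
                 closing_pressure_mean = peep + 0.6,
                 closing_pressure_sd = 1e-6,
                 opening_offset_mean = 1, opening_offset_sd = 1e-6,
                 duration = duration, ...)
}

# Independent trapezoidal cumulative integral (oracle for volume checks).
trapz_cum <- function(x, h) {
  n <- length(x)
  c(0, cumsum((x[-1] + x[-n]) / 2) * h)
}

# Exact Kruskal-Wallis permutation oracle: statistic by the textbook
# formula and p by full enumeration of group assignments.
kw_oracle <- function(groups) {
  x <- unlist(groups); n <- lengths(groups); N <- length(x)
  H_of <- function(xx) {
    r <- rank(xx)
    idx <- split(seq_len(N), rep(seq_along(n), n))
    rbar <- vapply(idx, function(i) mean(r[i]), numeric(1))
    H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
    ties <- table(xx)
    H / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  H_obs <- H_of(x)
  perms <- combn(N, n[1])
  ps <- 0; tot <- 0
  # enumerate all assignments for exactly three groups
  stopifnot(length(n) == 3L)
  for (j in seq_len(ncol(perms))) {
    g1 <- perms[, j]
    rest <- setdiff(seq_len(N), g1)
    sub <- combn(rest, n[2])
    for (k in seq_len(ncol(sub))) {
      g2 <- sub[, k]
      g3 <- setdiff(rest, g2)
      Hp <- H_of(x[c(g1, g2, g3)])
      tot <- tot + 1
      if (Hp >= H_obs - 1e-12) ps <- ps + 1
    }
  }
  list(H = H_obs, p = ps / tot)
}
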