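test_that("volume integration: zero flow, closed-form half-sine, drift", {
  expect_equal(integrate_volume(rep(0, 100), fs = 200), rep(0, 100))

  # half-sine inspiratory flow, amplitude A over duration T: TV = 2AT/pi
  fs <- 200; A <- 0.8; Tdur <- 1.0
  t <- seq(0, Tdur, by = 1 / fs)
  f <- A * sin(pi * t / Tdur)
  v <- integrate_volume(f, fs = fs)
  expect_equal(max(v), 2 * A * Tdur / pi, tolerance = 1e-4)

  # independent trapezoid oracle
  expect_equal(v, trapz_cum(f, 1 / fs))

  # non-uniform grid rejected
  expect_error(integrate_volume(f, t = cumsum(runif(length(f)))),
               "not uniform")

  # drift correction zeroes volume at breath ends
  cfg <- quiet_cfg()
  sim <- simulate_breathing(cfg, 0, 6)
  b <- detect_breaths(sim$waves)
  vd <- integrate_volume(sim$waves$flow, fs = sim$waves$fs, breaths = b)
  expect_lt(max(abs(vd[b$end_idx])), 1e-12)
})

test_that("breath detection is accurate, filtered, and idempotent", {
  w0 <- structure(list(t = seq(0, 5, by = 0.005), flow = rep(0, 1001),
                       fs = 200), class = "waveform_set")
  expect_equal(nrow(detect_breaths(w0)), 0L)

  cfg <- sim_config(rr_intercept = 30, rr_slope = 0, noise_sd_frac = 0.01,
                    tv_jitter_frac = 0.1, seed = 5)
  sim <- simulate_breathing(cfg, 3, 100)
  b <- detect_breaths(sim$waves)
  expect_true(abs(sum(b$kept) - 50) <= 1)
  expect_equal(mean(b$rr_local[b$kept]), 30, tolerance = 0.02)

  # simulator oracle: TV within 1%
  gt <- sim$gt$breaths
  match_gt <- sapply(b$t_start[b$kept], function(ts) {
    gt$tv[which.min(abs(gt$t_start - ts))]
  })
  expect_lt(median(abs(b$tv[b$kept] - match_gt) / match_gt), 0.01)

  # idempotence: re-detection on a crop spanning two breaths re-finds the
  # first breath with identical boundaries
  k <- which(b$kept)[3]
  seg <- b$start_idx[k]:b$end_idx[k + 1L]
  wseg <- structure(list(t = sim$waves$t[seg], flow = sim$waves$flow[seg],
                         fs = sim$waves$fs), class = "waveform_set")
  b2 <- detect_breaths(wseg)
  expect_gte(nrow(b2), 1L)
  expect_equal(b2$t_start[1], b$t_start[k], tolerance = 0.02)
  expect_equal(b2$t_insp_end[1], b$t_insp_end[k], tolerance = 0.02)
  expect_equal(b2$t_end[1], b$t_end[k], tolerance = 0.02)
})

test_that("drive-model sweep: mean detected RR within 2% at every PEEP", {
  cfg <- sim_config(seed = 11)
  for (peep in c(0, 6, 15)) {
    sim <- simulate_breathing(cfg, peep, 40, seed = 50 + peep)
    b <- detect_breaths(sim$waves)
    drive <- cfg$rr_intercept + cfg$rr_slope * peep
    expect_equal(mean(b$rr_local[b$kept]), drive, tolerance = 0.02)
  }
})

test_that("multilinear fit recovers mechanics exactly without noise", {
  for (rrs in c(5, 16.7, 30)) {
    for (ers in c(15, 30, 60)) {
      cfg <- quiet_cfg(rrs = rrs, ers = ers)
      sim <- simulate_breathing(cfg, 3, 6)
      b <- detect_breaths(sim$waves)
      fit <- fit_multilinear(sim$waves, b[2, ])
      expect_equal(fit$rrs, rrs, tolerance = 1e-6)
      expect_equal(fit$ers, ers, tolerance = 1e-6)
      expect_gt(fit$r2, 0.999)
    }
  }
})

test_that("fit agrees with a brute-force normal-equations solve", {
  cfg <- sim_config(seed = 8)
  sim <- simulate_breathing(cfg, 6, 10)
  b <- detect_breaths(sim$waves)
  k <- which(b$kept)[2]
  fit <- fit_multilinear(sim$waves, b[k, ])
  seg <- b$start_idx[k]:b$end_idx[k]
  f <- sim$waves$flow[seg]
  v <- trapz_cum(f, 1 / sim$waves$fs)
  p <- sim$waves$pao[seg] - sim$waves$peso[seg]
  X <- cbind(1, f, v)
  beta <- solve(t(X) %*% X, t(X) %*% p)
  expect_equal(fit$p0, beta[1], tolerance = 1e-9)
  expect_equal(fit$rrs, beta[2], tolerance = 1e-9)
  expect_equal(fit$ers, beta[3], tolerance = 1e-9)
})

test_that("flow rescaling rescales resistance as expected", {
  cfg <- quiet_cfg()
  sim <- simulate_breathing(cfg, 3, 6)
  b <- detect_breaths(sim$waves)
  fit <- fit_multilinear(sim$waves, b[2, ])
  w2 <- sim$waves
  w2$flow <- 2 * w2$flow   # halving resistance leaves pressures unchanged
  b2 <- detect_breaths(w2)
  fit2 <- fit_multilinear(w2, b2[2, ])
  expect_equal(fit2$rrs, fit$rrs / 2, tolerance = 1e-6)
  expect_equal(fit2$ers, fit$ers / 2, tolerance = 1e-6)
})

test_that("static or degenerate segments give an indeterminate-fit error", {
  cfg <- quiet_cfg()
  sim <- simulate_breathing(cfg, 3, 6)
  b <- detect_breaths(sim$waves)
  w <- sim$waves
  w$flow[] <- 0
  expect_error(fit_multilinear(w, b[2, ]), "identically zero")
  w$flow[] <- 1e-4   # constant flow: volume proportional to time, but
  w$pao[] <- 5       # constant pressure -> rank-deficient response ok;
  # constant flow makes flow column collinear with intercept
  expect_error(fit_multilinear(w, b[2, ]), "indeterminate")
})

test_that("noisy Monte-Carlo recovery: median resistance error under 5%", {
  cfg <- sim_config(noise_sd_frac = 0.02, tv_jitter_frac = 0.15, seed = 17)
  errs <- c()
  for (rep in 1:4) {
    sim <- simulate_breathing(cfg, 6, 55, seed = 1000 + rep)
    b <- detect_breaths(sim$waves)
    b <- b[b$kept, ]
    for (k in seq_len(nrow(b))) {
      fit <- fit_multilinear(sim$waves, b[k, ])
      errs <- c(errs, abs(fit$rrs - cfg$rrs) / cfg$rrs)
    }
    if (length(errs) >= 200) break
  }
  expect_gte(length(errs), 200)
  expect_lt(median(errs), 0.05)
})

test_that("ptp_max follows the resistive-correction formula", {
  # constructed breath: (pao - peso)max = 30, rrs = 10, peak flow = 1
  n <- 201
  t <- seq(0, 1, length.out = n)
  flow <- sin(pi * t)           # peak 1.0 at t = 0.5
  pao <- 10 + 20 * sin(pi * t)  # (pao - peso) max = 30 at t = 0.5
  w <- structure(list(t = t, pao = pao, peso = rep(-10 + 10 * 0, n),
                      flow = flow, fs = 1 / (t[2] - t[1])),
                 class = "waveform_set")
  w$peso <- rep(0, n)
  br <- data.frame(start_idx = 1L, insp_end_idx = 101L, end_idx = n)
  fit <- structure(list(rrs = 10, ers = 20, p0 = 0, r2 = 1,
                        rms_residual = 0, reliable = TRUE), class = "mech_fit")
  p <- compute_ptp_max(w, br, fit)
  expect_equal(p$ptp_max_prel, 30)
  expect_equal(p$ptp_max, 20)
  # rrs = 0 leaves the preliminary value untouched
  fit0 <- structure(list(rrs = 0), class = "mech_fit")
  expect_equal(compute_ptp_max(w, br, fit0)$ptp_max, 30)
  # invariant: corrected never exceeds preliminary for positive rrs
  expect_lte(p$ptp_max, p$ptp_max_prel)
})

test_that("ptp_max matches the simulator's ground truth within 5%", {
  cfg <- quiet_cfg()
  for (peep in c(3, 9, 15)) {
    sim <- simulate_breathing(cfg, peep, 30)
    b <- detect_breaths(sim$waves)
    b <- b[b$kept & b$t_start > 2, ]
    gt <- sim$gt$breaths
    for (k in seq_len(min(3, nrow(b)))) {
      fit <- fit_multilinear(sim$waves, b[k, ])
      p <- compute_ptp_max(sim$waves, b[k, ], fit)
      gk <- which.min(abs(gt$t_start - b$t_start[k]))
      expect_equal(p$ptp_max, gt$ptp_max[gk], tolerance = 0.05)
    }
  }
})

test_that("EAdi statistics: constants, simulator oracle, amplitude trend", {
  w <- structure(list(eadi_t = seq(0, 2, by = 0.01),
                      eadi = rep(1, 201)), class = "waveform_set")
  br <- data.frame(t_start = 0.2, t_insp_end = 0.8, t_end = 1.8)
  es <- extract_eadi_stats(w, br)
  expect_equal(es$eadi_max, 1)
  expect_equal(es$eadi_min, 1)

  cfg <- quiet_cfg(eadi_tonic = 0.5)
  sim <- simulate_breathing(cfg, 6, 12)
  b <- detect_breaths(sim$waves)
  b <- b[b$kept, ]
  gt <- sim$gt$breaths
  for (k in 2:3) {
    es <- extract_eadi_stats(sim$waves, b[k, ])
    gk <- which.min(abs(gt$t_start - b$t_start[k]))
    expect_equal(es$eadi_max, gt$eadi_max[gk], tolerance = 0.05)
    expect_equal(es$eadi_min, 0.5, tolerance = 0.05)
  }

  # raising assist-phase amplitude raises eadi_max, not the tonic floor
  cfg2 <- quiet_cfg(eadi_tonic = 0.5, tv_intercept = 0.12)
  sim2 <- simulate_breathing(cfg2, 6, 12)
  b2 <- detect_breaths(sim2$waves); b2 <- b2[b2$kept, ]
  es1 <- extract_eadi_stats(sim$waves, b[2, ])
  es2 <- extract_eadi_stats(sim2$waves, b2[2, ])
  expect_gt(es2$eadi_max, es1$eadi_max)
  expect_equal(es2$eadi_min, 0.5, tolerance = 0.05)
})
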