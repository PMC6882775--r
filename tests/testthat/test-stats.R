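test_that("Kruskal-Wallis: identical groups, enumeration oracle, ties", {
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1)))$H, 0)
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1)))$p, 1)

  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis(g)
  orc <- kw_oracle(g)
  expect_equal(kw$H, orc$H, tolerance = 1e-12)
  # chi-square p is an approximation; the exact permutation p is the
  # reference for the extreme separation case
  expect_lt(orc$p, 0.05)
  expect_lt(kw$p, 0.05)

  # tie-corrected H equals the hand formula
  gt <- list(c(1, 2, 2), c(2, 3, 4), c(5, 6, 6))
  kwt <- kruskal_wallis(gt)
  x <- unlist(gt); N <- 9; r <- rank(x)
  rb <- tapply(r, rep(1:3, each = 3), mean)
  H <- 12 / (N * (N + 1)) * sum(3 * (rb - (N + 1) / 2)^2)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(kwt$H, H, tolerance = 1e-12)
})

test_that("Dunn-Sidak post hoc: identities and separation pattern", {
  # two identical groups: adjusted p = 1 (m = 1, raw p = 1)
  g2 <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  ph2 <- dunn_sidak_posthoc(g2)
  expect_equal(nrow(ph2), 1L)
  expect_equal(ph2$p_adj, 1)

  # m = 1: Sidak adjustment is the identity
  g2b <- list(a = c(1, 2, 3, 9), b = c(4, 5, 6, 7))
  ph <- dunn_sidak_posthoc(g2b)
  expect_equal(ph$p_adj, ph$p_raw, tolerance = 1e-12)

  # monotonicity: adjusted p >= raw p, all unordered pairs covered
  set.seed(10)
  g3 <- list(lo = rnorm(20), mid = rnorm(20, 2), hi = rnorm(20, 8))
  ph3 <- dunn_sidak_posthoc(g3)
  expect_equal(nrow(ph3), 3L)
  expect_true(all(ph3$p_adj >= ph3$p_raw - 1e-12))
  expect_true(all(ph3$p_adj >= 0 & ph3$p_adj <= 1))
  # far-apart pair flagged; the CI of that pair excludes zero
  far <- ph3[ph3$x == "lo" & ph3$y == "hi", ]
  expect_true(far$significant)
  expect_true(far$ci_high < 0)

  # single group: empty table
  expect_equal(nrow(dunn_sidak_posthoc(list(a = 1:3))), 0L)
})

test_that("Ansari-Bradley matches exhaustive enumeration on small cases", {
  check_exact <- function(x, y) {
    res2 <- ansari_bradley(x, y, "two.sided", center = FALSE)
    res1 <- ansari_bradley(x, y, "greater", center = FALSE)
    pooled <- c(x, y); N <- length(pooled); m <- length(x)
    a <- pmin(rank(pooled), N + 1 - rank(pooled))
    allsums <- apply(combn(N, m), 2, function(ix) sum(a[ix]))
    ab <- sum(a[seq_len(m)])
    expect_equal(res2$ab, ab)
    expect_equal(res1$p, mean(allsums <= ab), tolerance = 1e-12)
    expect_equal(res2$p, min(1, 2 * min(mean(allsums <= ab),
                                        mean(allsums >= ab))),
                 tolerance = 1e-12)
    expect_equal(res2$method, "exact")
  }
  set.seed(3)
  check_exact(rnorm(4), rnorm(4))
  check_exact(rnorm(6, sd = 3), rnorm(6))
  check_exact(rnorm(5), rnorm(7, sd = 0.3))

  # identical samples: degenerate path
  same <- c(2, 2, 2, 2)
  expect_equal(ansari_bradley(same, same)$p, 1)
  expect_false(ansari_bradley(same, same)$h)

  # cross-check against the standard implementation on pre-centered data
  x <- c(-1.8, -0.2, 0.4, 1.1, 2.3, -0.9)
  y <- c(-0.5, 0.1, 0.3, -0.25, 0.15, 0.55)
  mine <- ansari_bradley(x, y, "two.sided", center = FALSE)
  ref <- stats::ansari.test(x, y, alternative = "two.sided", exact = TRUE)
  expect_equal(mine$ab, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("Ansari-Bradley one-tailed direction and tie handling", {
  set.seed(8)
  wide <- rnorm(15, sd = 6); narrow <- rnorm(15, sd = 1)
  expect_lt(ansari_bradley(wide, narrow, "greater")$p, 0.05)
  expect_gt(ansari_bradley(narrow, wide, "greater")$p, 0.5)

  # ties force the normal approximation even at small pooled size
  xt <- c(1, 2, 2, 3); yt <- c(2, 2, 4, 0)
  res <- ansari_bradley(xt, yt, center = FALSE)
  expect_equal(res$method, "normal")
  expect_true(res$p >= 0 && res$p <= 1)
})

test_that("Ansari-Bradley type-I error stays near nominal under the null", {
  set.seed(99)
  reps <- 1000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    rej[i] <- ansari_bradley(rnorm(50), rnorm(50), "two.sided")$h
  }
  rate <- mean(rej)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("polynomial regression: interpolation, degenerate and oracle cases", {
  x <- c(-2, -1, 0, 1, 2, 3)
  y <- 0.5 * x^3 - 2 * x^2 + x - 4
  fit <- fit_regression(x, y, 3)
  expect_equal(fit$coefficients, c(0.5, -2, 1, -4), tolerance = 1e-9)
  expect_equal(fit$r2, 1)

  # constant response: r2 = 0
  expect_equal(fit_regression(x, rep(2, 6), 1)$r2, 0)

  # noisy linear data against a normal-equations oracle
  set.seed(12)
  xs <- runif(40, 0, 15); ys <- 1.1 * xs + 9 + rnorm(40)
  f1 <- fit_regression(xs, ys, 1)
  X <- cbind(1, xs)
  beta <- solve(t(X) %*% X, t(X) %*% ys)
  expect_equal(f1$coefficients, rev(as.vector(beta)), tolerance = 1e-9)
  expect_true(f1$p < 1e-6)

  expect_error(fit_regression(c(1, 1, 1, 1, 1), 1:5, 2), "all equal")
  expect_error(fit_regression(1:3, 1:3, 3), "n > degree")
})

test_that("Wilcoxon signed-rank in Q2 matches exact sign-flip enumeration", {
  a <- c(17.2, 14.1, 20.3, 11.8, 16.4, 18.9, 13.0, 15.5)
  b <- c(4.0, 3.1, 5.2, 3.9, 4.4, 4.8, 3.5, 4.1)
  d <- a - b
  wt <- wilcox.test(a, b, paired = TRUE)
  # enumeration over all 2^8 sign assignments of |d| ranks
  r <- rank(abs(d))
  Vobs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  Vall <- as.matrix(signs) %*% r
  p_exact <- mean(Vall >= Vobs) * 2
  p_exact <- min(1, 2 * min(mean(Vall >= Vobs), mean(Vall <= Vobs)))
  expect_equal(wt$p.value, p_exact, tolerance = 1e-9)

  # the battery wires this comparison for compartment fields
  rd_tbl <- data.frame(
    breath = 1:16,
    peep = rep(c(0, 15), each = 8),
    direction = "up",
    rd_pct_eelv = c(rnorm(8, 5, 2), rnorm(8, 1, 0.5)),
    atelectasis_ee_ml = c(a, b),
    atelectasis_ee_g = c(a, b) * 0.95,
    atelectasis_pct_eelw = c(a, b) * 2
  )
  rep_ <- run_q_battery(rd_tbl = rd_tbl)
  q2 <- rep_$q2[[1]]
  expect_equal(q2$field, "atelectasis_ee_ml")
  expect_equal(q2$p, p_exact, tolerance = 1e-9)
})

test_that("the Q battery reproduces programmed trends and null behavior", {
  set.seed(77)
  # synthetic per-breath table following the drive model signs
  peeps <- rep(c(0, 3, 6, 9, 12, 15, 12, 9, 6, 3, 0), each = 8)
  dirs <- rep(c(rep("up", 6), rep("down", 5)), each = 8)
  n <- length(peeps)
  bt <- data.frame(
    peep = peeps, direction = dirs,
    rr_local = 95 - 5.8 * peeps + rnorm(n, 0, 3),
    tv = 0.06 + 0.0206 * peeps + rnorm(n, 0, 0.01),
    ptp_max = 9 + 1.1 * peeps + rnorm(n, 0, 2),
    kept = TRUE
  )
  # R/D shrinking in mean and dispersion with PEEP
  rd <- data.frame(
    breath = seq_len(n), peep = peeps, direction = dirs,
    rd_pct_eelv = pmax(0, rnorm(n, 6 - 0.35 * peeps, 3 / (1 + 0.4 * peeps))),
    atelectasis_ee_ml = pmax(0, rnorm(n, 17 - 0.9 * peeps, 2)),
    atelectasis_ee_g = pmax(0, rnorm(n, 16 - 0.85 * peeps, 2)),
    atelectasis_pct_eelw = pmax(0, rnorm(n, 37 - 1.8 * peeps, 4))
  )
  rep_ <- run_q_battery(bt, rd)
  expect_lt(rep_$q1$rr$coefficients[1], 0)
  expect_gt(rep_$q1$tv$coefficients[1], 0)
  expect_lt(rep_$q3$kw_pooled$p, 0.01)
  q4 <- rep_$q4$lower_peep_more_dispersed
  expect_true(q4$h[q4$peep_low == 0 & q4$peep_high == 12])
  expect_equal(nrow(q4), choose(6, 2))
  expect_equal(length(rep_$q5), 3L)
  expect_gt(rep_$q5$linear$coefficients[1], 0)

  # constant R/D: no rejections anywhere
  rd0 <- rd
  rd0$rd_pct_eelv <- rep(c(2.0, 2.1, 1.9, 2.05), n / 4)
  rep0 <- run_q_battery(bt, rd0)
  expect_gt(rep0$q3$kw_pooled$p, 0.05)
  expect_true(all(!rep0$q4$lower_peep_more_dispersed$h))
  expect_true(all(!rep0$q4$updown_two_sided$h))
})
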