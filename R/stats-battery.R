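#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square approximation
#' (df = k - 1), via [stats::kruskal.test()].  The degenerate case of all
#' pooled values identical returns H = 0, p = 1.
#'
#' @param groups A list of numeric vectors (one per group).
#' @return A list: `H`, `p`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  stop_if_not(is.list(groups) && length(groups) >= 2L,
              "need at least 2 groups")
  stop_if_not(all(vapply(groups, length, integer(1)) >= 1L),
              "every group needs at least one observation")
  x <- unlist(groups, use.names = FALSE)
  stop_if_not(length(x) >= 3L, "need at least 3 observations in total")
  if (length(unique(x)) == 1L) {
    return(list(H = 0, p = 1, df = length(groups) - 1L, n = length(x)))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = length(x))
}

# Dunn's z statistic machinery shared by the post hoc table.
dunn_z <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  list(rbar = rbar, s2 = s2, n = lengths(groups), N = N)
}

#' Dunn's post hoc pairwise comparisons with Sidak correction
#'
#' After a Kruskal-Wallis test, compares every unordered pair of groups
#' with Dunn's mean-rank z statistic (tie-corrected pooled rank
#' variance).  Raw two-sided normal p-values are Sidak-adjusted,
#' `p_adj = 1 - (1 - p)^m` with `m` the number of pairs.  Alongside the
#' rank test, the difference of raw group means is reported with a
#' Sidak-level normal confidence interval based on the pooled
#' within-group variance; the significance flag follows the rank-based
#' adjusted p-value.
#'
#' @param groups A named list of numeric vectors.
#' @param alpha Significance level for flags and CI coverage.
#' @param pairs Optional two-column matrix of group indices restricting
#'   the comparisons (m then equals its row count).
#' @return A data.frame: `x`, `y` (group labels), `ci_low`, `mean_diff`,
#'   `ci_high`, `z`, `p_raw`, `p_adj`, `significant`.
#' @export
dunn_sidak_posthoc <- function(groups, alpha = 0.05, pairs = NULL) {
  stop_if_not(is.list(groups) && length(groups) >= 1L, "need groups")
  labs <- names(groups) %||% as.character(seq_along(groups))
  if (length(groups) < 2L) {
    return(data.frame(x = character(), y = character(), ci_low = numeric(),
                      mean_diff = numeric(), ci_high = numeric(),
                      z = numeric(), p_raw = numeric(), p_adj = numeric(),
                      significant = logical()))
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(length(groups), 2L))
  }
  m <- nrow(pairs)
  dz <- dunn_z(groups)
  # pooled within-group variance for the raw-mean CI
  devs <- unlist(lapply(groups, function(v) v - mean(v)), use.names = FALSE)
  df_w <- dz$N - length(groups)
  s2_pool <- if (df_w > 0) sum(devs^2) / df_w else NA_real_
  alpha_sidak <- 1 - (1 - alpha)^(1 / m)
  zcrit <- stats::qnorm(1 - alpha_sidak / 2)
  rows <- lapply(seq_len(m), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    se_rank <- sqrt(dz$s2 * (1 / dz$n[i] + 1 / dz$n[j]))
    z <- (dz$rbar[i] - dz$rbar[j]) / se_rank
    p_raw <- 2 * stats::pnorm(-abs(z))
    md <- mean(groups[[i]]) - mean(groups[[j]])
    se_mean <- sqrt(s2_pool * (1 / dz$n[i] + 1 / dz$n[j]))
    data.frame(x = labs[i], y = labs[j],
               ci_low = md - zcrit * se_mean, mean_diff = md,
               ci_high = md + zcrit * se_mean,
               z = unname(z), p_raw = p_raw,
               p_adj = min(1, 1 - (1 - p_raw)^m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  out
}

# Ansari-Bradley scores of the pooled sample: rank symmetrically from both
# ends (extremes score 1), midranks for ties.
ab_scores <- function(pooled) {
  N <- length(pooled)
  r <- rank(pooled)
  pmin(r, N + 1 - r)
}

# Exact null distribution of the AB statistic (sum of x scores) by
# dynamic-programming enumeration over all C(N, m) assignments.
# Scores are doubled so midranks stay integral.
ab_exact_dist <- function(scores2, m) {
  N <- length(scores2)
  maxsum <- sum(sort(scores2, decreasing = TRUE)[seq_len(m)])
  # ways[j+1, s+1] = number of j-subsets with doubled-score sum s
  ways <- matrix(0, m + 1L, maxsum + 1L)
  ways[1L, 1L] <- 1
  for (a in scores2) {
    jmax <- m
    for (j in seq(jmax, 1L)) {
      shifted <- c(rep(0, a), ways[j, seq_len(maxsum + 1L - a)])
      ways[j + 1L, ] <- ways[j + 1L, ] + shifted
    }
  }
  counts <- ways[m + 1L, ]
  counts / sum(counts)   # probability over doubled sums 0..maxsum
}

#' Ansari-Bradley test of equal dispersion
#'
#' Rank-based two-sample dispersion test.  Each sample is centered at its
#' own median (the test assumes equal locations), the samples are pooled
#' and ranked symmetrically from both ends so extreme values get low
#' scores; the statistic is the sum of scores of `x`.  The null
#' distribution is enumerated exactly when the pooled size is at most 20
#' and the pooled values are untied; otherwise a normal approximation
#' from the finite-population score moments is used.  The one-tailed
#' alternative `"greater"` states that `x` is more dispersed than `y`
#' (small AB statistic).
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param tail `"two.sided"` or `"greater"` (x more dispersed than y).
#' @param alpha Rejection level for the `h` flag.
#' @param center Center each sample at its own median before pooling.
#' @param exact_max Largest pooled size for exact enumeration.
#' @return A list of class `dispersion_test`: `ab` (statistic), `p`,
#'   `tail`, `h` (reject flag at `alpha`), `method` ("exact" or
#'   "normal"), `n_x`, `n_y`.
#' @export
ansari_bradley <- function(x, y, tail = c("two.sided", "greater"),
                           alpha = 0.05, center = TRUE, exact_max = 20L) {
  tail <- match.arg(tail)
  stop_if_not(length(x) >= 2L && length(y) >= 2L,
              "both samples need at least 2 observations")
  if (center) {
    x <- x - stats::median(x)
    y <- y - stats::median(y)
  }
  pooled <- c(x, y)
  m <- length(x); N <- length(pooled)
  if (length(unique(pooled)) == 1L) {
    res <- list(ab = sum(ab_scores(pooled)[seq_len(m)]), p = 1, tail = tail,
                h = FALSE, method = "degenerate", n_x = m, n_y = N - m)
    class(res) <- "dispersion_test"
    return(res)
  }
  a <- ab_scores(pooled)
  ab <- sum(a[seq_len(m)])
  has_ties <- anyDuplicated(pooled) > 0
  if (N <= exact_max && !has_ties) {
    dist <- ab_exact_dist(as.integer(round(2 * a)), m)
    sums <- seq_along(dist) - 1L          # doubled sums
    ab2 <- as.integer(round(2 * ab))
    p_le <- sum(dist[sums <= ab2])
    p_ge <- sum(dist[sums >= ab2])
    method <- "exact"
  } else {
    abar <- mean(a)
    varsum <- m * (N - m) / (N * (N - 1)) * sum((a - abar)^2)
    zden <- sqrt(varsum)
    p_le <- stats::pnorm((ab - m * abar) / zden)
    p_ge <- stats::pnorm((ab - m * abar) / zden, lower.tail = FALSE)
    method <- "normal"
  }
  p <- switch(tail,
              two.sided = min(1, 2 * min(p_le, p_ge)),
              greater = p_le)   # more dispersed x -> extreme ranks -> low AB
  res <- list(ab = ab, p = p, tail = tail, h = p < alpha,
              method = method, n_x = m, n_y = N - m)
  class(res) <- "dispersion_test"
  res
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf("<Ansari-Bradley %s (%s)> AB = %g, p = %.4g%s\n",
              x$tail, x$method, x$ab, x$p,
              if (x$h) " *" else ""))
  invisible(x)
}

#' Polynomial least-squares regression with fit statistics
#'
#' Fits `y` on a raw polynomial basis of `x` of the given degree and
#' reports the coefficients (highest power first), the coefficient of
#' determination and the overall F-test p-value.
#'
#' @param x,y Numeric vectors of equal length.
#' @param degree Polynomial degree (1, 2 or 3).
#' @return A list of class `regression_fit`: `degree`, `coefficients`
#'   (highest to lowest power), `r2`, `p`, `n`.
#' @export
fit_regression <- function(x, y, degree = 1L) {
  stop_if_not(degree %in% 1:3, "`degree` must be 1, 2 or 3")
  stop_if_not(length(x) == length(y), "`x` and `y` lengths differ")
  stop_if_not(length(x) > degree + 1L, "need n > degree + 1 observations")
  stop_if_not(length(unique(x)) > 1L, "`x` values are all equal")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient polynomial design", call. = FALSE)
  }
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) {
    r2 <- 0
    p <- 1
  } else {
    r2 <- clamp(1 - sum(stats::residuals(fit)^2) / sst, 0, 1)
    sm <- suppressWarnings(summary(fit))
    p <- if (is.null(sm$fstatistic)) NA_real_ else
      stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE)
  }
  structure(list(degree = as.integer(degree),
                 coefficients = rev(unname(stats::coef(fit))),
                 r2 = r2, p = unname(p), n = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit deg %d> coefs [%s], R2 = %.4f, p = %.3g\n",
              x$degree, paste(signif(x$coefficients, 4), collapse = ", "),
              x$r2, x$p))
  invisible(x)
}

peep_groups <- function(df, value, by_direction = FALSE) {
  if (by_direction) {
    key <- interaction(df$peep, df$direction, drop = TRUE, lex.order = TRUE)
  } else {
    key <- factor(df$peep, levels = sort(unique(df$peep)))
  }
  split(df[[value]], key)
}

#' Run the PEEP-response statistical battery (Q1-Q5)
#'
#' Executes the study's five hypothesis blocks on per-breath mechanics and
#' R/D tables:
#' \describe{
#'   \item{Q1}{Linear regressions of respiratory rate and tidal volume on
#'     PEEP (pooled across breaths; per subject when a `subject` column is
#'     present).}
#'   \item{Q2}{Wilcoxon signed-rank comparisons of per-breath compartment
#'     quantities (end-expiratory atelectasis volume/weight) between the
#'     PEEP extremes, pairing breaths by within-level order.}
#'   \item{Q3}{Kruskal-Wallis across PEEP levels on R/D (pooled limbs and
#'     per-limb), Dunn-Sidak post hoc over all PEEP pairs, and the
#'     ascending-vs-descending pairwise table per PEEP.}
#'   \item{Q4}{One-tailed Ansari-Bradley over all PEEP pairs (lower PEEP
#'     more dispersed) and two-tailed ascending-vs-descending dispersion
#'     per PEEP.}
#'   \item{Q5}{Degree 1-3 polynomial regressions of the
#'     resistive-corrected maximal transpulmonary pressure on PEEP.}
#' }
#' Sections whose inputs are missing are skipped with a message and
#' recorded as `NULL`.
#'
#' @param breath_tbl Per-breath mechanics table (`peep`, `direction`,
#'   `rr_local`, `tv`, `ptp_max`, `kept`).
#' @param rd_tbl R/D table of stacked [compute_rd()] rows.
#' @param rd_field Column of `rd_tbl` analyzed in Q3/Q4.
#' @param alpha Significance level used throughout.
#' @return A list of class `q_report` with elements `q1` ... `q5`.
#' @export
run_q_battery <- function(breath_tbl = NULL, rd_tbl = NULL,
                          rd_field = "rd_pct_eelv", alpha = 0.05) {
  rep_ <- list(q1 = NULL, q2 = NULL, q3 = NULL, q4 = NULL, q5 = NULL,
               alpha = alpha)

  if (!is.null(breath_tbl) && nrow(breath_tbl)) {
    bt <- breath_tbl[breath_tbl$kept %||% TRUE, , drop = FALSE]
    if (length(unique(bt$peep)) >= 3L) {
      q1 <- list(
        rr = fit_regression(bt$peep, bt$rr_local, 1L),
        tv = fit_regression(bt$peep, bt$tv, 1L)
      )
      if (!is.null(bt$subject)) {
        q1$per_subject <- lapply(split(bt, bt$subject), function(s) {
          list(rr = fit_regression(s$peep, s$rr_local, 1L),
               tv = fit_regression(s$peep, s$tv, 1L))
        })
      }
      rep_$q1 <- q1
      # degree-d polynomial needs more than d distinct PEEP levels
      k_lev <- length(unique(bt$peep))
      q5 <- lapply(1:3, function(d) {
        if (k_lev > d) fit_regression(bt$peep, bt$ptp_max, d) else NULL
      })
      names(q5) <- c("linear", "quadratic", "cubic")
      rep_$q5 <- q5
    } else message("Q1/Q5 skipped: fewer than 3 PEEP levels")
  } else message("Q1/Q5 skipped: no breath table")

  if (!is.null(rd_tbl) && nrow(rd_tbl)) {
    peeps <- sort(unique(rd_tbl$peep))
    lo <- min(peeps); hi <- max(peeps)

    # Q2: compartment quantities at the PEEP extremes (paired by order)
    paired_wilcox <- function(field) {
      a <- rd_tbl[[field]][rd_tbl$peep == lo]
      b <- rd_tbl[[field]][rd_tbl$peep == hi]
      n <- min(length(a), length(b))
      if (n < 3L) return(NULL)
      wt <- suppressWarnings(
        stats::wilcox.test(a[seq_len(n)], b[seq_len(n)], paired = TRUE))
      list(field = field, peep_low = lo, peep_high = hi, n = n,
           V = unname(wt$statistic), p = wt$p.value,
           mean_low = mean(a), mean_high = mean(b))
    }
    q2 <- Filter(Negate(is.null),
                 lapply(c("atelectasis_ee_ml", "atelectasis_ee_g",
                          "atelectasis_pct_eelw"), paired_wilcox))
    rep_$q2 <- if (length(q2)) q2 else NULL

    if (length(peeps) >= 2L) {
      g_pool <- peep_groups(rd_tbl, rd_field)
      g_limb <- peep_groups(rd_tbl, rd_field, by_direction = TRUE)
      q3 <- list(
        kw_pooled = kruskal_wallis(g_pool),
        kw_by_limb = if (length(g_limb) >= 2L) kruskal_wallis(g_limb) else NULL,
        posthoc_peep = dunn_sidak_posthoc(g_pool, alpha = alpha)
      )
      # ascending-vs-descending couples at the same PEEP
      both_dir <- peeps[vapply(peeps, function(p) {
        length(unique(rd_tbl$direction[rd_tbl$peep == p])) == 2L
      }, logical(1))]
      if (length(both_dir)) {
        labs <- names(g_limb)
        idx <- do.call(rbind, lapply(both_dir, function(p) {
          i <- which(labs == paste(p, "down", sep = "."))
          j <- which(labs == paste(p, "up", sep = "."))
          if (length(i) && length(j)) c(j, i) else NULL
        }))
        if (!is.null(idx)) {
          q3$posthoc_updown <- dunn_sidak_posthoc(g_limb, alpha = alpha,
                                                  pairs = idx)
        }
      }
      rep_$q3 <- q3

      # Q4: dispersion battery
      pair_idx <- t(utils::combn(length(peeps), 2L))
      ab_rows <- lapply(seq_len(nrow(pair_idx)), function(k) {
        i <- pair_idx[k, 1]; j <- pair_idx[k, 2]   # peeps[i] < peeps[j]
        xs <- g_pool[[i]]; ys <- g_pool[[j]]
        if (length(xs) < 2L || length(ys) < 2L) return(NULL)
        tst <- ansari_bradley(xs, ys, tail = "greater", alpha = alpha)
        data.frame(peep_low = peeps[i], peep_high = peeps[j],
                   ab = tst$ab, p = tst$p, h = tst$h, method = tst$method)
      })
      q4 <- list(lower_peep_more_dispersed =
                   do.call(rbind, Filter(Negate(is.null), ab_rows)))
      ud_rows <- lapply(both_dir, function(p) {
        xs <- rd_tbl[[rd_field]][rd_tbl$peep == p & rd_tbl$direction == "up"]
        ys <- rd_tbl[[rd_field]][rd_tbl$peep == p & rd_tbl$direction == "down"]
        if (length(xs) < 2L || length(ys) < 2L) return(NULL)
        tst <- ansari_bradley(xs, ys, tail = "two.sided", alpha = alpha)
        data.frame(peep = p, ab = tst$ab, p = tst$p, h = tst$h,
                   method = tst$method)
      })
      q4$updown_two_sided <- do.call(rbind, Filter(Negate(is.null), ud_rows))
      rep_$q4 <- q4
    }
  } else message("Q2-Q4 skipped: no R/D table")

  class(rep_) <- "q_report"
  rep_
}

#' @export
print.q_report <- function(x, ...) {
  cat("<q_report>\n")
  if (!is.null(x$q1)) {
    cat(sprintf("  Q1 RR~PEEP slope %.3f (R2 %.3f), TV~PEEP slope %.5f (R2 %.3f)\n",
                x$q1$rr$coefficients[1], x$q1$rr$r2,
                x$q1$tv$coefficients[1], x$q1$tv$r2))
  }
  if (!is.null(x$q3)) {
    cat(sprintf("  Q3 KW pooled: H = %.2f, p = %.3g\n",
                x$q3$kw_pooled$H, x$q3$kw_pooled$p))
  }
  if (!is.null(x$q4) && !is.null(x$q4$lower_peep_more_dispersed)) {
    cat(sprintf("  Q4 one-tailed AB pairs: %d (rejections: %d)\n",
                nrow(x$q4$lower_peep_more_dispersed),
                sum(x$q4$lower_peep_more_dispersed$h)))
  }
  if (!is.null(x$q5) && !is.null(x$q5$cubic)) {
    cat(sprintf("  Q5 cubic R2 = %.3f\n", x$q5$cubic$r2))
  }
  invisible(x)
}
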