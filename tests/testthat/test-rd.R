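mk_profile <- function(non_ml, non_g, lung_ml, tissue_g, gas_ml) {
  structure(list(
    compartments = data.frame(compartment = "non", voxel_count = NA,
                              volume_ml = non_ml, weight_g = non_g),
    lung_volume_ml = lung_ml, tissue_weight_g = tissue_g,
    gas_volume_ml = gas_ml, timestamp = NA_real_
  ), class = "aeration_profile")
}

test_that("R/D arithmetic follows its definition", {
  ee <- mk_profile(10, 9.5, 100, 60, 40)
  ei <- mk_profile(7, 6.7, 100, 60, 43)
  rd <- compute_rd(ee, ei, breath = 1, peep = 6, direction = "up")
  expect_equal(rd$rd_volume_ml, 3)
  expect_equal(rd$rd_pct_eelv, 3)
  expect_equal(rd$rd_weight_g, 2.8)
  expect_equal(rd$rd_pct_eelw, 100 * 2.8 / 60)
  expect_equal(rd$atelectasis_ee_ml, 10)
  expect_equal(rd$atelectasis_pct_eelw, 100 * 9.5 / 60)
  expect_false(rd$negative_rd)

  # identical frames give zero in every normalization
  rd0 <- compute_rd(ee, ee)
  expect_equal(rd0$rd_volume_ml, 0)
  expect_equal(rd0$rd_pct_eelv, 0)
  expect_equal(rd0$rd_pct_eelw, 0)

  # negative R/D is retained and flagged, not clipped
  rdn <- compute_rd(ei, ee)
  expect_equal(rdn$rd_volume_ml, -3)
  expect_true(rdn$negative_rd)

  # gas-volume denominator option
  rdg <- compute_rd(ee, ei, denominator = "gas")
  expect_equal(rdg$rd_pct_eelv, 100 * 3 / 40)

  # zero denominators error
  bad <- mk_profile(0, 0, 0, 0, 0)
  expect_error(compute_rd(bad, bad), "zero")
})

test_that("phantom programmed at 5% of eeLV toggling recovers 5.0%", {
  cfg <- sim_config(seed = 2)
  sim <- simulate_breathing(cfg, 3, 13)
  pcfg <- toggling_phantom(peep = 3, frac = 0.05)
  ct <- simulate_ct_sequence(pcfg, sim)
  sy <- synchronize(ct_gas_series(ct$seq), sim$waves)
  b <- detect_breaths(sim$waves)
  pairs <- select_breath_frames(sy, b[b$kept, ], ct$seq)
  prof <- tidalRD:::profile_sequence(ct$seq)
  rd <- sapply(seq_len(nrow(pairs)), function(k) {
    compute_rd(tidalRD:::profile_from_row(prof[pairs$ee_frame_idx[k], ]),
               tidalRD:::profile_from_row(prof[pairs$ei_frame_idx[k], ]))$rd_pct_eelv
  })
  quantum <- 100 * ct$gt$lung$voxel_volume_ml /
    (ct$gt$lung$npx * ct$gt$lung$voxel_volume_ml)
  expect_lt(abs(median(rd) - 5.0), quantum + 1e-9)
})

test_that("R/D volume and weight are density-consistent and bounded", {
  cfg <- sim_config(seed = 6)
  sim <- simulate_breathing(cfg, 3, 13)
  ct <- simulate_ct_sequence(small_phantom(seed = 6), sim)
  sy <- synchronize(ct_gas_series(ct$seq), sim$waves)
  b <- detect_breaths(sim$waves)
  pairs <- select_breath_frames(sy, b[b$kept, ], ct$seq)
  prof <- tidalRD:::profile_sequence(ct$seq)
  for (k in seq_len(min(5, nrow(pairs)))) {
    rd <- compute_rd(tidalRD:::profile_from_row(prof[pairs$ee_frame_idx[k], ]),
                     tidalRD:::profile_from_row(prof[pairs$ei_frame_idx[k], ]))
    expect_lte(abs(rd$rd_volume_ml), rd$eelv_ml)
    if (rd$rd_volume_ml > 0) {
      # toggled voxels are collapsed tissue near water density minus the
      # open-state gas content; the g/ml ratio must be physically plausible
      expect_gt(rd$rd_weight_g / rd$rd_volume_ml, 0)
      expect_lt(rd$rd_weight_g / rd$rd_volume_ml, 1.1)
    }
  }
})

test_that("aggregation by PEEP and direction matches a hand oracle", {
  m <- data.frame(
    breath = 1:6,
    peep = c(0, 0, 0, 0, 6, 6),
    direction = c("up", "up", "down", "down", "up", "up"),
    rd_pct_eelv = c(4, 6, 3, 5, 1, 2)
  )
  agg <- aggregate_by_peep(m, fields = "rd_pct_eelv")
  pooled <- agg$pooled
  expect_equal(pooled$rd_pct_eelv_mean[pooled$peep == 0], mean(c(4, 6, 3, 5)))
  expect_equal(pooled$rd_pct_eelv_sd[pooled$peep == 0], sd(c(4, 6, 3, 5)))
  expect_equal(pooled$n, c(4L, 2L))
  bpd <- agg$by_peep_direction
  up0 <- bpd[bpd$peep == 0 & bpd$direction == "up", ]
  expect_equal(up0$rd_pct_eelv_mean, 5)
  expect_equal(up0$rd_pct_eelv_sd, sd(c(4, 6)))

  # single-measure groups report NA sd and n = 1
  one <- aggregate_by_peep(m[5, , drop = FALSE], fields = "rd_pct_eelv")
  expect_equal(one$pooled$n, 1L)
  expect_true(is.na(one$pooled$rd_pct_eelv_sd))
})
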