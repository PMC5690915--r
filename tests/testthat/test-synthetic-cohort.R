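test_that("degenerate generator propagates deterministically through the gate", {
  # all spreads zero, no biases: every XC is exactly zero and no XV is taken
  zero <- cohort_truth(n_treatments = 4L, fractions_per_treatment = rep(3L, 4),
                       n_patients = 4L,
                       frame_systematic = rep(0, 6), localizer_systematic = rep(0, 6),
                       mask_sd = rep(0, 6), setup_sd = rep(0, 6), xray_sd = rep(0, 6),
                       seed = 1)
  out <- generate_cohort(zero)
  expect_true(all(out$records$stage == "XC"))
  expect_true(all(as.matrix(out$records[, 5:10]) == 0))

  # a frame bias above tolerance forces one XV per fraction, carrying only
  # the localizer systematic
  biased <- cohort_truth(n_treatments = 4L, fractions_per_treatment = rep(3L, 4),
                         n_patients = 4L,
                         frame_systematic = c(1, 0, 0, 0, 0, 0),
                         localizer_systematic = c(0.1, 0, 0, 0, 0, 0),
                         mask_sd = rep(0, 6), setup_sd = rep(0, 6), xray_sd = rep(0, 6),
                         seed = 1)
  out2 <- generate_cohort(biased)
  xc <- out2$records[out2$records$stage == "XC", ]
  xv <- out2$records[out2$records$stage == "XV", ]
  expect_equal(nrow(xv), nrow(xc))
  expect_true(all(xc$lat_mm == 1))
  expect_true(all(xv$lat_mm == 0.1))
  expect_true(all(xv$long_mm == 0))
})

test_that("the generator is fully determined by its seed", {
  t1 <- cohort_truth(seed = 123)
  a <- generate_cohort(t1)
  b <- generate_cohort(cohort_truth(seed = 123))
  expect_identical(a, b)
  expect_identical(generate_wl_log(t1, 12), generate_wl_log(t1, 12))
  c <- generate_cohort(cohort_truth(seed = 124))
  expect_false(identical(a$records, c$records))
})

test_that("cohort moments match the generative parameters at large n", {
  # one treatment with many fractions: the grand XC mean estimates
  # mask bias + frame systematic, the SD estimates sqrt(setup^2 + xray^2)
  truth <- cohort_truth(n_treatments = 2400L,
                        fractions_per_treatment = rep(5L, 2400),
                        n_patients = 2400L, force_xv = TRUE, seed = 77)
  out <- generate_cohort(truth)
  xc <- out$records[out$records$stage == "XC", ]
  n <- nrow(xc)
  expect_equal(n, 12000)
  for (ax in c("lat_mm", "long_mm", "vert_mm")) {
    i <- match(ax, names(truth$frame_systematic))
    tot_sd <- sqrt(truth$mask_sd[i]^2 + truth$setup_sd[i]^2 + truth$xray_sd[i]^2)
    se <- tot_sd / sqrt(n)
    expect_lt(abs(mean(xc[[ax]]) - truth$frame_systematic[i]), 3 * se)
    # pooled within-treatment SD (mask bias removed) -> sqrt(setup^2 + xray^2)
    within <- xc |>
      dplyr::group_by(treatment_id) |>
      dplyr::mutate(dev = .data[[ax]] - mean(.data[[ax]])) |>
      dplyr::pull(dev)
    pooled <- sqrt(sum(within^2) / (n - 2400))
    expect_equal(pooled, unname(sqrt(truth$setup_sd[i]^2 + truth$xray_sd[i]^2)),
                 tolerance = 0.05)
  }
})

test_that("tolerance pass rate decreases as mask spread grows", {
  scales <- c(0.25, 1, 4)
  pass_rate <- vapply(scales, function(s) {
    truth <- cohort_truth(mask_sd = c(0.73, 2.05, 1.37, 0.51, 0.72, 0.87) * s,
                          seed = 31)
    rec <- generate_cohort(truth)$records
    xc <- rec[rec$stage == "XC", ]
    mean(within_tolerance(xc))
  }, numeric(1))
  expect_true(all(diff(pass_rate) <= 0))
  expect_gt(pass_rate[1], pass_rate[3])
})

test_that("Winston-Lutz logs honour their axis parameters", {
  truth <- cohort_truth(seed = 8)
  # zero spread: every record equals the configured mean offsets
  zero_ax <- wl_axis_reference()
  zero_ax[, c("sd_lat", "sd_long", "sd_vert")] <-
    lapply(zero_ax[, c("sd_lat", "sd_long", "sd_vert")], function(x) ifelse(is.na(x), NA, 0))
  t0 <- cohort_truth(wl_axes = zero_ax, seed = 8)
  log0 <- generate_wl_log(t0, n_sessions = 3)
  g <- log0[log0$axis == "gantry", ]
  expect_true(all(g$lat_mm == 0.27) && all(g$long_mm == 0.24) && all(g$vert_mm == 0.34))
  expect_true(all(is.na(log0$vert_mm[log0$axis == "collimator"])))

  # stochastic log: per-axis sample means within 3 SE of the truth
  log1 <- generate_wl_log(truth, n_sessions = 24)
  g1 <- log1[log1$axis == "gantry", ]
  for (ax in c("lat_mm", "long_mm", "vert_mm")) {
    mu <- wl_axis_reference()[[paste0("mean_", sub("_mm", "", ax))]][1]
    sd <- wl_axis_reference()[[paste0("sd_", sub("_mm", "", ax))]][1]
    expect_lt(abs(mean(g1[[ax]]) - mu), 3 * sd / sqrt(24))
  }
  expect_error(generate_wl_log(truth, n_sessions = 0), ">= 1")
})

test_that("couch-sag generation is a verbatim lookup", {
  truth <- cohort_truth(seed = 4)
  sag <- generate_couch_sag(truth)
  expect_identical(as.data.frame(sag), as.data.frame(couch_sag_reference()))
  row <- sag[sag$load_kg == 0 & sag$angle_deg == 45, ]
  expect_equal(c(row$lat_mm, row$long_mm, row$vert_mm), c(-0.20, 0.60, -0.30))
  empty <- cohort_truth(couch_sag_table = couch_sag_reference()[0, ], seed = 4)
  expect_equal(nrow(generate_couch_sag(empty)), 0)
})

test_that("heavy-tailed mask option widens extremes but keeps the location", {
  base <- cohort_truth(n_treatments = 400L, fractions_per_treatment = rep(1L, 400),
                       n_patients = 400L, seed = 55)
  heavy <- cohort_truth(n_treatments = 400L, fractions_per_treatment = rep(1L, 400),
                        n_patients = 400L, mask_tail_df = 3, seed = 55)
  b <- generate_cohort(base)$mask_bias
  h <- generate_cohort(heavy)$mask_bias
  expect_gt(max(abs(h$long_mm)), max(abs(b$long_mm)))
  expect_lt(abs(mean(h$long_mm)), 0.5)
})
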