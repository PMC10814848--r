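ne_fixture <- function(ct_target_fbs = c(15, 15.5, 16, 14.5),
                       ct_target_x1 = c(17, 17.5, 18, 16.5),
                       ct_best_shift = 0, ct_worst_shift = 0) {
  donors <- paste0("D", 1:4)
  ct <- rbind(
    TGT = c(ct_target_fbs, ct_target_x1),
    BEST = c(rep(12, 4), rep(12, 4) + ct_best_shift),
    WORST = c(rep(14, 4), rep(14, 4) + ct_worst_shift))
  colnames(ct) <- paste0(rep(donors, 2), "_", rep(c("FBS", "X1"), each = 4))
  make_ct(ct, conditions = rep(c("FBS", "X1"), each = 4),
          donors = rep(donors, 2))
}

test_that("fold_change implements delta-delta-Ct with antisymmetry", {
  x <- ne_fixture(ct_target_x1 = c(15, 15.5, 16, 14.5))  # identical Ct
  expect_equal(fold_change(x, "TGT", "BEST", c("X1", "FBS"), "D1"), 1)

  # delta-Ct 5 in the numerator condition, 3 in the reference -> 2^-2
  x2 <- ne_fixture(ct_target_fbs = rep(15, 4), ct_target_x1 = rep(17, 4))
  expect_equal(fold_change(x2, "TGT", "BEST", c("X1", "FBS"), "D1"), 0.25)
  expect_equal(fold_change(x2, "TGT", "BEST", c("FBS", "X1"), "D1"), 4)
  expect_equal(fold_change(x2, "TGT", "BEST", c("X1", "FBS"), "D1") *
                 fold_change(x2, "TGT", "BEST", c("FBS", "X1"), "D1"), 1)

  expect_error(fold_change(x2, "TGT", "TGT", c("X1", "FBS"), "D1"),
               "different genes")
  expect_error(fold_change(x2, "TGT", "BEST", c("X1", "FBS"), "D9"),
               "0 sample")
})

test_that("worst/best ratios flag normalizer-driven distortions", {
  x <- ne_fixture(ct_worst_shift = -1)  # worst HKG gains 1 Ct of signal in X1
  fb <- fold_change_set(x, "TGT", "BEST", c("X1", "FBS"))
  fw <- fold_change_set(x, "TGT", "WORST", c("X1", "FBS"))
  wb <- wb_ratio(fb, fw)
  expect_equal(wb$wb_ratio, rep(0.5, 4))
  expect_false(any(wb$flagged))

  # identical normalizers give ratio 1 everywhere
  wb1 <- wb_ratio(fb, fb)
  expect_equal(wb1$wb_ratio, rep(1, 4))

  # hand-computed ratio with flagging
  fb2 <- fb; fb2$fc <- rep(0.2, 4)
  fw2 <- fw; fw2$fc <- rep(0.5, 4)
  wb2 <- wb_ratio(fb2, fw2)
  expect_equal(wb2$wb_ratio, rep(2.5, 4))
  expect_true(all(wb2$flagged))
})

test_that("W/B ratio depends only on the normalizers, never on the target", {
  for (seed in 1:20) {
    ct <- rand_ct(3, 8, seed = 600 + seed)
    rownames(ct) <- c("TGT", "BEST", "WORST")
    donors <- rep(paste0("D", 1:4), 2)
    conds <- rep(c("A", "B"), each = 4)
    colnames(ct) <- paste0(donors, "_", conds)
    x <- make_ct(ct, conditions = conds, donors = donors)
    fb <- fold_change_set(x, "TGT", "BEST", c("B", "A"))
    fw <- fold_change_set(x, "TGT", "WORST", c("B", "A"))
    wb <- wb_ratio(fb, fw)
    # E^(dWorst - dBest) where d is the HKG's numerator-minus-reference Ct
    # change: only the two normalizers' behaviour enters
    for (i in 1:4) {
      d <- paste0("D", i)
      db <- ct["BEST", paste0(d, "_B")] - ct["BEST", paste0(d, "_A")]
      dw <- ct["WORST", paste0(d, "_B")] - ct["WORST", paste0(d, "_A")]
      expect_equal(wb$wb_ratio[wb$donor == d], 2^(dw - db),
                   tolerance = 1e-12)
    }
    # shifting the target equally in both conditions cannot change W/B
    ct2 <- ct; ct2["TGT", ] <- ct2["TGT", ] + 3
    x2 <- make_ct(ct2, conditions = conds, donors = donors)
    wb2 <- wb_ratio(fold_change_set(x2, "TGT", "BEST", c("B", "A")),
                    fold_change_set(x2, "TGT", "WORST", c("B", "A")))
    expect_equal(wb$wb_ratio, wb2$wb_ratio, tolerance = 1e-12)
  }
})

test_that("one-sample t-test against unity matches the reference implementation", {
  r <- one_sample_t_vs_unity(rep(1, 4))
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  expect_identical(r$tier, "ns")

  fc <- c(1.5, 2.0, 2.5, 2.0)
  r <- one_sample_t_vs_unity(fc)
  ref <- t.test(fc, mu = 1)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(r$mean, 2)
  expect_equal(r$sd, sqrt(1 / 6), tolerance = 1e-12)

  # mirroring around 1 flips the sign of t (valid while 2 - FC stays > 0)
  fcm <- c(0.6, 1.2, 1.4, 0.8)
  rm1 <- one_sample_t_vs_unity(fcm)
  rm2 <- one_sample_t_vs_unity(2 - fcm)
  expect_equal(rm2$t, -rm1$t, tolerance = 1e-12)
  expect_equal(rm2$p_value, rm1$p_value, tolerance = 1e-12)

  for (seed in 1:50) {
    fc <- withr::with_seed(seed, exp(rnorm(sample(3:10, 1), sd = 0.5)))
    mine <- one_sample_t_vs_unity(fc)
    ref <- t.test(fc, mu = 1)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  }

  expect_warning(rdeg <- one_sample_t_vs_unity(c(2, 2, 2)), "zero variance")
  expect_equal(rdeg$p_value, 0)
  expect_error(one_sample_t_vs_unity(1.5), "at least 2")

  # log-scale variant tests log2 FC against 0
  fc <- c(2, 4, 8)
  rl <- one_sample_t_vs_unity(fc, log_scale = TRUE)
  refl <- t.test(log2(fc), mu = 0)
  expect_equal(rl$p_value, refl$p.value, tolerance = 1e-12)
})

test_that("significance tiers follow the conventional cut points", {
  expect_identical(significance_tier(c(0.2, 0.05, 0.01, 0.001, 0.0001, 1e-6)),
                   c("ns", "*", "**", "***", "****", "****"))
})

test_that("merged report recovers a planted fold change and flags a biased normalizer", {
  # true 4-fold IL6 reduction in X1, nearly noiseless, stable normalizers
  cfg <- default_study_config(seed = 77,
                              target_log2fc = list(IL6 = c(X1 = -2, X2 = -2)))
  cfg$genes$noise_sd <- 0.02
  cfg$donor_sd <- 0.3
  cfg$condition_shift[hkg_genes, ] <- 0  # perfectly stable HKGs
  x <- generate_ct(cfg)
  rep <- merged_condition_report(x, "IL6", best_hkg = "GAPDH",
                                 worst_hkg = "TBP", comparison = c("X1", "FBS"))
  expect_equal(rep$merged$mean_fc_best, 0.25, tolerance = 0.05)
  expect_lt(rep$merged$p_best, 0.05)

  # identical best and worst normalizers give identical columns
  rep2 <- merged_condition_report(x, "IL6", "GAPDH", "GAPDH", c("X1", "FBS"))
  expect_equal(rep2$per_donor$fc_best, rep2$per_donor$fc_worst)
  expect_equal(rep2$wb_geomean_overall, 1, tolerance = 1e-12)

  # a worst normalizer that gains exactly 1 Ct in the numerator condition
  # inflates every apparent fold change twofold
  cfg3 <- cfg
  cfg3$condition_shift["TBP", "X1"] <- 1
  x3 <- generate_ct(cfg3)
  cfg3$genes$noise_sd[] <- 0
  cfg3$donor_sd <- 0
  x3 <- generate_ct(cfg3)
  # noiseless fold changes are exactly constant, so the t-test is degenerate
  rep3 <- suppressWarnings(
    merged_condition_report(x3, "IL6", "GAPDH", "TBP", c("X1", "FBS")))
  expect_equal(rep3$per_donor$wb_ratio, rep(2, 4), tolerance = 1e-12)
  expect_true(all(rep3$per_donor$flagged))
})
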