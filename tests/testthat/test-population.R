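test_that("bootstrap SD is zero for identical values and seed-reproducible", {
  b <- bootstrap_mean_sd(rep(2.5, 30), mean, 200, seed = 1)
  expect_equal(b$mean, 2.5)
  expect_equal(b$sd, 0)
  x <- rnorm(50)
  b1 <- bootstrap_mean_sd(x, mean, 500, seed = 9)
  b2 <- bootstrap_mean_sd(x, mean, 500, seed = 9)
  expect_identical(b1, b2)
  expect_false(identical(b1, bootstrap_mean_sd(x, mean, 500, seed = 10)))
  expect_error(bootstrap_mean_sd(numeric(0)), "at least 2")
})

test_that("bootstrap SD of a Gaussian mean approximates the analytic SE", {
  set.seed(12)
  x <- rnorm(100)
  b <- bootstrap_mean_sd(x, mean, 1000, seed = 3)
  expect_equal(b$sd, 0.1, tolerance = 0.2)
  # convergence at n = 1000: within 10% of sigma/sqrt(n)
  y <- rnorm(1000, sd = 2)
  b2 <- bootstrap_mean_sd(y, mean, 1000, seed = 4)
  expect_equal(b2$sd, 2 / sqrt(1000), tolerance = 0.1)
})

test_that("the fixed-difference significance rule matches the reported comparisons", {
  a <- data.frame(label = "untreated", mean_D = 0.0272, immobile_fraction = 0.131)
  b <- data.frame(label = "moenomycin", mean_D = 0.019, immobile_fraction = 0.226)
  cmp <- significant_difference(a, b, "mean_D")
  expect_true(cmp$significant)
  expect_equal(cmp$difference, 0.0082, tolerance = 1e-12)
  c2 <- data.frame(label = "lowdose", mean_D = 0.0250)
  expect_false(significant_difference(a, c2, "mean_D")$significant)
  # symmetric and reflexive-negative
  expect_identical(significant_difference(b, a, "mean_D")$significant,
                   cmp$significant)
  expect_false(significant_difference(a, a, "mean_D")$significant)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  out <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  # SSB = 13.5 (df 1), SSW = 4 (df 4) -> F = 13.5 / 1 = 13.5
  expect_equal(out$F, 13.5, tolerance = 1e-12)
  expect_equal(unname(out$df), c(1, 4))
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_error(one_way_anova(list(c(1, 2), c(3))), "at least 2")
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(5)
  ps <- replicate(1000, {
    one_way_anova(list(rnorm(6), rnorm(6), rnorm(6)))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("condition summaries recover the immobile fraction of a mixture", {
  set.seed(23)
  n <- 2000
  mobility <- ifelse(runif(n) < 0.25, "immobile", "mobile")
  motion <- data.frame(track_id = 1:n, n_frames = 8, mobility = mobility,
                       alpha = ifelse(mobility == "mobile", 1, NA),
                       D_um2_s = ifelse(mobility == "mobile",
                                        rnorm(n, 0.027, 0.01), NA),
                       alpha_in_range = mobility == "mobile",
                       exclusion_cause = NA_character_)
  s <- summarize_condition(motion, "mix", n_boot = 500, seed = 2)
  expect_lt(abs(s$immobile_fraction - 0.25), 0.04)
  expect_equal(s$mean_D, mean(motion$D_um2_s[mobility == "mobile"]))
  expect_gt(s$boot_sd_fraction, 0)
  # byte-identical under a fixed seed
  expect_identical(s, summarize_condition(motion, "mix", n_boot = 500, seed = 2))
})

test_that("all-immobile input yields fraction one and empty D with a warning", {
  motion <- data.frame(track_id = 1:10, n_frames = 8, mobility = "immobile",
                       alpha = NA_real_, D_um2_s = NA_real_,
                       alpha_in_range = NA, exclusion_cause = NA_character_)
  expect_warning(s <- summarize_condition(motion, "still", 100, 1), "no mobile")
  expect_equal(s$immobile_fraction, 1)
  expect_true(is.na(s$mean_D))
})

test_that("alpha-excluded tracks count in the denominator but not the D mean", {
  motion <- data.frame(track_id = 1:4, n_frames = 8,
                       mobility = c("immobile", "mobile", "mobile", "excluded"),
                       alpha = c(NA, 1, 1.2, 1.8),
                       D_um2_s = c(NA, 0.02, 0.03, 0.5),
                       alpha_in_range = c(NA, TRUE, TRUE, FALSE),
                       exclusion_cause = c(NA, NA, NA, "alpha_out_of_range"))
  s <- summarize_condition(motion, "c", 100, 1)
  expect_equal(s$immobile_fraction, 0.25)
  expect_equal(s$mean_D, 0.025)
  expect_identical(s$n_mobile_retained, 2L)
})
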