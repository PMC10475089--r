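test_that("mobility classification follows the one-pixel bounding box", {
  # confined to 100 x 100 nm
  set.seed(1)
  t1 <- data.frame(x_nm = runif(8, 0, 100), y_nm = runif(8, 0, 100))
  expect_identical(classify_mobility(t1), "immobile")
  # spans 500 nm in x only
  t2 <- data.frame(x_nm = seq(0, 500, length.out = 8), y_nm = rep(0, 8))
  expect_identical(classify_mobility(t2), "mobile")
  # all positions identical
  t3 <- data.frame(x_nm = rep(5, 6), y_nm = rep(5, 6))
  expect_identical(classify_mobility(t3), "immobile")
  # box side exactly 160 nm is not smaller than one pixel
  t4 <- data.frame(x_nm = c(0, 160), y_nm = c(0, 0))
  expect_identical(classify_mobility(t4), "mobile")
})

test_that("TAMSD has closed forms for ballistic and stationary motion", {
  v <- 100; tau <- 0.1 # nm per frame step
  tr <- data.frame(x_nm = v * (0:9), y_nm = rep(0, 10))
  curve <- tamsd(tr, tau)
  expect_equal(curve$tamsd_um2, ((v / 1000) * (1:9))^2, tolerance = 1e-12)
  still <- data.frame(x_nm = rep(3, 6), y_nm = rep(8, 6))
  expect_true(all(tamsd(still, tau)$tamsd_um2 == 0))
})

test_that("TAMSD equals the brute-force double loop exactly on random tracks", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    tr <- data.frame(x_nm = rnorm(n, 0, 300), y_nm = rnorm(n, 0, 300))
    expect_identical(tamsd(tr, 0.1)$tamsd_um2,
                     tamsd_bruteforce(tr, 0.1)$tamsd_um2)
  }
})

test_that("pair counts decrease with lag and lags increase", {
  tr <- data.frame(x_nm = rnorm(10), y_nm = rnorm(10))
  curve <- tamsd(tr, 0.1)
  expect_true(all(diff(curve$n_pairs) < 0))
  expect_true(all(diff(curve$lag_s) > 0))
})

test_that("anomalous fit recovers exact power laws", {
  # exact free diffusion: TAMSD = 4 * 0.01 * dt
  lag <- (1:6) * 0.1
  c1 <- data.frame(lag_s = lag, tamsd_um2 = 4 * 0.01 * lag, n_pairs = 6:1)
  f1 <- fit_anomalous(c1)
  expect_equal(f1$alpha, 1, tolerance = 1e-9)
  expect_equal(f1$D, 0.01, tolerance = 1e-9)
  # constant curve: alpha 0
  c2 <- data.frame(lag_s = lag, tamsd_um2 = rep(0.02, 6), n_pairs = 6:1)
  expect_equal(fit_anomalous(c2)$alpha, 0, tolerance = 1e-12)
  # ballistic: alpha 2
  c3 <- data.frame(lag_s = lag, tamsd_um2 = (0.1 * lag)^2, n_pairs = 6:1)
  expect_equal(fit_anomalous(c3)$alpha, 2, tolerance = 1e-9)
  # zero entries make the log fit undefined
  c4 <- data.frame(lag_s = lag, tamsd_um2 = c(0, 1, 2, 3, 4, 5), n_pairs = 6:1)
  expect_null(fit_anomalous(c4))
  expect_null(fit_anomalous(c1[1:3, ]))
})

test_that("alpha retention keeps [0, 1.5] inclusive", {
  expect_true(filter_alpha(1.0))
  expect_true(filter_alpha(0))
  expect_true(filter_alpha(1.5))
  expect_false(filter_alpha(1.6))
  expect_false(filter_alpha(-0.2))
})

test_that("diffusion fit recovers slope/4 and absorbs a static-noise offset", {
  lag <- (1:5) * 0.1
  c1 <- data.frame(lag_s = lag, tamsd_um2 = 4 * 0.02 * lag, n_pairs = 5:1)
  expect_equal(fit_diffusion_coefficient(c1)$D, 0.02, tolerance = 1e-12)
  # + 4 sigma^2 offset from 20 nm static error
  c2 <- c1; c2$tamsd_um2 <- c2$tamsd_um2 + 0.0016
  expect_equal(fit_diffusion_coefficient(c2)$D, 0.02, tolerance = 1e-12)
  # through-origin variant reproduces the no-offset formula
  expect_equal(fit_diffusion_coefficient(c1, through_origin = TRUE)$D, 0.02,
               tolerance = 1e-12)
  expect_null(fit_diffusion_coefficient(c1[1:3, ]))
})

test_that("per-track D and alpha recover truth on noise-free Brownian tracks", {
  D <- 0.0272
  tr <- simulate_planar_tracks(2000, D, localization_sigma = 0,
                               length_range = c(5, 12), seed = 202)
  res <- lapply(split(tr, tr$track_id), function(t) {
    curve <- tamsd(t, 0.1)
    c(D = fit_diffusion_coefficient(curve)$D,
      a = fit_anomalous(curve)$alpha)
  })
  res <- do.call(rbind, res)
  expect_equal(mean(res[, "D"]), D, tolerance = 0.10)
  expect_gt(median(res[, "a"]), 0.9)
  expect_lt(median(res[, "a"]), 1.1)
})

test_that("ballistic tracks get alpha near 2 and are excluded by the filter", {
  tr <- data.frame(track_id = 1, frame = 1:10,
                   x_nm = 150 * (1:10), y_nm = rep(0, 10))
  out <- analyze_tracks(tr, 0.1)
  expect_identical(out$mobility, "excluded")
  expect_equal(out$alpha, 2, tolerance = 1e-6)
  expect_identical(out$exclusion_cause, "alpha_out_of_range")
})

test_that("immobile classifier power matches an independent Monte-Carlo oracle", {
  set.seed(314)
  lens <- sample_track_lengths(2000)
  # oracle rates from the displacement distribution
  oracle_mobile <- bbox_immobile_rate_mc(0.0272, 20, lens)
  oracle_immobile <- bbox_immobile_rate_mc(0, 20, lens)
  # pipeline rates on generated tracks
  mob <- simulate_planar_tracks(2000, 0.0272, seed = 315)
  imm <- simulate_planar_tracks(2000, 0, seed = 316)
  rate_mob <- mean(analyze_tracks(mob)$mobility == "immobile")
  rate_imm <- mean(analyze_tracks(imm)$mobility == "immobile")
  expect_lt(abs(rate_mob - oracle_mobile), 0.03)
  expect_lt(abs(rate_imm - oracle_immobile), 0.03)
  # true immobile particles are recognized essentially always
  expect_gte(rate_imm, 0.9)
})

test_that("analyze_tracks composes the stages and is deterministic", {
  tr <- simulate_planar_tracks(300, 0.0272, seed = 17)
  out1 <- analyze_tracks(tr)
  out2 <- analyze_tracks(tr)
  expect_identical(out1, out2)
  expect_identical(out1$track_id, unique(tr$track_id)) # input order preserved
  # all-stationary input: all immobile, no fits
  still <- simulate_planar_tracks(50, 0, localization_sigma = 5, seed = 18)
  res <- analyze_tracks(still)
  expect_true(all(res$mobility == "immobile"))
  expect_true(all(is.na(res$alpha)))
  # 4-frame mobile tracks are excluded from fitting with a cause
  four <- data.frame(track_id = 1, frame = 1:4,
                     x_nm = c(0, 300, 600, 900), y_nm = 0)
  r4 <- analyze_tracks(four)
  expect_identical(r4$mobility, "mobile")
  expect_identical(r4$exclusion_cause, "too_few_lags")
  expect_true(is.na(r4$D_um2_s))
})

test_that("ensemble MSD fit agrees with per-track averaging on Brownian tracks", {
  D <- 0.0272
  tr <- simulate_planar_tracks(1500, D, localization_sigma = 20, seed = 55)
  ens <- ensemble_msd_fit(tr, 0.1)
  expect_equal(ens$D, D, tolerance = 0.10)
})
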