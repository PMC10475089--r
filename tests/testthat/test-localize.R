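test_that("a flat frame yields no candidates", {
  cfg <- imaging_config()
  expect_identical(nrow(detect_candidates(matrix(100, 30, 30), cfg)), 0L)
})

test_that("bright spots are detected at their pixel positions", {
  cfg <- imaging_config()
  hits <- 0L
  for (seed in 1:25) {
    set.seed(seed)
    pos <- cbind(runif(1, 1500, 3500), runif(1, 1500, 3500))
    fr <- render_test_frame(pos, photons = 8000, background = 10, seed = seed)
    cand <- detect_candidates(fr, cfg)
    if (nrow(cand) == 1 &&
        abs((cand$col - 0.5) * 160 - pos[1]) <= 240 &&
        abs((cand$row - 0.5) * 160 - pos[2]) <= 240) hits <- hits + 1L
  }
  expect_gte(hits, 24) # SNR ~ 20: essentially always one candidate within a pixel
})

test_that("two well-separated spots give two candidates", {
  pos <- rbind(c(1600, 1600), c(3200, 3200)) # 10 px apart in x and y
  fr <- render_test_frame(pos, photons = 8000, seed = 5)
  cand <- detect_candidates(fr, imaging_config())
  expect_identical(nrow(cand), 2L)
})

test_that("a noiseless rendered Gaussian is recovered to nanometre accuracy", {
  cfg <- imaging_config()
  truth <- c(2531, 2467)
  img <- sptpalm:::emitter_image(truth[1], truth[2], 32, 32, 160, 130, 5000) + 10
  fit <- fit_spot(img, list(row = 16, col = 16), cfg)
  expect_lt(abs(fit$x_nm - truth[1]), 1)
  expect_lt(abs(fit$y_nm - truth[2]), 1)
  expect_equal(fit$sigma_nm, 130, tolerance = 0.01)
  expect_equal(fit$amplitude, 5000, tolerance = 0.01)
})

test_that("5000-photon spots are localized with RMSE at or below 20 nm", {
  cfg <- imaging_config()
  err2 <- c()
  for (seed in 1:100) {
    set.seed(seed + 500)
    pos <- c(runif(1, 2400, 2720), runif(1, 2400, 2720))
    fr <- render_test_frame(rbind(pos), photons = 5000, background = 10,
                            seed = seed + 500)
    cand <- detect_candidates(fr, cfg)
    expect_gte(nrow(cand), 1)
    fit <- fit_spot(fr, cand[1, ], cfg)
    err2 <- c(err2, (fit$x_nm - pos[1])^2 + (fit$y_nm - pos[2])^2)
  }
  rmse <- sqrt(mean(err2) / 2) # per-axis RMSE
  expect_lte(rmse, 20)
})

test_that("the fitter matches a dense grid-search oracle of the same objective", {
  cfg <- imaging_config()
  px <- 160
  for (seed in 1:10) {
    set.seed(seed)
    pos <- c(runif(1, 2480, 2640), runif(1, 2480, 2640))
    fr <- render_test_frame(rbind(pos), photons = 5000, background = 10,
                            seed = seed + 40)
    cand <- detect_candidates(fr, cfg)
    fit <- fit_spot(fr, cand[1, ], cfg)

    # oracle: profile the linear parameters (signal, offset) in closed
    # form on a 1-nm grid of centers and a sigma grid, minimizing the
    # identical least-squares objective on the identical window
    half <- (cfg$fit_window - 1) %/% 2
    r <- (cand$row[1] - half):(cand$row[1] + half)
    cc <- (cand$col[1] - half):(cand$col[1] + half)
    v <- as.vector(fr[r, cc])
    npx <- length(v)
    gxs <- seq(pos[1] - 30, pos[1] + 30, by = 1)
    gys <- seq(pos[2] - 30, pos[2] + 30, by = 1)
    sigs <- seq(110, 160, by = 5)
    best <- c(ssr = Inf, x = NA, y = NA)
    phix <- function(x0, s) diff(pnorm(((min(cc) - 1):max(cc) * px - x0) / s))
    phiy <- function(y0, s) diff(pnorm(((min(r) - 1):max(r) * px - y0) / s))
    for (s in sigs) {
      pxs <- vapply(gxs, phix, numeric(length(cc)), s = s)
      pys <- vapply(gys, phiy, numeric(length(r)), s = s)
      nr_w <- length(r); nc_w <- length(cc)
      for (ix in seq_along(gxs)) {
        # columns index the y grid; rows run over the window pixels in the
        # same column-major order as v (row fastest, then column)
        g <- pys[rep(seq_len(nr_w), times = nc_w), , drop = FALSE] *
          pxs[rep(seq_len(nc_w), each = nr_w), ix]
        sg <- colSums(g); sgg <- colSums(g * g); sgv <- as.vector(crossprod(g, v))
        sv <- sum(v)
        det <- npx * sgg - sg^2
        aN <- (npx * sgv - sg * sv) / det
        b <- (sv - aN * sg) / npx
        ssr <- sum(v^2) - 2 * aN * sgv - 2 * b * sv +
          aN^2 * sgg + 2 * aN * b * sg + npx * b^2
        j <- which.min(ssr)
        if (ssr[j] < best["ssr"]) best <- c(ssr = ssr[j], x = gxs[ix], y = gys[j])
      }
    }
    expect_lt(abs(fit$x_nm - best["x"]), 2)
    expect_lt(abs(fit$y_nm - best["y"]), 2)
  }
})

test_that("candidates too close to the frame edge are skipped and logged", {
  cfg <- imaging_config(fit_window = 7)
  fr <- matrix(10, 20, 20)
  expect_warning(res <- fit_spot(fr, list(row = 2, col = 10), cfg), "edge")
  expect_null(res)
})

test_that("localization error scales as one over the square root of photons", {
  cfg <- imaging_config()
  photons <- c(500, 2000, 8000)
  rmse <- vapply(photons, function(ph) {
    e2 <- c()
    for (seed in 1:50) {
      set.seed(seed * 7 + ph)
      pos <- c(runif(1, 2400, 2720), runif(1, 2400, 2720))
      fr <- render_test_frame(rbind(pos), photons = ph, background = 10,
                              seed = seed * 7 + ph)
      cand <- detect_candidates(fr, cfg)
      if (nrow(cand) == 0) next
      fit <- fit_spot(fr, cand[1, ], cfg)
      if (is.null(fit)) next
      e2 <- c(e2, (fit$x_nm - pos[1])^2 + (fit$y_nm - pos[2])^2)
    }
    sqrt(mean(e2) / 2)
  }, numeric(1))
  slope <- coef(lm(log(rmse) ~ log(photons)))[2]
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)
})

test_that("localize_movie is deterministic, keeps frame indices, rejects non-2D", {
  loc <- data.frame(frame = c(1L, 3L), x_nm = c(1600, 2400), y_nm = c(1600, 2400))
  stack <- render_movie(loc, n_frames = 3, dim = c(30, 30), photons = 6000,
                        background = 10, seed = 12)
  out1 <- localize_movie(stack)
  out2 <- localize_movie(stack)
  expect_identical(out1, out2)
  expect_true(all(out1$frame %in% c(1L, 3L)))
  expect_identical(nrow(localize_movie(list())), 0L)
  expect_error(localize_movie(list(array(0, c(3, 3, 3)))), "non-2D")
})

test_that("round-tripping render plus fit recovers coordinates within 5 nm", {
  cfg <- imaging_config()
  for (seed in 1:5) {
    set.seed(seed)
    pos <- c(runif(1, 2450, 2670), runif(1, 2450, 2670))
    img <- sptpalm:::emitter_image(pos[1], pos[2], 32, 32, 160, 130, 50000) + 100
    cand <- detect_candidates(img, cfg)
    fit <- fit_spot(img, cand[1, ], cfg)
    expect_lt(sqrt((fit$x_nm - pos[1])^2 + (fit$y_nm - pos[2])^2), 5)
  }
})

test_that("a sparse simulated movie is localized near-completely", {
  # sptPALM-sparse activation: at most one visible emitter at a time in
  # most frames, so the window-merge rule rarely collapses real spots
  cell <- build_cell(5, 1, center = c(3.84, 1.92))
  cfg <- simulation_config(n_particles = 50, n_frames = 400,
                           activation_rate = 0.15, seed = 31)
  gt <- simulate_tracks(cell, cfg)
  stack <- render_movie(gt$localizations, n_frames = 400, dim = c(24, 48),
                        photons = 6000, background = 10, seed = 32)
  found <- localize_movie(stack)
  truth <- gt$localizations
  matched <- 0L
  for (i in seq_len(nrow(truth))) {
    ff <- found[found$frame == truth$frame[i], ]
    if (nrow(ff) == 0) next
    d <- sqrt((ff$x_nm - truth$x_nm[i])^2 + (ff$y_nm - truth$y_nm[i])^2)
    if (min(d) <= 80) matched <- matched + 1L
  }
  expect_gte(matched / nrow(truth), 0.95)
})
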