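#' Imaging and spot-fitting configuration
#'
#' @param pixel_size Pixel size in nm (default 160).
#' @param frame_interval Frame interval in seconds (default 0.1, 10 Hz).
#' @param detection_threshold Candidate threshold in multiples of the
#'   robust SD of the band-pass-filtered frame (default 5).
#' @param fit_window Side of the square fitting window in pixels; odd,
#'   at least 5 (default 9).
#' @param psf_sigma_start Starting value for the PSF sigma in the fit, nm.
#' @param dog_sigma Inner and outer sigmas (pixels) of the
#'   difference-of-Gaussians detection filter.
#' @return An `imaging_config` list.
#' @export
imaging_config <- function(pixel_size = 160, frame_interval = 0.1,
                           detection_threshold = 5, fit_window = 9,
                           psf_sigma_start = 130, dog_sigma = c(1, 3)) {
  stopifnot(pixel_size > 0, frame_interval > 0, detection_threshold > 0,
            fit_window >= 5, fit_window %% 2 == 1, length(dog_sigma) == 2)
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 detection_threshold = detection_threshold,
                 fit_window = as.integer(fit_window),
                 psf_sigma_start = psf_sigma_start,
                 dog_sigma = dog_sigma),
            class = "imaging_config")
}

#' Detect candidate spots in one frame
#'
#' Band-pass filters the frame with a difference of Gaussians (sigmas
#' `cfg$dog_sigma` pixels), finds strict 8-neighbourhood local maxima
#' exceeding `detection_threshold` times the robust (MAD) SD of the
#' filtered frame, and merges maxima closer than `fit_window` pixels,
#' keeping the brighter one.
#'
#' @param frame Numeric matrix (one image).
#' @param cfg An [imaging_config()].
#' @return data.frame `row, col` (1-based pixel indices), possibly empty.
#' @export
detect_candidates <- function(frame, cfg = imaging_config()) {
  stopifnot(is.matrix(frame))
  if (length(frame) == 0) return(data.frame(row = integer(), col = integer()))
  fr <- matrix(as.double(frame), nrow(frame), ncol(frame))
  dog <- EBImage::gblur(fr, sigma = cfg$dog_sigma[1]) -
         EBImage::gblur(fr, sigma = cfg$dog_sigma[2])
  thr <- cfg$detection_threshold * stats::mad(dog)
  mx <- local_maxima(dog)
  keep <- which(mx & dog > thr, arr.ind = TRUE)
  if (nrow(keep) == 0) return(data.frame(row = integer(), col = integer()))
  # brightest-first suppression of neighbours within one fit window
  ord <- order(dog[keep], decreasing = TRUE)
  keep <- keep[ord, , drop = FALSE]
  taken <- logical(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    if (i == 1) { taken[1] <- TRUE; next }
    prev <- keep[taken, , drop = FALSE]
    d2 <- (prev[, 1] - keep[i, 1])^2 + (prev[, 2] - keep[i, 2])^2
    taken[i] <- all(d2 >= cfg$fit_window^2)
  }
  out <- keep[taken, , drop = FALSE]
  data.frame(row = as.integer(out[, 1]), col = as.integer(out[, 2]))
}

# Strict local maxima over the 8-neighbourhood (edges excluded).
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(matrix(FALSE, nr, nc))
  res <- matrix(FALSE, nr, nc)
  ci <- 2:(nr - 1); cj <- 2:(nc - 1)
  ctr <- m[ci, cj]
  ok <- ctr > m[ci - 1, cj] & ctr > m[ci + 1, cj] &
        ctr > m[ci, cj - 1] & ctr > m[ci, cj + 1] &
        ctr > m[ci - 1, cj - 1] & ctr > m[ci - 1, cj + 1] &
        ctr > m[ci + 1, cj - 1] & ctr > m[ci + 1, cj + 1]
  res[ci, cj] <- ok
  res
}

#' Fit one candidate spot with an integrated symmetric 2D Gaussian
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the model
#' `b + N * [Phi((x - x0 + p/2)/s) - Phi((x - x0 - p/2)/s)] * [same in y]`
#' over a `fit_window` x `fit_window` window: a symmetric Gaussian of
#' total signal N integrated over each pixel, plus a constant offset.
#' The fitted center is returned in nm using the half-pixel-center
#' convention of [render_movie()].
#'
#' Fits are rejected (return `NULL`) when the candidate is closer than
#' half a window to the frame edge, the optimizer fails, the fitted
#' sigma falls outside `[0.3, 3]` pixels, or the center leaves the
#' window.
#'
#' @param frame Numeric matrix.
#' @param candidate List or data.frame row with `row`, `col` (1-based).
#' @param cfg An [imaging_config()].
#' @return One-row data.frame `x_nm, y_nm, amplitude, sigma_nm, offset,
#'   residual_rms`, or `NULL` with attribute-free warning on rejection.
#' @export
fit_spot <- function(frame, candidate, cfg = imaging_config()) {
  half <- (cfg$fit_window - 1L) %/% 2L
  r0 <- candidate$row - half; r1 <- candidate$row + half
  c0 <- candidate$col - half; c1 <- candidate$col + half
  if (r0 < 1 || c0 < 1 || r1 > nrow(frame) || c1 > ncol(frame)) {
    warning("candidate at (", candidate$row, ",", candidate$col,
            ") too close to the frame edge; skipped")
    return(NULL)
  }
  px <- cfg$pixel_size
  win <- frame[r0:r1, c0:c1]
  xs <- ((c0:c1) - 0.5) * px  # pixel-center x (nm), 1-based cols
  ys <- ((r0:r1) - 0.5) * px
  v <- as.vector(win)
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))

  b0 <- min(v)
  w <- pmax(v - b0, 0)
  if (sum(w) <= 0) return(NULL)
  start <- list(x0 = sum(gx * w) / sum(w), y0 = sum(gy * w) / sum(w),
                N = sum(w), b = b0, s = cfg$psf_sigma_start)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ b + N * (pnorm((gx - x0 + px / 2) / s) - pnorm((gx - x0 - px / 2) / s)) *
                  (pnorm((gy - y0 + px / 2) / s) - pnorm((gy - y0 - px / 2) / s)),
      start = start,
      lower = c(x0 = xs[1] - px, y0 = ys[1] - px, N = 0, b = -Inf, s = 0.05 * px),
      upper = c(x0 = xs[length(xs)] + px, y0 = ys[length(ys)] + px,
                N = Inf, b = Inf, s = 5 * px),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- as.list(stats::coef(fit))
  if (cf$s < 0.3 * px || cf$s > 3 * px) return(NULL)
  if (cf$x0 < xs[1] - px / 2 || cf$x0 > xs[length(xs)] + px / 2 ||
      cf$y0 < ys[1] - px / 2 || cf$y0 > ys[length(ys)] + px / 2) return(NULL)
  data.frame(x_nm = cf$x0, y_nm = cf$y0, amplitude = cf$N,
             sigma_nm = cf$s, offset = cf$b,
             residual_rms = sqrt(mean(stats::resid(fit)^2)))
}

#' Localize every frame of a movie
#'
#' Runs [detect_candidates()] and [fit_spot()] on each frame and
#' concatenates the results. Deterministic given its inputs. Rejected
#' fits are counted in the `rejections` attribute.
#'
#' @param stack List of numeric matrices (or a single matrix).
#' @param cfg An [imaging_config()].
#' @return data.frame `frame, x_nm, y_nm, amplitude, sigma_nm, offset,
#'   residual_rms` with attribute `rejections` (named counts).
#' @export
localize_movie <- function(stack, cfg = imaging_config()) {
  if (is.matrix(stack)) stack <- list(stack)
  stopifnot(is.list(stack))
  bad <- !vapply(stack, is.matrix, logical(1))
  if (any(bad)) stop("non-2D frame(s) at index: ", paste(which(bad), collapse = ", "))
  rej <- c(edge = 0L, fit = 0L)
  out <- vector("list", length(stack))
  for (f in seq_along(stack)) {
    cand <- detect_candidates(stack[[f]], cfg)
    if (nrow(cand) == 0) next
    fits <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      res <- withCallingHandlers(
        fit_spot(stack[[f]], cand[i, ], cfg),
        warning = function(w) {
          rej["edge"] <<- rej["edge"] + 1L
          invokeRestart("muffleWarning")
        })
      if (is.null(res)) {
        rej["fit"] <- rej["fit"] + 1L
      } else {
        fits[[i]] <- cbind(frame = f, res)
      }
    }
    out[[f]] <- do.call(rbind, fits)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                      amplitude = numeric(), sigma_nm = numeric(),
                      offset = numeric(), residual_rms = numeric())
  }
  rownames(res) <- NULL
  rej["fit"] <- rej["fit"] - rej["edge"]  # edge skips were counted once in fit loop
  attr(res, "rejections") <- rej
  res
}
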