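#' Classify a track as immobile or mobile
#'
#' A particle is immobile when the area it explores during its track
#' stays within one camera pixel: the axis-aligned bounding box of all
#' its positions must have both side lengths strictly smaller than
#' `box_size` (default 160 nm).
#'
#' @param track data.frame with `x_nm`, `y_nm` (one track).
#' @param box_size Bounding-box side threshold in nm.
#' @return `"immobile"` or `"mobile"`.
#' @export
classify_mobility <- function(track, box_size = 160) {
  dx <- diff(range(track$x_nm))
  dy <- diff(range(track$y_nm))
  if (dx < box_size && dy < box_size) "immobile" else "mobile"
}

#' Time-averaged mean squared displacement of one track
#'
#' For each lag k = 1 .. n-1 frames, the mean over all `n - k`
#' overlapping pairs of the squared planar displacement, in um^2.
#'
#' @param track data.frame with `x_nm`, `y_nm`, ordered in time with
#'   consecutive frames.
#' @param frame_interval Frame interval in seconds.
#' @return data.frame `lag_s, tamsd_um2, n_pairs`.
#' @export
tamsd <- function(track, frame_interval = 0.1) {
  x <- track$x_nm / 1000
  y <- track$y_nm / 1000
  n <- length(x)
  stopifnot(n >= 2)
  lags <- seq_len(n - 1)
  vals <- vapply(lags, function(k) {
    i <- seq_len(n - k)
    mean((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
  }, numeric(1))
  data.frame(lag_s = lags * frame_interval, tamsd_um2 = vals,
             n_pairs = n - lags)
}

#' Fit the anomalous diffusion exponent
#'
#' Ordinary least squares of `log(TAMSD)` on `log(lag)` over the first
#' four lags: `log(TAMSD) = log(4 D) + alpha * log(dt)`. The slope is
#' the anomalous exponent alpha (1 for free Brownian motion, < 1
#' subdiffusive, 2 ballistic); the intercept gives a log-domain D.
#'
#' @param curve A [tamsd()] data.frame.
#' @param n_lags Number of initial lags used (default 4).
#' @return List `alpha`, `D` (um^2/s), or `NULL` when fewer than
#'   `n_lags` strictly positive TAMSD values are available (the log fit
#'   is then undefined).
#' @export
fit_anomalous <- function(curve, n_lags = 4) {
  if (nrow(curve) < n_lags) return(NULL)
  cv <- curve[seq_len(n_lags), ]
  if (any(cv$tamsd_um2 <= 0)) return(NULL)
  fit <- stats::lm(log(tamsd_um2) ~ log(lag_s), data = cv)
  co <- stats::coef(fit)
  list(alpha = unname(co[2]), D = unname(exp(co[1]) / 4))
}

#' Apply the anomalous-exponent retention filter
#'
#' Diffusive membrane particles in this regime show alpha between 0 and
#' 1.5; tracks outside that range (e.g. ballistic, alpha near 2, or
#' pathological fits) are excluded from the mobile population. Both
#' bounds are inclusive.
#'
#' @param alpha Fitted exponent.
#' @param range Inclusive retention interval.
#' @return Logical.
#' @export
filter_alpha <- function(alpha, range = c(0, 1.5)) {
  !is.na(alpha) && alpha >= range[1] && alpha <= range[2]
}

#' Fit the diffusion coefficient from the first MSD points
#'
#' Straight-line least squares of TAMSD against lag over the first four
#' lags, following `MSD = 4 D dt`; `D` is the slope over four. The fit
#' keeps a free intercept so that the constant offset contributed by
#' static localization error (4 sigma^2 added to every lag) is absorbed
#' rather than biasing D; a through-origin variant is available.
#'
#' @param curve A [tamsd()] data.frame.
#' @param n_lags Number of initial lags used (default 4).
#' @param through_origin Force a zero intercept (the textbook formula).
#' @return List `D` (um^2/s; may be negative for noise-dominated
#'   tracks), `nonpositive` flag — or `NULL` with fewer than `n_lags`
#'   lags.
#' @export
fit_diffusion_coefficient <- function(curve, n_lags = 4, through_origin = FALSE) {
  if (nrow(curve) < n_lags) return(NULL)
  cv <- curve[seq_len(n_lags), ]
  fit <- if (through_origin) stats::lm(tamsd_um2 ~ 0 + lag_s, data = cv)
         else stats::lm(tamsd_um2 ~ lag_s, data = cv)
  slope <- unname(stats::coef(fit)[["lag_s"]])
  D <- slope / 4
  list(D = D, nonpositive = D <= 0)
}

#' Per-track motion analysis
#'
#' Applies, track by track: mobility classification; for mobile tracks
#' the TAMSD, the anomalous-exponent fit with its retention filter, and
#' the diffusion-coefficient fit. Immobile tracks bypass all fitting.
#' Mobile tracks that cannot be fitted (fewer than four usable lags, or
#' a zero-valued TAMSD entry) are marked with an exclusion cause; tracks
#' with alpha outside the retention range are marked `excluded`.
#'
#' @param tracks data.frame with `track_id, frame, x_nm, y_nm`
#'   (typically output of [filter_track_lengths()]).
#' @param frame_interval Frame interval in seconds.
#' @param box_size Immobility bounding-box threshold, nm.
#' @param alpha_range Inclusive alpha retention interval.
#' @param n_lags Lags used in both fits.
#' @param through_origin Passed to [fit_diffusion_coefficient()].
#' @return data.frame `track_id, n_frames, mobility, alpha, D_um2_s,
#'   alpha_in_range, exclusion_cause`, one row per track in input
#'   order. `mobility` is `immobile`, `mobile`, or `excluded` (mobile
#'   but alpha out of range).
#' @export
analyze_tracks <- function(tracks, frame_interval = 0.1, box_size = 160,
                           alpha_range = c(0, 1.5), n_lags = 4,
                           through_origin = FALSE) {
  stopifnot(is.data.frame(tracks), "track_id" %in% names(tracks))
  ids <- unique(tracks$track_id)
  res <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    row <- data.frame(track_id = id, n_frames = nrow(tr),
                      mobility = NA_character_, alpha = NA_real_,
                      D_um2_s = NA_real_, alpha_in_range = NA,
                      exclusion_cause = NA_character_)
    if (classify_mobility(tr, box_size) == "immobile") {
      row$mobility <- "immobile"
      return(row)
    }
    row$mobility <- "mobile"
    curve <- tamsd(tr, frame_interval)
    an <- fit_anomalous(curve, n_lags)
    if (is.null(an)) {
      row$exclusion_cause <- if (nrow(curve) < n_lags) "too_few_lags"
                             else "zero_tamsd"
      return(row)
    }
    row$alpha <- an$alpha
    row$alpha_in_range <- filter_alpha(an$alpha, alpha_range)
    dd <- fit_diffusion_coefficient(curve, n_lags, through_origin)
    row$D_um2_s <- dd$D
    if (!row$alpha_in_range) {
      row$mobility <- "excluded"
      row$exclusion_cause <- "alpha_out_of_range"
    } else if (dd$nonpositive) {
      row$exclusion_cause <- "nonpositive_D" # flagged, still in the mean
    }
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Ensemble-averaged MSD diffusion fit
#'
#' Cross-check estimator for the population diffusion coefficient: the
#' per-lag TAMSD values of all tracks are pooled (weighted by their
#' pair counts) into one ensemble MSD curve, which is fitted like a
#' single track.
#'
#' @param tracks data.frame with `track_id, frame, x_nm, y_nm`.
#' @param frame_interval Frame interval, seconds.
#' @param n_lags Lags used in the fit.
#' @return List `D`, `curve` (the pooled data.frame).
#' @export
ensemble_msd_fit <- function(tracks, frame_interval = 0.1, n_lags = 4) {
  ids <- unique(tracks$track_id)
  curves <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tamsd(tr[order(tr$frame), ], frame_interval)
  })
  all <- do.call(rbind, curves)
  agg <- stats::aggregate(cbind(w = all$n_pairs,
                                wv = all$tamsd_um2 * all$n_pairs),
                          by = list(lag_s = all$lag_s), FUN = sum)
  curve <- data.frame(lag_s = agg$lag_s, tamsd_um2 = agg$wv / agg$w,
                      n_pairs = agg$w)
  curve <- curve[order(curve$lag_s), ]
  fit <- fit_diffusion_coefficient(curve, n_lags)
  list(D = if (is.null(fit)) NA_real_ else fit$D, curve = curve)
}
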