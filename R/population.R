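#' Bootstrap mean and standard deviation of a statistic
#'
#' Resamples the per-track values with replacement `n_boot` times
#' (default 1000) and returns the mean and SD of the statistic across
#' resamples. The sampling unit is always the track, never the single
#' displacement. Deterministic for a given seed.
#'
#' @param values Numeric or logical vector, one entry per track.
#' @param statistic Function of a vector, e.g. `mean`.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return List `mean`, `sd`.
#' @export
bootstrap_mean_sd <- function(values, statistic = mean, n_boot = 1000, seed = 1L) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values to bootstrap")
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      statistic(values[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    list(mean = mean(reps), sd = stats::sd(reps))
  })
}

#' Compare two condition summaries with the fixed-difference rule
#'
#' Two bootstrap means are called significantly different when they
#' differ by more than `threshold` (default 0.005) in the statistic's
#' native units (um^2/s for diffusion coefficients, dimensionless for
#' immobile fractions). The rule is symmetric, and a summary compared
#' with itself is never significant.
#'
#' @param a,b One-row `population_summary` data.frames (see
#'   [summarize_condition()]).
#' @param statistic `"immobile_fraction"` or `"mean_D"`.
#' @param threshold Significance threshold, native units.
#' @return One-row data.frame `condition_a, condition_b, statistic,
#'   difference, significant, threshold`.
#' @export
significant_difference <- function(a, b,
                                   statistic = c("immobile_fraction", "mean_D"),
                                   threshold = 0.005) {
  statistic <- match.arg(statistic)
  va <- a[[statistic]]; vb <- b[[statistic]]
  if (is.null(va) || is.null(vb) || is.na(va) || is.na(vb)) {
    stop("both summaries must carry the statistic '", statistic, "'")
  }
  diff <- va - vb
  data.frame(condition_a = a$label, condition_b = b$label,
             statistic = statistic, difference = diff,
             significant = abs(diff) > threshold, threshold = threshold)
}

#' One-way ANOVA between groups of per-cell values
#'
#' Classical fixed-effects one-way analysis of variance
#' (between/within sum-of-squares decomposition via `lm`/`anova`),
#' as used for comparing cell-dimension distributions between strains
#' or treatments.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @return List `F`, `p`, `df` (c(between, within)).
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("every group needs at least 2 values")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  tab <- stats::anova(stats::lm(y ~ g))
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (is.nan(f)) { f <- 0; p <- 1 } # all residuals zero, identical groups
  list(F = f, p = p, df = c(between = tab$Df[1], within = tab$Df[2]))
}

#' Summarize one experimental condition
#'
#' Aggregates per-track motion results into a one-row population
#' summary: the immobile fraction over all retained tracks (immobile +
#' mobile + alpha-excluded) and the mean diffusion coefficient over the
#' mobile, alpha-retained tracks, each with a bootstrap SD over 1000
#' track resamples.
#'
#' @param motion data.frame from [analyze_tracks()].
#' @param label Condition label.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return One-row data.frame (class `population_summary` prepended):
#'   `label, n_tracks, n_immobile, n_mobile_retained, immobile_fraction,
#'   boot_sd_fraction, mean_D, boot_sd_D, n_boot, seed`.
#' @export
summarize_condition <- function(motion, label = "condition",
                                n_boot = 1000, seed = 1L) {
  stopifnot(is.data.frame(motion), nrow(motion) >= 1)
  is_imm <- motion$mobility == "immobile"
  frac <- mean(is_imm)
  bf <- if (nrow(motion) >= 2) {
    bootstrap_mean_sd(is_imm, mean, n_boot, seed)
  } else list(mean = frac, sd = NA_real_)

  mob <- motion[motion$mobility == "mobile" & !is.na(motion$alpha_in_range) &
                  motion$alpha_in_range & !is.na(motion$D_um2_s), , drop = FALSE]
  if (nrow(mob) == 0) {
    warning("no mobile alpha-retained tracks; D fields empty")
    md <- NA_real_; bd <- list(mean = NA_real_, sd = NA_real_)
  } else {
    md <- mean(mob$D_um2_s)
    bd <- if (nrow(mob) >= 2) {
      bootstrap_mean_sd(mob$D_um2_s, mean, n_boot, seed + 1L)
    } else list(mean = md, sd = NA_real_)
  }
  out <- data.frame(label = label, n_tracks = nrow(motion),
                    n_immobile = sum(is_imm), n_mobile_retained = nrow(mob),
                    immobile_fraction = frac, boot_sd_fraction = bf$sd,
                    mean_D = md, boot_sd_D = bd$sd,
                    n_boot = n_boot, seed = seed)
  class(out) <- c("population_summary", class(out))
  out
}
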