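# Table schemas used across the pipeline. CSV is deliberate: the data
# volumes are small and the files stay diffable and language-neutral.
.schemas <- list(
  localizations = c("frame", "x_nm", "y_nm", "amplitude", "sigma_nm",
                    "offset", "residual_rms"),
  tracks = c("track_id", "frame", "x_nm", "y_nm"),
  motion = c("track_id", "n_frames", "mobility", "alpha", "D_um2_s",
             "alpha_in_range", "exclusion_cause"),
  summary = c("label", "n_tracks", "n_immobile", "n_mobile_retained",
              "immobile_fraction", "boot_sd_fraction", "mean_D",
              "boot_sd_D", "n_boot", "seed")
)

check_schema <- function(df, what) {
  need <- .schemas[[what]]
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(what, " table is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Numeric columns are serialized with %.17g so that write -> read
# round-trips doubles exactly.
write_table_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write / read a multi-page 16-bit grayscale TIFF movie
#'
#' Frames are integer count matrices in `[0, 65535]`; they are stored as
#' 16-bit grayscale pages and recovered exactly.
#'
#' @param stack List of integer matrices.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path) {
  if (is.matrix(stack)) stack <- list(stack)
  pages <- lapply(stack, function(m) {
    stopifnot(is.matrix(m), all(m >= 0), all(m <= 65535))
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_movie
#' @return `read_movie`: list of integer count matrices.
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    storage.mode(m) <- "integer"
    m
  })
}

#' CSV round-trips for pipeline tables
#'
#' Writers validate the schema and serialize doubles at full precision;
#' readers validate that all required columns are present (missing
#' columns give a named schema error).
#'
#' @param df The table.
#' @param path File path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_localizations <- function(df, path) {
  write_table_precise(check_schema(df, "localizations"), path)
}

#' @rdname table_io
#' @export
read_localizations <- function(path) {
  check_schema(utils::read.csv(path, stringsAsFactors = FALSE), "localizations")
}

#' @rdname table_io
#' @export
write_tracks <- function(df, path) {
  df <- check_schema(df, "tracks")
  write_table_precise(df[order(df$track_id, df$frame), , drop = FALSE], path)
}

#' @rdname table_io
#' @export
read_tracks <- function(path) {
  check_schema(utils::read.csv(path, stringsAsFactors = FALSE), "tracks")
}

#' @rdname table_io
#' @export
write_motion_results <- function(df, path) {
  write_table_precise(check_schema(df, "motion"), path)
}

#' @rdname table_io
#' @export
write_summary <- function(df, path) {
  write_table_precise(check_schema(as.data.frame(df), "summary"), path)
}

#' @rdname table_io
#' @export
read_summary <- function(path) {
  check_schema(utils::read.csv(path, stringsAsFactors = FALSE), "summary")
}
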