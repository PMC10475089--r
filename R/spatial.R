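#' Render a binary cell mask from a geometry
#'
#' Projects the spherocylinder to the image plane (a stadium shape:
#' points within one radius of the long-axis segment) and marks every
#' pixel whose center falls inside it. This is the synthetic counterpart
#' of a DIC-derived segmentation mask.
#'
#' @param cell A [build_cell()] geometry.
#' @param pixel_size Pixel size in nm.
#' @param dim Optional `c(rows, cols)`; computed from the geometry plus
#'   `margin` pixels when `NULL`.
#' @param margin Margin in pixels around the cell when `dim` is `NULL`.
#' @return Logical matrix (`TRUE` inside the cell).
#' @export
render_cell_mask <- function(cell, pixel_size = 160, dim = NULL, margin = 4) {
  px_um <- pixel_size / 1000
  ends <- local_to_image(matrix(c(-axis_half_length(cell), 0,
                                  axis_half_length(cell), 0),
                                2, 2, byrow = TRUE), cell)
  if (is.null(dim)) {
    r <- cell$radius
    xr <- range(ends[, 1]) + c(-r, r)
    yr <- range(ends[, 2]) + c(-r, r)
    dim <- c(ceiling(diff(yr) / px_um) + 2 * margin,
             ceiling(diff(xr) / px_um) + 2 * margin)
    # shift the cell so it sits inside the frame
    offset <- c(margin * px_um - xr[1], margin * px_um - yr[1])
  } else {
    offset <- c(0, 0)
  }
  nr <- dim[1]; nc <- dim[2]
  xs <- (seq_len(nc) - 0.5) * px_um - offset[1]
  ys <- (seq_len(nr) - 0.5) * px_um - offset[2]
  a <- ends[1, 1:2]; b <- ends[2, 1:2]
  ab <- b - a
  len2 <- sum(ab^2)
  px_grid <- matrix(xs, nr, nc, byrow = TRUE)
  py_grid <- matrix(ys, nr, nc)
  tt <- if (len2 > 0) ((px_grid - a[1]) * ab[1] + (py_grid - a[2]) * ab[2]) / len2
        else matrix(0, nr, nc)
  tt <- pmin(pmax(tt, 0), 1)
  d2 <- (px_grid - (a[1] + tt * ab[1]))^2 + (py_grid - (a[2] + tt * ab[2]))^2
  mask <- d2 <= cell$radius^2
  attr(mask, "offset_um") <- offset
  mask
}

#' Extract the cell axis and dimensions from a binary mask
#'
#' Computes a smoothed centerline (the ridge of the mask), extends it to
#' the outline at both ends, and derives cell length (arc length of the
#' extended centerline) and width (twice the near-maximal
#' distance-transform value along the central 50% of the centerline).
#' The mask must be a single connected region of at least 20 pixels.
#'
#' The midline is found by projecting mask-pixel centers on the
#' principal axis, taking the transverse mid-extent in axial bins of one
#' pixel, and smoothing; this coincides with the distance-transform
#' ridge for convex rod shapes.
#'
#' @param mask Logical or 0/1 matrix.
#' @param pixel_size Pixel size in nm.
#' @param cell_id Identifier stored in the record.
#' @return A `cell_record`: list with `cell_id`, `centerline` (matrix of
#'   nm coordinates, tips included), `length_um`, `width_um`,
#'   `lw_ratio`, `pixel_size`, `mask`.
#' @export
extract_cell_axis <- function(mask, pixel_size = 160, cell_id = 1L) {
  m <- mask != 0
  npix <- sum(m)
  if (npix < 20) stop("mask too small (", npix, " pixels; need >= 20)")
  lab <- EBImage::bwlabel(m * 1)
  if (max(lab) != 1) stop("mask must be a single connected region (found ",
                          max(lab), ")")
  px <- pixel_size
  idx <- which(m, arr.ind = TRUE)
  x <- (idx[, 2] - 0.5) * px
  y <- (idx[, 1] - 0.5) * px
  cx <- mean(x); cy <- mean(y)
  ev <- eigen(stats::cov(cbind(x, y)))$vectors[, 1]
  tcoord <- (x - cx) * ev[1] + (y - cy) * ev[2]
  ucoord <- -(x - cx) * ev[2] + (y - cy) * ev[1]

  bins <- floor((tcoord - min(tcoord)) / px)
  mids <- tapply(ucoord, bins, function(u) (min(u) + max(u)) / 2)
  tmid <- tapply(tcoord, bins, function(t) (min(t) + max(t)) / 2)
  ord <- order(tmid)
  tmid <- as.numeric(tmid[ord]); umid <- as.numeric(mids[ord])
  if (length(tmid) >= 8) {
    umid <- stats::predict(stats::smooth.spline(tmid, umid,
                                                df = min(5, length(tmid) - 2)),
                           tmid)$y
  }
  cl <- cbind(x = cx + tmid * ev[1] - umid * ev[2],
              y = cy + tmid * ev[2] + umid * ev[1])

  inside <- function(p) {
    i <- floor(p[2] / px) + 1; j <- floor(p[1] / px) + 1
    i >= 1 && j >= 1 && i <= nrow(m) && j <= ncol(m) && m[i, j]
  }
  extend <- function(pt, dir) {
    dir <- dir / sqrt(sum(dir^2))
    step <- 0.2 * px
    cur <- pt
    repeat {
      nxt <- cur + step * dir
      if (!inside(nxt)) return(cur)
      cur <- nxt
    }
  }
  n <- nrow(cl)
  tip1 <- extend(cl[1, ], cl[1, ] - cl[min(2, n), ])
  tip2 <- extend(cl[n, ], cl[n, ] - cl[max(1, n - 1), ])
  cl <- rbind(tip1, cl, tip2)

  seglen <- sqrt(rowSums(diff(cl)^2))
  length_nm <- sum(seglen)

  dm <- EBImage::distmap(m * 1)
  arc <- c(0, cumsum(seglen))
  central <- arc >= 0.25 * length_nm & arc <= 0.75 * length_nm
  cpts <- cl[central, , drop = FALSE]
  ri <- pmin(pmax(floor(cpts[, 2] / px) + 1, 1), nrow(m))
  ci <- pmin(pmax(floor(cpts[, 1] / px) + 1, 1), ncol(m))
  # near-maximal medial radius: on a rod the transform is flat along the
  # axis so this matches the median, but it stays correct for isotropic
  # shapes where the transform tapers away from the single central peak
  width_nm <- 2 * stats::quantile(dm[cbind(ri, ci)], 0.95, names = FALSE) * px

  structure(list(cell_id = cell_id, centerline = cl,
                 length_um = length_nm / 1000, width_um = width_nm / 1000,
                 lw_ratio = length_nm / width_nm,
                 pixel_size = pixel_size, mask = m),
            class = "cell_record")
}

#' Build a cell record directly from an idealized geometry
#'
#' Straight tip-to-tip centerline in image coordinates; used when
#' analysing simulated data where the true geometry is known and no
#' mask segmentation is involved.
#'
#' @param cell A [build_cell()] geometry.
#' @param cell_id Identifier.
#' @return A `cell_record` (no mask).
#' @export
cell_record_from_geometry <- function(cell, cell_id = 1L) {
  h <- cell$total_length / 2
  tips <- local_to_image(matrix(c(-h, 0, h, 0), 2, 2, byrow = TRUE), cell)
  structure(list(cell_id = cell_id,
                 centerline = cbind(x = tips[, 1], y = tips[, 2]) * 1000,
                 length_um = cell$total_length, width_um = cell$width,
                 lw_ratio = cell$total_length / cell$width,
                 pixel_size = NA_real_, mask = NULL),
            class = "cell_record")
}

#' Assign localizations to pole or nonpolar regions
#'
#' Each point is projected onto the cell's extended centerline; it is
#' polar when the arc-length distance from its projection to the nearer
#' cell tip is at most `pole_depth` (default 480 nm, three pixels).
#'
#' @param points data.frame with `x_nm`, `y_nm`.
#' @param cell A `cell_record`.
#' @param pole_depth Pole depth in nm.
#' @return The input with columns `region` (`"pole"`/`"nonpolar"`),
#'   `arc_nm` (arc-length position along the centerline) and `cell_id`
#'   appended.
#' @export
assign_region <- function(points, cell, pole_depth = 480) {
  stopifnot(inherits(cell, "cell_record"), pole_depth > 0,
            all(c("x_nm", "y_nm") %in% names(points)))
  cl <- cell$centerline
  nseg <- nrow(cl) - 1
  seglen <- sqrt(rowSums((cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  np <- nrow(points)
  best_d2 <- rep(Inf, np)
  best_arc <- rep(0, np)
  for (s in seq_len(nseg)) {
    a <- cl[s, ]; b <- cl[s + 1, ]
    ab <- b - a
    l2 <- sum(ab^2)
    if (l2 == 0) next
    tt <- ((points$x_nm - a[1]) * ab[1] + (points$y_nm - a[2]) * ab[2]) / l2
    tt <- pmin(pmax(tt, 0), 1)
    d2 <- (points$x_nm - (a[1] + tt * ab[1]))^2 +
          (points$y_nm - (a[2] + tt * ab[2]))^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum[s] + tt[upd] * seglen[s]
  }
  tip_dist <- pmin(best_arc, total - best_arc)
  out <- points
  out$region <- ifelse(tip_dist <= pole_depth, "pole", "nonpolar")
  out$arc_nm <- best_arc
  out$cell_id <- cell$cell_id
  out
}

#' Fraction of particles at the cell poles
#'
#' One item is one particle: by default a track contributes its first
#' localization's region (tracks rarely cross the pole boundary within
#' ~1 s); with `by = "localization"` every localization counts, and a
#' majority vote per track is available as `by = "majority"`.
#'
#' @param assigned data.frame with a `region` column (output of
#'   [assign_region()]); needs `track_id` and `frame` for the per-track
#'   modes.
#' @param by `"track"`, `"majority"`, or `"localization"`.
#' @return List `fraction`, `n_pole`, `n_nonpolar`.
#' @export
polar_fraction <- function(assigned, by = c("track", "majority", "localization")) {
  by <- match.arg(by)
  stopifnot("region" %in% names(assigned))
  regions <- switch(by,
    localization = assigned$region,
    track = {
      stopifnot(all(c("track_id", "frame") %in% names(assigned)))
      a <- assigned[order(assigned$track_id, assigned$frame), ]
      a$region[!duplicated(a$track_id)]
    },
    majority = {
      stopifnot("track_id" %in% names(assigned))
      vapply(split(assigned$region, assigned$track_id), function(r) {
        names(sort(table(r), decreasing = TRUE))[1]
      }, character(1))
    })
  n_pole <- sum(regions == "pole")
  n_non <- sum(regions == "nonpolar")
  if (n_pole + n_non == 0) stop("no assigned items; polar fraction undefined")
  list(fraction = n_pole / (n_pole + n_non),
       n_pole = n_pole, n_nonpolar = n_non)
}

#' Background-subtracted mean fluorescence intensity of one cell
#'
#' Mean pixel value inside the cell mask minus the median pixel value
#' outside all cell masks (the image background).
#'
#' @param mask Logical matrix for the cell of interest.
#' @param frame Numeric matrix, same dimensions.
#' @param all_masks Logical matrix marking every cell in the field
#'   (defaults to `mask`).
#' @return Mean background-subtracted counts.
#' @export
mean_cell_intensity <- function(mask, frame, all_masks = mask) {
  stopifnot(all(dim(mask) == dim(frame)), all(dim(all_masks) == dim(frame)))
  m <- mask != 0
  if (!any(m)) stop("empty cell mask")
  bg <- stats::median(frame[!(all_masks != 0)])
  if (is.na(bg)) bg <- 0
  mean(frame[m]) - bg
}

#' Morphometry of labelled cells
#'
#' Runs [extract_cell_axis()] on every label of a label image and
#' optionally measures per-cell mean fluorescence.
#'
#' @param labels Integer matrix (0 = background, k = cell k).
#' @param pixel_size Pixel size in nm.
#' @param fluorescence Optional intensity frame of the same dimensions.
#' @return data.frame `cell_id, length_um, width_um, lw_ratio,
#'   mean_intensity`.
#' @export
measure_cells <- function(labels, pixel_size = 160, fluorescence = NULL) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  all_m <- labels != 0
  rows <- lapply(ids, function(k) {
    rec <- extract_cell_axis(labels == k, pixel_size, cell_id = k)
    mi <- if (is.null(fluorescence)) NA_real_ else
      mean_cell_intensity(labels == k, fluorescence, all_m)
    data.frame(cell_id = k, length_um = rec$length_um,
               width_um = rec$width_um, lw_ratio = rec$lw_ratio,
               mean_intensity = mi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
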