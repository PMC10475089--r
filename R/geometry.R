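#' Spherocylindrical cell geometry
#'
#' Build the idealized geometry of a rod-shaped bacterium: a cylinder of
#' length `total_length - width` capped by two hemispheres of radius
#' `width / 2`. All downstream geometry (surface sampling, surface
#' diffusion, pole-zone areas) is defined on this shape. The cell lies
#' flat on the coverslip plane, so in the local frame the long axis runs
#' along x at height z = radius, and the lowest surface point touches
#' z = 0.
#'
#' @param total_length Tip-to-tip cell length in micrometres.
#' @param width Cell width (diameter, twice the radius) in micrometres.
#' @param center Image-plane position of the cell centroid, `c(x, y)` in
#'   micrometres.
#' @param orientation Angle of the long axis in the image plane, radians.
#' @return An object of class `cell_geometry` with fields `total_length`,
#'   `width`, `radius`, `cyl_length`, `center`, `orientation`.
#' @examples
#' cell <- build_cell(5, 1)
#' surface_area(cell) # 5 * pi
#' @export
build_cell <- function(total_length, width, center = c(0, 0), orientation = 0) {
  stopifnot(is.numeric(total_length), is.numeric(width),
            length(center) == 2, is.numeric(orientation))
  if (!(width > 0)) stop("cell width must be positive")
  if (total_length < width) {
    stop("total_length must be >= width: no spherocylinder exists for ",
         total_length, " x ", width)
  }
  structure(list(
    total_length = total_length,
    width        = width,
    radius       = width / 2,
    cyl_length   = total_length - width,
    center       = as.numeric(center),
    orientation  = orientation
  ), class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "spherocylinder: L = %.3g um, W = %.3g um (cylinder %.3g um, r = %.3g um)\n",
    x$total_length, x$width, x$cyl_length, x$radius))
  cat(sprintf("  center (%.3g, %.3g) um, orientation %.3g rad, area %.4g um^2\n",
              x$center[1], x$center[2], x$orientation, surface_area(x)))
  invisible(x)
}

#' Surface area of a spherocylinder
#'
#' `2*pi*r*Lcyl + 4*pi*r^2`: lateral cylinder area plus the two
#' hemispherical caps.
#'
#' @param cell A [build_cell()] geometry.
#' @return Area in square micrometres.
#' @export
surface_area <- function(cell) {
  r <- cell$radius
  2 * pi * r * cell$cyl_length + 4 * pi * r^2
}

#' Fraction of the cell surface inside the pole regions
#'
#' A pole is the surface within `pole_depth` of a cell end, measured
#' along the long axis. On the hemispherical cap the zone of axial depth
#' d has area `2*pi*r*d` (a spherical zone); for `d > r` the zone is the
#' full cap `2*pi*r^2` plus a cylinder collar `2*pi*r*(d - r)`. The
#' fraction is twice the per-pole zone over the total surface area. For a
#' typical 5 um x 1 um rod and the default 480 nm depth this evaluates
#' to 0.192.
#'
#' @param cell A [build_cell()] geometry.
#' @param pole_depth Pole depth in nanometres (default 480, i.e. three
#'   160 nm pixels).
#' @return Fraction in `[0, 1]`.
#' @export
pole_surface_fraction <- function(cell, pole_depth = 480) {
  stopifnot(pole_depth > 0)
  d <- pole_depth / 1000 # nm -> um
  r <- cell$radius
  if (d >= cell$total_length / 2) {
    warning("pole_depth reaches mid-cell; the two pole zones cover the cell")
    return(1)
  }
  zone <- if (d <= r) 2 * pi * r * d else 2 * pi * r^2 + 2 * pi * r * (d - r)
  2 * zone / surface_area(cell)
}

# Endpoints of the axis segment in the local frame (z = r, y = 0).
axis_half_length <- function(cell) cell$cyl_length / 2

#' Sample points uniformly on the cell surface
#'
#' Area-weighted sampling: a point lands on the cylindrical wall with
#' probability proportional to its area, otherwise uniformly on the
#' sphere formed by the two caps. Used both by the simulator (initial
#' particle placement) and as a Monte-Carlo oracle for the analytic
#' pole-zone formula.
#'
#' @param cell A [build_cell()] geometry.
#' @param n Number of points.
#' @param frame `"local"` (axis along x, coverslip at z = 0) or
#'   `"image"` (cell pose applied to x, y).
#' @return Matrix `n x 3` with columns `x`, `y`, `z` in micrometres.
#' @export
sample_surface_uniform <- function(cell, n, frame = c("local", "image")) {
  frame <- match.arg(frame)
  r <- cell$radius
  h <- axis_half_length(cell)
  a_cyl <- 2 * pi * r * cell$cyl_length
  on_cyl <- stats::runif(n) < a_cyl / surface_area(cell)
  ncyl <- sum(on_cyl)

  out <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  if (ncyl > 0) {
    phi <- stats::runif(ncyl, 0, 2 * pi)
    out[on_cyl, ] <- cbind(stats::runif(ncyl, -h, h),
                           r * sin(phi),
                           r * (1 + cos(phi)))
  }
  ncap <- n - ncyl
  if (ncap > 0) {
    u <- matrix(stats::rnorm(3 * ncap), ncap, 3)
    u <- u / sqrt(rowSums(u^2))
    # sign of the axial component selects the cap
    out[!on_cyl, ] <- cbind(sign(u[, 1]) * h + r * u[, 1],
                            r * u[, 2],
                            r + r * u[, 3])
  }
  if (frame == "image") out <- local_to_image(out, cell)
  out
}

# Nearest point on the axis segment for each row of p (local frame).
nearest_axis_point <- function(p, cell) {
  h <- axis_half_length(cell)
  cbind(pmin(pmax(p[, 1], -h), h), 0, cell$radius)
}

#' Project points back onto the spherocylinder surface
#'
#' Orthogonal reprojection: each point is moved along the ray from its
#' nearest axis-segment point so that it sits exactly at distance r from
#' the axis. Used after every tangent-plane diffusion step.
#'
#' @param p Matrix `n x 3` of local-frame positions (micrometres).
#' @param cell A [build_cell()] geometry.
#' @return Matrix `n x 3` on the surface.
#' @keywords internal
reproject_to_surface <- function(p, cell) {
  a <- nearest_axis_point(p, cell)
  v <- p - a
  nv <- sqrt(rowSums(v^2))
  # a point exactly on the axis has no preferred normal; push it up
  deg <- nv < 1e-12
  if (any(deg)) {
    v[deg, ] <- matrix(c(0, 0, 1), sum(deg), 3, byrow = TRUE)
    nv[deg] <- 1
  }
  a + v * (cell$radius / nv)
}

# Signed distance of points from the surface (0 on the surface).
surface_distance <- function(p, cell) {
  a <- nearest_axis_point(p, cell)
  sqrt(rowSums((p - a)^2)) - cell$radius
}

#' Map local cell coordinates to image-plane coordinates
#'
#' Applies the cell's pose: rotation by `orientation` and translation by
#' `center`. The z coordinate (height above the coverslip) is unchanged.
#'
#' @param p Matrix `n x 3` (or `n x 2`) in the local frame, micrometres.
#' @param cell A [build_cell()] geometry.
#' @return Matrix with the same number of columns.
#' @keywords internal
local_to_image <- function(p, cell) {
  co <- cos(cell$orientation); si <- sin(cell$orientation)
  x <- p[, 1] * co - p[, 2] * si + cell$center[1]
  y <- p[, 1] * si + p[, 2] * co + cell$center[2]
  if (ncol(p) >= 3) cbind(x = x, y = y, z = p[, 3]) else cbind(x = x, y = y)
}
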