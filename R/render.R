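#' Render a localization list into a camera movie
#'
#' Each visible emitter is drawn as a symmetric 2D Gaussian integrated
#' over the pixel area (error-function model, appropriate when the PSF
#' width is comparable to the 160 nm pixel), scaled so its total
#' expected signal is `photons` counts. Poisson shot noise is applied to
#' signal plus uniform background and the result clipped to the 16-bit
#' camera range `[0, 65535]`.
#'
#' Pixel convention: frames are matrices indexed `[row, col]`; the pixel
#' in 0-based row i, column j covers physical x in
#' `[j, j+1] * pixel_size` and y in `[i, i+1] * pixel_size`, so its
#' center is `((j + 0.5) * pixel_size, (i + 0.5) * pixel_size)`.
#'
#' @param localizations data.frame with `frame`, `x_nm`, `y_nm` (emitter
#'   positions per frame; frames are 1-based indices into the stack).
#' @param n_frames Number of frames in the stack.
#' @param dim Frame dimensions `c(rows, cols)` in pixels.
#' @param pixel_size Pixel size in nm (default 160).
#' @param psf_sigma PSF standard deviation in nm.
#' @param photons Expected total signal per emitter per frame, counts.
#' @param background Expected background per pixel, counts.
#' @param seed Integer seed for the Poisson noise.
#' @return List of `n_frames` integer matrices (counts).
#' @export
render_movie <- function(localizations, n_frames, dim = c(64, 64),
                         pixel_size = 160, psf_sigma = 130,
                         photons = 3000, background = 10, seed = 1L) {
  if (psf_sigma <= 0) stop("psf_sigma must be positive")
  stopifnot(n_frames >= 1, length(dim) == 2, pixel_size > 0,
            photons >= 0, background >= 0)
  nr <- as.integer(dim[1]); nc <- as.integer(dim[2])
  with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      img <- matrix(background, nr, nc)
      sel <- which(localizations$frame == f)
      for (i in sel) {
        img <- img + emitter_image(localizations$x_nm[i], localizations$y_nm[i],
                                   nr, nc, pixel_size, psf_sigma, photons)
      }
      counts <- stats::rpois(nr * nc, as.vector(img))
      matrix(pmin(counts, 65535L), nr, nc)
    })
  })
}

# Expected-count image of one emitter: integrated Gaussian per pixel.
emitter_image <- function(x_nm, y_nm, nr, nc, pixel_size, psf_sigma, photons) {
  ex <- diff(stats::pnorm(((0:nc) * pixel_size - x_nm) / psf_sigma))
  ey <- diff(stats::pnorm(((0:nr) * pixel_size - y_nm) / psf_sigma))
  photons * (ey %o% ex)
}
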