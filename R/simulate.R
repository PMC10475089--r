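#' Simulation configuration
#'
#' Parameters of the ground-truthed sptPALM simulator. Defaults emulate
#' the imaging regime the analysis is designed for: 10 Hz acquisition,
#' membrane diffusion coefficients of order 2e-2 um^2/s, photobleaching
#' lifetimes that put most tracks in the 4-12-frame retention window,
#' ~20 nm localization precision, and HILO-style illumination that only
#' reaches a thin slab of the cell surface next to the coverslip.
#'
#' @param n_particles Total number of activatable particles.
#' @param frac_immobile Probability that a particle is immobile.
#' @param D_mobile Diffusion coefficient of mobile particles on the cell
#'   surface, um^2/s.
#' @param frame_interval Frame interval in seconds (default 0.1, 10 Hz).
#' @param n_frames Number of movie frames.
#' @param localization_sigma Isotropic Gaussian localization noise SD, nm.
#' @param activation_rate Expected number of newly photoactivated
#'   particles per frame (Poisson).
#' @param mean_on_frames Mean fluorescent on-time before photobleaching,
#'   frames (geometric lifetime).
#' @param hilo_depth Depth of the illuminated slab above the coverslip,
#'   nm. Particles above it are invisible in that frame.
#' @param seed Integer seed; the simulator is fully reproducible.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_particles = 500,
                              frac_immobile = 0.131,
                              D_mobile = 0.0272,
                              frame_interval = 0.1,
                              n_frames = 600,
                              localization_sigma = 20,
                              activation_rate = 1,
                              mean_on_frames = 8,
                              hilo_depth = 300,
                              seed = 1L) {
  cfg <- list(n_particles = as.integer(n_particles),
              frac_immobile = frac_immobile,
              D_mobile = D_mobile,
              frame_interval = frame_interval,
              n_frames = as.integer(n_frames),
              localization_sigma = localization_sigma,
              activation_rate = activation_rate,
              mean_on_frames = mean_on_frames,
              hilo_depth = hilo_depth,
              seed = as.integer(seed))
  stopifnot(cfg$n_particles >= 1, cfg$n_frames >= 1,
            cfg$frac_immobile >= 0, cfg$frac_immobile <= 1,
            cfg$D_mobile >= 0, cfg$frame_interval > 0,
            cfg$localization_sigma >= 0, cfg$activation_rate > 0,
            cfg$mean_on_frames > 0, cfg$hilo_depth > 0)
  class(cfg) <- "simulation_config"
  cfg
}

# One Euler step of surface Brownian motion for all active particles:
# draw an isotropic N(0, 2 D dt) step in the local tangent plane, then
# reproject orthogonally onto the spherocylinder. Valid for D*dt << r^2.
surface_step <- function(p, cell, D, dt) {
  n <- nrow(p)
  if (n == 0) return(p)
  a <- nearest_axis_point(p, cell)
  nrm <- (p - a) / cell$radius
  # tangent basis: t1 = e_x orthogonalized against the normal (falls back
  # to e_y at the cap apices where the normal is axis-aligned), t2 = n x t1
  t1 <- cbind(1 - nrm[, 1]^2, -nrm[, 1] * nrm[, 2], -nrm[, 1] * nrm[, 3])
  l1 <- sqrt(rowSums(t1^2))
  deg <- l1 < 1e-8
  if (any(deg)) {
    t1[deg, ] <- cbind(-nrm[deg, 2] * nrm[deg, 1],
                       1 - nrm[deg, 2]^2,
                       -nrm[deg, 2] * nrm[deg, 3])
    l1[deg] <- sqrt(rowSums(t1[deg, , drop = FALSE]^2))
  }
  t1 <- t1 / l1
  t2 <- cbind(nrm[, 2] * t1[, 3] - nrm[, 3] * t1[, 2],
              nrm[, 3] * t1[, 1] - nrm[, 1] * t1[, 3],
              nrm[, 1] * t1[, 2] - nrm[, 2] * t1[, 1])
  s <- sqrt(2 * D * dt)
  step <- t1 * stats::rnorm(n, 0, s) + t2 * stats::rnorm(n, 0, s)
  reproject_to_surface(p + step, cell)
}

#' Simulate ground-truthed particle tracks on a cell surface
#'
#' Particles are placed uniformly on the spherocylinder surface and
#' assigned an immobile or mobile state once (states do not switch
#' within the short tracks considered here). Photoactivation consumes
#' the particle pool at a Poisson rate per frame; each activated
#' particle stays on for a geometric number of frames (mean
#' `mean_on_frames`) and then bleaches. Mobile particles perform
#' tangent-plane Brownian steps with per-axis variance `2 * D * dt`,
#' reprojected to the surface. The observed table contains one noisy
#' planar localization per frame in which the particle is on and inside
#' the illuminated slab (`z <= hilo_depth`).
#'
#' @param cell A [build_cell()] geometry.
#' @param cfg A [simulation_config()].
#' @return A list with
#'   \describe{
#'     \item{truth}{data.frame `particle_id, frame, x_um, y_um, z_um,
#'       state, true_D` — noise-free image-frame positions for every
#'       on-frame (visible or not).}
#'     \item{localizations}{data.frame `frame, x_nm, y_nm, particle_id`
#'       — noisy planar positions of visible on-frames, sorted by frame.}
#'     \item{particles}{data.frame `particle_id, state, true_D,
#'       start_frame, on_frames`.}
#'   }
#' @export
simulate_tracks <- function(cell, cfg) {
  stopifnot(inherits(cell, "cell_geometry"), inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_particles
    dt <- cfg$frame_interval

    state <- ifelse(stats::runif(n) < cfg$frac_immobile, "immobile", "mobile")
    true_d <- ifelse(state == "mobile", cfg$D_mobile, 0)

    # activation schedule: Poisson(activation_rate) new particles per
    # frame until the pool is consumed
    start_frame <- rep(NA_integer_, n)
    consumed <- 0L
    for (f in seq_len(cfg$n_frames)) {
      k <- stats::rpois(1, cfg$activation_rate)
      if (k > 0 && consumed < n) {
        take <- min(k, n - consumed)
        start_frame[consumed + seq_len(take)] <- f
        consumed <- consumed + take
      }
      if (consumed >= n) break
    }
    active <- which(!is.na(start_frame))

    on_frames <- stats::rgeom(n, prob = 1 / cfg$mean_on_frames) + 1L
    end_frame <- pmin(start_frame + on_frames - 1L, cfg$n_frames)
    dur <- end_frame - start_frame + 1L

    p0 <- sample_surface_uniform(cell, n, frame = "local")

    # step all still-on mobile particles in lockstep, one frame at a time
    max_dur <- if (length(active)) max(dur[active]) else 0L
    pos <- vector("list", max_dur)
    cur <- p0
    if (max_dur > 0) pos[[1]] <- cur
    t_idx <- 1L
    while (t_idx < max_dur) {
      mob <- active[dur[active] > t_idx & state[active] == "mobile"]
      if (length(mob)) {
        cur[mob, ] <- surface_step(cur[mob, , drop = FALSE], cell,
                                   cfg$D_mobile, dt)
      }
      t_idx <- t_idx + 1L
      pos[[t_idx]] <- cur
    }

    if (length(active)) {
      dur_a <- dur[active]
      pid <- rep(active, dur_a)
      step_idx <- sequence(dur_a)
      frame <- rep(start_frame[active], dur_a) + step_idx - 1L
      xyz <- matrix(0, length(pid), 3)
      for (s in seq_len(max_dur)) {
        sel <- which(step_idx == s)
        if (length(sel)) xyz[sel, ] <- pos[[s]][pid[sel], , drop = FALSE]
      }
      img <- local_to_image(xyz, cell)
      truth <- data.frame(particle_id = pid, frame = frame,
                          x_um = img[, 1], y_um = img[, 2], z_um = img[, 3],
                          state = state[pid], true_D = true_d[pid])
      truth <- truth[order(truth$particle_id, truth$frame), , drop = FALSE]
      rownames(truth) <- NULL
    } else {
      truth <- data.frame(particle_id = integer(), frame = integer(),
                          x_um = numeric(), y_um = numeric(), z_um = numeric(),
                          state = character(), true_D = numeric())
    }

    vis <- truth[truth$z_um <= cfg$hilo_depth / 1000, , drop = FALSE]
    sig_um <- cfg$localization_sigma / 1000
    locs <- data.frame(
      frame = vis$frame,
      x_nm = (vis$x_um + stats::rnorm(nrow(vis), 0, sig_um)) * 1000,
      y_nm = (vis$y_um + stats::rnorm(nrow(vis), 0, sig_um)) * 1000,
      particle_id = vis$particle_id)
    locs <- locs[order(locs$frame, locs$particle_id), , drop = FALSE]
    rownames(locs) <- NULL

    list(truth = truth,
         localizations = locs,
         particles = data.frame(particle_id = seq_len(n), state = state,
                                true_D = true_d, start_frame = start_frame,
                                on_frames = on_frames))
  })
}

#' Simulate planar free-diffusion tracks
#'
#' Reference generator for validating the motion statistics: tracks of
#' ideal two-dimensional Brownian motion (per-axis step variance
#' `2 * D * dt`) plus isotropic Gaussian localization noise, with no
#' surface curvature, projection or visibility effects. Track lengths
#' are geometric with mean `mean_on_frames`, optionally restricted to a
#' retention window by rejection.
#'
#' @param n_tracks Number of tracks to return.
#' @param D Diffusion coefficient, um^2/s (0 for immobile particles).
#' @param frame_interval Frame interval, seconds.
#' @param localization_sigma Localization noise SD, nm.
#' @param mean_on_frames Mean geometric track length, frames.
#' @param length_range Keep only lengths inside `c(min, max)` (rejection
#'   sampling); `NULL` keeps all.
#' @param seed Integer seed.
#' @return data.frame `track_id, frame, x_nm, y_nm` (tracks start at
#'   frame 1 for simplicity; linking is not intended to be run on this
#'   output).
#' @export
simulate_planar_tracks <- function(n_tracks, D,
                                   frame_interval = 0.1,
                                   localization_sigma = 20,
                                   mean_on_frames = 8,
                                   length_range = c(4, 12),
                                   seed = 1L) {
  stopifnot(n_tracks >= 1, D >= 0, frame_interval > 0)
  with_seed(seed, {
    lens <- integer(0)
    while (length(lens) < n_tracks) {
      l <- stats::rgeom(2L * n_tracks, prob = 1 / mean_on_frames) + 1L
      if (!is.null(length_range)) l <- l[l >= length_range[1] & l <= length_range[2]]
      lens <- c(lens, l)
    }
    lens <- lens[seq_len(n_tracks)]
    s_step <- sqrt(2 * D * frame_interval) * 1000 # nm
    s_loc <- localization_sigma
    out <- lapply(seq_len(n_tracks), function(i) {
      n <- lens[i]
      x <- cumsum(c(0, stats::rnorm(n - 1, 0, s_step)))
      y <- cumsum(c(0, stats::rnorm(n - 1, 0, s_step)))
      data.frame(track_id = i, frame = seq_len(n),
                 x_nm = x + stats::rnorm(n, 0, s_loc),
                 y_nm = y + stats::rnorm(n, 0, s_loc))
    })
    do.call(rbind, out)
  })
}
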