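#' Emitter model for movie simulation
#'
#' Describes a set of point emitters with two-state (on/off) blinking
#' kinetics and an in-focus Gaussian PSF. A fiducial marker is the special
#' case `k_on = 1, k_off = 0` (always on).
#'
#' @param positions numeric matrix with columns `x`, `y` (camera px, pixel
#'   centre of pixel (0,0) at (0.5, 0.5)).
#' @param k_on,k_off per-frame switching probabilities of the off->on and
#'   on->off transitions, both in `[0, 1]`.
#' @param photons_per_frame mean photon count emitted per on-frame.
#' @param psf_sigma_px Gaussian PSF standard deviation in px.
#' @return an `emitter_model`.
#' @export
emitter_model <- function(positions, k_on = 0.02, k_off = 0.5,
                          photons_per_frame = 1000, psf_sigma_px = 1.3) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, k_on >= 0, k_on <= 1, k_off >= 0, k_off <= 1,
            photons_per_frame > 0, psf_sigma_px > 0)
  structure(list(positions = positions, k_on = k_on, k_off = k_off,
                 photons_per_frame = photons_per_frame,
                 psf_sigma_px = psf_sigma_px),
            class = "emitter_model")
}

#' Camera noise and background model
#'
#' Background is a plane `offset + gx*x + gy*y` that may creep linearly in
#' time; shot noise is plain Poisson and read noise additive Gaussian
#' (EMCCD excess noise is deliberately not modelled).
#'
#' @param background_offset baseline background in counts.
#' @param background_gradient length-2 `(gx, gy)` in counts/px (may be signed).
#' @param background_drift_per_frame counts/frame added uniformly over time.
#' @param read_noise_sigma Gaussian read noise sd in counts.
#' @param poisson logical; apply Poisson shot noise to signal + background.
#' @return a `noise_model`.
#' @export
noise_model <- function(background_offset = 0, background_gradient = c(0, 0),
                        background_drift_per_frame = 0, read_noise_sigma = 0,
                        poisson = TRUE) {
  stopifnot(background_offset >= 0, background_drift_per_frame >= 0,
            read_noise_sigma >= 0, length(background_gradient) == 2)
  structure(list(background_offset = background_offset,
                 background_gradient = as.numeric(background_gradient),
                 background_drift_per_frame = background_drift_per_frame,
                 read_noise_sigma = read_noise_sigma,
                 poisson = isTRUE(poisson)),
            class = "noise_model")
}

# expected background image for frame t (0-based)
background_image <- function(noise, shape, t) {
  xc <- matrix(rep(seq_len(shape[2]) - 0.5, each = shape[1]), shape[1], shape[2])
  yc <- matrix(rep(seq_len(shape[1]) - 0.5, times = shape[2]), shape[1], shape[2])
  noise$background_offset + noise$background_gradient[1] * xc +
    noise$background_gradient[2] * yc + noise$background_drift_per_frame * t
}

# pixel-integrated Gaussian PSF: expected photons per pixel for one emitter
psf_pixel_image <- function(x0, y0, sigma, photons, shape) {
  fx <- pnorm(seq(0, shape[2]), mean = x0, sd = sigma)
  fy <- pnorm(seq(0, shape[1]), mean = y0, sd = sigma)
  photons * (diff(fy) %o% diff(fx))
}

#' Simulate a blinking-emitter SMLM movie with ground truth
#'
#' Each on-state emitter contributes a pixel-integrated 2D Gaussian PSF
#' (difference of Gaussian CDFs over pixel edges, not point sampling);
#' optional lateral drift shifts the true positions per frame; Poisson shot
#' noise and Gaussian read noise are applied on top of an inhomogeneous,
#' slowly varying background. Blinking is a first-order two-state Markov
#' chain per frame initialised from its stationary distribution.
#'
#' @param emitters an [emitter_model].
#' @param noise a [noise_model].
#' @param drift a [drift_trace] of length `n_frames`, or `NULL` for none.
#' @param n_frames number of frames (>= 1).
#' @param shape `(rows, cols)` of the camera field.
#' @param seed integer seed fixing all randomness.
#' @param pixel_size_nm,frame_interval_s calibration for the output movie.
#' @return list with `movie` (an [smlm_movie]) and `truth`, a list holding
#'   `states` (n_frames x n_emitters on/off matrix), `emissions` (data.frame
#'   frame, emitter, x, y, clipped — drifted true position per on-event),
#'   `drift` and the input models.
#' @export
simulate_movie <- function(emitters, noise, drift = NULL, n_frames, shape,
                           seed = 1, pixel_size_nm = 100,
                           frame_interval_s = 0.03) {
  stopifnot(n_frames >= 1, length(shape) == 2)
  set.seed(seed)
  ne <- nrow(emitters$positions)
  if (!is.null(drift) && length(drift$dx) != n_frames)
    stop("drift trace length must equal n_frames")

  p_on_stat <- if (emitters$k_on + emitters$k_off > 0)
    emitters$k_on / (emitters$k_on + emitters$k_off) else 0
  states <- matrix(FALSE, n_frames, ne)
  if (ne > 0) {
    states[1, ] <- runif(ne) < p_on_stat
    if (n_frames > 1) for (t in 2:n_frames) {
      prev <- states[t - 1, ]
      states[t, ] <- ifelse(prev, runif(ne) >= emitters$k_off,
                            runif(ne) < emitters$k_on)
    }
  }

  data <- array(0, dim = c(shape[1], shape[2], n_frames))
  em_frame <- integer(0); em_id <- integer(0)
  em_x <- numeric(0); em_y <- numeric(0); em_clip <- logical(0)
  for (t in seq_len(n_frames)) {
    img <- background_image(noise, shape, t - 1)
    dx <- if (is.null(drift)) 0 else drift$dx[t]
    dy <- if (is.null(drift)) 0 else drift$dy[t]
    on <- which(states[t, ])
    for (e in on) {
      x0 <- emitters$positions[e, 1] + dx
      y0 <- emitters$positions[e, 2] + dy
      clipped <- x0 < 0 || x0 > shape[2] || y0 < 0 || y0 > shape[1]
      img <- img + psf_pixel_image(x0, y0, emitters$psf_sigma_px,
                                   emitters$photons_per_frame, shape)
      em_frame <- c(em_frame, t - 1L); em_id <- c(em_id, e)
      em_x <- c(em_x, x0); em_y <- c(em_y, y0); em_clip <- c(em_clip, clipped)
    }
    if (noise$poisson) img <- matrix(rpois(length(img), pmax(img, 0)),
                                     shape[1], shape[2])
    if (noise$read_noise_sigma > 0)
      img <- img + matrix(rnorm(length(img), 0, noise$read_noise_sigma),
                          shape[1], shape[2])
    data[, , t] <- img
  }
  truth <- list(states = states,
                emissions = data.frame(frame = em_frame, emitter = em_id,
                                       x = em_x, y = em_y, clipped = em_clip),
                drift = drift, emitters = emitters, noise = noise)
  list(movie = smlm_movie(data, pixel_size_nm, frame_interval_s),
       truth = truth)
}

#' Simulate static blinking emitters directly at the localization level
#'
#' Shortcut for validation of post-processing stages: each emitter is
#' re-localized on every frame it is on, with independent per-axis Gaussian
#' localization noise, skipping the image-formation and fitting steps.
#'
#' @param positions matrix of true `(x, y)` in px.
#' @param n_frames number of frames.
#' @param sigma_loc_px per-axis localization noise sd in px.
#' @param p_on per-frame probability that an emitter is on (independent
#'   frames; use [simulate_movie] for Markov blinking).
#' @param intensity mean reported intensity (constant).
#' @param seed integer seed.
#' @param pixel_size_nm,frame_interval_s calibration metadata.
#' @return a `loc_table` with `track_id` set to the emitter index.
#' @export
simulate_static_locs <- function(positions, n_frames, sigma_loc_px = 0.1,
                                 p_on = 1, intensity = 1000, seed = 1,
                                 pixel_size_nm = 100, frame_interval_s = 0.03) {
  set.seed(seed)
  positions <- as.matrix(positions)
  ne <- nrow(positions)
  on <- matrix(runif(n_frames * ne) < p_on, n_frames, ne)
  idx <- which(on, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  n <- nrow(idx)
  loc_table(frame = idx[, 1] - 1L,
            x = positions[idx[, 2], 1] + rnorm(n, 0, sigma_loc_px),
            y = positions[idx[, 2], 2] + rnorm(n, 0, sigma_loc_px),
            intensity = rep(intensity, n),
            track_id = as.integer(idx[, 2] - 1L),
            pixel_size_nm = pixel_size_nm, frame_interval_s = frame_interval_s)
}

#' Simulate Brownian trajectories with optional blinking
#'
#' Per-axis increments are independent Gaussians with variance `2*D*tau` per
#' frame step (`tau` = 1 frame), giving 2D single-frame jump distances that
#' follow a Rayleigh law with `E[r^2] = 4*D*tau`. Populations with different
#' diffusion coefficients are mixed according to `fractions`.
#'
#' @param n_particles number of particles.
#' @param D_list diffusion coefficients, px^2/frame, one per population.
#' @param fractions population fractions summing to 1.
#' @param n_frames trajectory length in frames.
#' @param p_blink per-frame probability that a localization is missed.
#' @param sigma_loc_px per-axis localization noise added to observed positions.
#' @param box field side length in px for uniform starting positions.
#' @param seed integer seed.
#' @param pixel_size_nm,frame_interval_s calibration metadata.
#' @return list with `table` (a `loc_table`, `track_id` = particle) and
#'   `truth` (data.frame particle, population, D).
#' @export
simulate_tracks <- function(n_particles, D_list, fractions = NULL,
                            n_frames = 20, p_blink = 0, sigma_loc_px = 0,
                            box = 100, seed = 1,
                            pixel_size_nm = 100, frame_interval_s = 0.03) {
  if (length(D_list) == 0) stop("D_list must not be empty")
  if (any(D_list < 0)) stop("diffusion coefficients must be >= 0")
  if (is.null(fractions)) fractions <- rep(1 / length(D_list), length(D_list))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  set.seed(seed)
  pop <- sample.int(length(D_list), n_particles, replace = TRUE, prob = fractions)
  frames <- integer(0); xs <- numeric(0); ys <- numeric(0); ids <- integer(0)
  for (p in seq_len(n_particles)) {
    D <- D_list[pop[p]]
    stepsd <- sqrt(2 * D)
    x <- cumsum(c(runif(1, 0, box), rnorm(n_frames - 1, 0, stepsd)))
    y <- cumsum(c(runif(1, 0, box), rnorm(n_frames - 1, 0, stepsd)))
    keep <- runif(n_frames) >= p_blink
    if (!any(keep)) next
    f <- which(keep) - 1L
    xo <- x[keep] + rnorm(sum(keep), 0, sigma_loc_px)
    yo <- y[keep] + rnorm(sum(keep), 0, sigma_loc_px)
    frames <- c(frames, f); xs <- c(xs, xo); ys <- c(ys, yo)
    ids <- c(ids, rep(p - 1L, sum(keep)))
  }
  ord <- order(frames, ids)
  tab <- loc_table(frame = frames[ord], x = xs[ord], y = ys[ord],
                   intensity = rep(1000, length(ord)), track_id = ids[ord],
                   pixel_size_nm = pixel_size_nm,
                   frame_interval_s = frame_interval_s)
  list(table = tab,
       truth = data.frame(particle = seq_len(n_particles) - 1L,
                          population = pop, D = D_list[pop]))
}

#' Simulate paired two-colour bead/nanoruler localizations
#'
#' Docking sites shared by two colour channels: channel 1 observes the true
#' sites, channel 2 observes the sites mapped through a chromatic transform.
#' Used to validate affine channel registration.
#'
#' @param n_sites number of docking sites (>= 3 for affine estimation).
#' @param spacing_nm target spacing of the site grid in nm.
#' @param transform an [affine2d] applied to channel-2 site positions.
#' @param sigma_loc_px per-axis localization noise in px.
#' @param n_locs_per_site repeated localizations per site per channel.
#' @param field_px field side in px.
#' @param seed integer seed.
#' @param pixel_size_nm calibration.
#' @return list with `table` (channels 0 and 1; `track_id` = site index) and
#'   `truth` (data.frame site, x, y and the transform).
#' @export
simulate_nanoruler_pairs <- function(n_sites, spacing_nm = 2000,
                                     transform = affine2d(),
                                     sigma_loc_px = 0.02, n_locs_per_site = 10,
                                     field_px = 64, seed = 1,
                                     pixel_size_nm = 100) {
  stopifnot(n_sites >= 1)
  set.seed(seed)
  spacing_px <- spacing_nm / pixel_size_nm
  side <- ceiling(sqrt(n_sites))
  gx <- ((seq_len(n_sites) - 1) %% side) * spacing_px
  gy <- ((seq_len(n_sites) - 1) %/% side) * spacing_px
  off <- (field_px - max(gx, gy)) / 2
  sx <- gx + off + runif(n_sites, -spacing_px / 4, spacing_px / 4)
  sy <- gy + off + runif(n_sites, -spacing_px / 4, spacing_px / 4)
  t2 <- affine_apply_xy(transform, sx, sy)
  mk <- function(px, py, channel) {
    n <- n_sites * n_locs_per_site
    site <- rep(seq_len(n_sites) - 1L, each = n_locs_per_site)
    data.frame(frame = seq_len(n) - 1L,
               x = px[site + 1L] + rnorm(n, 0, sigma_loc_px),
               y = py[site + 1L] + rnorm(n, 0, sigma_loc_px),
               intensity = 1000, track_id = site, channel = channel)
  }
  df <- rbind(mk(sx, sy, 0L), mk(t2$x, t2$y, 1L))
  tab <- loc_table(frame = df$frame, x = df$x, y = df$y,
                   intensity = df$intensity, track_id = df$track_id,
                   channel = df$channel, pixel_size_nm = pixel_size_nm)
  list(table = tab,
       truth = list(sites = data.frame(site = seq_len(n_sites) - 1L,
                                       x = sx, y = sy),
                    transform = transform))
}

#' Smooth synthetic drift trace
#'
#' Low-frequency lateral drift built from a sum of slow sinusoids plus a
#' linear component, scaled to a requested peak amplitude.
#'
#' @param n_frames number of frames.
#' @param amplitude_px peak displacement magnitude in px.
#' @param seed integer seed.
#' @return a [drift_trace] with reference frame 0.
#' @export
simulate_drift <- function(n_frames, amplitude_px = 0.5, seed = 1) {
  set.seed(seed)
  t <- seq(0, 1, length.out = n_frames)
  comp <- function() {
    ph <- runif(2, 0, 2 * pi)
    v <- runif(1, 0.3, 1) * t + sin(2 * pi * runif(1, 0.5, 1.5) * t + ph[1]) +
      0.5 * sin(2 * pi * runif(1, 1.5, 3) * t + ph[2])
    v - v[1]
  }
  dx <- comp(); dy <- comp()
  sc <- amplitude_px / max(sqrt(dx^2 + dy^2))
  drift_trace(dx * sc, dy * sc, reference_frame = 0L)
}
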