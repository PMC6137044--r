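# Synthetic-data generators.
#
# Every generator is a pure function of its arguments plus an explicit seed:
# the same call returns bit-identical output. Each returns its GroundTruth
# alongside the data, which downstream tests use as the recovery oracle.

#' Simulation configuration
#'
#' Acquisition settings shared by the image-level generators. Defaults mirror
#' the reference TIRF setup: 80 nm pixels, 100 ms frame interval, 50 frames.
#'
#' @param seed Integer RNG seed.
#' @param pixel_size_nm Physical pixel size in nm (> 0).
#' @param frame_interval_s Frame interval in seconds (> 0).
#' @param n_frames Number of frames (>= 2).
#' @param image_shape Integer pair `(rows, cols)`.
#' @param noise_sd Additive Gaussian camera noise, standard deviation in
#'   camera counts (>= 0).
#' @param psf_sigma_px Gaussian emitter blur, standard deviation in pixels.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, pixel_size_nm = 80, frame_interval_s = 0.1,
                       n_frames = 50L, image_shape = c(64L, 64L),
                       noise_sd = 0, psf_sigma_px = 1.3) {
  stop_if_not_scalar_pos(pixel_size_nm, "pixel_size_nm")
  stop_if_not_scalar_pos(frame_interval_s, "frame_interval_s")
  stop_if_not_scalar_pos(psf_sigma_px, "psf_sigma_px")
  stop_if_not_scalar_pos(noise_sd, "noise_sd", allow_zero = TRUE)
  if (!is.numeric(n_frames) || n_frames < 2) {
    stop("`n_frames` must be >= 2", call. = FALSE)
  }
  if (length(image_shape) != 2L || any(image_shape < 1)) {
    stop("`image_shape` must be a pair of positive integers", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), pixel_size_nm = pixel_size_nm,
         frame_interval_s = frame_interval_s, n_frames = as.integer(n_frames),
         image_shape = as.integer(image_shape), noise_sd = noise_sd,
         psf_sigma_px = psf_sigma_px),
    class = "sim_config")
}

#' Two-population diffusion parameters
#'
#' Mixture model for membrane-protein mobility: a fraction `alpha_mobile` of
#' molecules diffuses with coefficient `d_mobile_um2_s`, the rest with
#' `d_immobile_um2_s`. By convention the first population is the faster one.
#'
#' @param alpha_mobile Mobile fraction in `[0, 1]`.
#' @param d_mobile_um2_s Mobile diffusion coefficient, um^2/s (>= 0).
#' @param d_immobile_um2_s Immobile diffusion coefficient, um^2/s (>= 0, and
#'   <= `d_mobile_um2_s`).
#' @param loc_error_nm Static localization error, standard deviation per axis
#'   in nm (>= 0).
#' @return An object of class `two_population_params`.
#' @export
two_population_params <- function(alpha_mobile, d_mobile_um2_s,
                                  d_immobile_um2_s, loc_error_nm = 0) {
  if (!is.numeric(alpha_mobile) || alpha_mobile < 0 || alpha_mobile > 1) {
    stop("`alpha_mobile` must lie in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_pos(d_mobile_um2_s, "d_mobile_um2_s", allow_zero = TRUE)
  stop_if_not_scalar_pos(d_immobile_um2_s, "d_immobile_um2_s", allow_zero = TRUE)
  stop_if_not_scalar_pos(loc_error_nm, "loc_error_nm", allow_zero = TRUE)
  if (d_mobile_um2_s < d_immobile_um2_s) {
    stop("`d_mobile_um2_s` must be >= `d_immobile_um2_s` ",
         "(the first population is the faster one by convention)", call. = FALSE)
  }
  structure(
    list(alpha_mobile = alpha_mobile, d_mobile_um2_s = d_mobile_um2_s,
         d_immobile_um2_s = d_immobile_um2_s, loc_error_nm = loc_error_nm),
    class = "two_population_params")
}

#' Packaged simulation presets
#'
#' Named parameter sets matching the study conditions the package emulates:
#' \describe{
#'   \item{`aptes_yeast`}{Can1-mCardinal tracking in yeast immobilized on
#'     APTES-glutaraldehyde: mobile fraction 0.57, apparent
#'     D_mobile 5.1e-4 um^2/s, D_immobile 1e-5 um^2/s, 10 s lag. The reported
#'     diffusion coefficients are apparent values (localization error already
#'     absorbed), so the preset generates with `loc_error_nm = 0`.}
#'   \item{`cona_yeast`}{Same experiment on concanavalin-A-coated glass:
#'     mobile fraction 0.59, D_mobile 5.4e-4 um^2/s.}
#'   \item{`frap_guv_ld`}{FRAP of a fluorescent lipid in the liquid-disordered
#'     phase of a surface-bound GUV: mobile fraction 0.82, recovery halftime
#'     0.196 s, 20 pre-bleach frames, 50 ms sampling for 6 s, 0.5 um bleach
#'     radius, Axelrod geometry factor 0.88.}
#' }
#'
#' @param name Preset name.
#' @return A named list of generating parameters.
#' @export
sim_preset <- function(name = c("aptes_yeast", "cona_yeast", "frap_guv_ld")) {
  name <- match.arg(name)
  switch(name,
    aptes_yeast = list(
      kind = "spt",
      params = two_population_params(0.57, 5.1e-4, 1e-5, loc_error_nm = 0),
      dt_s = 10),
    cona_yeast = list(
      kind = "spt",
      params = two_population_params(0.59, 5.4e-4, 1e-5, loc_error_nm = 0),
      dt_s = 10),
    frap_guv_ld = list(
      kind = "frap",
      pre_level = 1000, bleach_depth = 0.6, mobile_fraction = 0.82,
      t_half_s = 0.196, n_pre = 20L, n_post = 120L, dt_s = 0.05,
      roi_radius_um = 0.5, gamma = 0.88))
}

#' Simulate a brightfield-like movie of rigidly drifting cells
#'
#' Builds a smooth cell-like base scene (a few Gaussian blobs) and translates
#' it by the cumulative per-pair shift, so that the noise-free content of frame
#' `k+1` is frame `k` translated by `shifts[k, ]`. Fresh camera noise is drawn
#' per frame.
#'
#' @param config A [sim_config()].
#' @param shifts Integer matrix `(n_frames - 1) x 2` of per-pair `(dx, dy)`
#'   shifts in pixels (`dx` along columns, `dy` along rows).
#' @param boundary `"periodic"` (default; shifts wrap, keeping the FFT
#'   correlation oracle exact) or `"zero"` (shifted-in pixels are zero).
#' @return A list with `stack` ([image_stack()]) and `ground_truth` (records
#'   the shifts, boundary mode and config).
#' @export
simulate_drifting_cells <- function(config, shifts,
                                    boundary = c("periodic", "zero")) {
  stopifnot(inherits(config, "sim_config"))
  boundary <- match.arg(boundary)
  shifts <- matrix(as.numeric(shifts), ncol = 2)
  if (nrow(shifts) != config$n_frames - 1L) {
    stop("`shifts` must have n_frames - 1 = ", config$n_frames - 1L,
         " rows, got ", nrow(shifts), call. = FALSE)
  }
  if (any(shifts != round(shifts))) stop("shifts must be integers", call. = FALSE)
  h <- config$image_shape[1]; w <- config$image_shape[2]
  bound <- floor(min(h, w) / 4)
  bad <- which(abs(shifts[, 1]) >= w / 4 | abs(shifts[, 2]) >= h / 4)
  if (length(bad)) {
    stop(sprintf(
      "shift for frame pair %d (%d, %d) exceeds the bound |shift| < %d px",
      bad[1], shifts[bad[1], 1], shifts[bad[1], 2], bound), call. = FALSE)
  }
  with_seed(config$seed, {
    # base scene: 6 soft blobs on a dim background
    n_blobs <- 6L
    cy <- stats::runif(n_blobs, h * 0.2, h * 0.8)
    cx <- stats::runif(n_blobs, w * 0.2, w * 0.8)
    sg <- stats::runif(n_blobs, 2, 5)
    amp <- stats::runif(n_blobs, 200, 800)
    rows <- matrix(seq_len(h) - 1, h, w)
    cols <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
    base <- matrix(100, h, w)
    for (b in seq_len(n_blobs)) {
      base <- base + amp[b] * exp(-((rows - cy[b])^2 + (cols - cx[b])^2) / (2 * sg[b]^2))
    }
    cum <- rbind(c(0, 0), apply(shifts, 2, cumsum))
    frames <- vector("list", config$n_frames)
    for (k in seq_len(config$n_frames)) {
      f <- if (boundary == "periodic") {
        roll_matrix(base, cum[k, 1], cum[k, 2])
      } else {
        shift_matrix_zero(base, cum[k, 1], cum[k, 2])
      }
      if (config$noise_sd > 0) {
        f <- f + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
      }
      frames[[k]] <- pmax(f, 0)
    }
    list(
      stack = image_stack(frames, config$pixel_size_nm, config$frame_interval_s),
      ground_truth = list(
        kind = "drifting_cells", shifts = shifts, boundary = boundary,
        seed = config$seed, noise_sd = config$noise_sd))
  })
}

#' Simulate two-population Brownian trajectories
#'
#' Each particle is assigned to the mobile population with probability
#' `alpha_mobile`; per-axis displacements per step are zero-mean Gaussian with
#' variance `2 * D * dt`, and independent Gaussian localization error
#' (`loc_error_nm` per axis) is added to every recorded position.
#'
#' @param params A [two_population_params()].
#' @param n_particles Number of particles (>= 1).
#' @param n_steps Number of steps per particle (trajectory length
#'   `n_steps + 1`).
#' @param dt_s Time between recorded positions, seconds (> 0).
#' @param seed Integer RNG seed.
#' @param origin_box_um Pair: particles start uniformly in
#'   `[0, origin_box_um[1]] x [0, origin_box_um[2]]` (um).
#' @return A list with `trajectories` (data frame `trajectory_id`, `frame`,
#'   `x_um`, `y_um`, `intensity`) and `ground_truth` (per-particle `mobile`
#'   labels, true positions, generating parameters).
#' @export
simulate_trajectories <- function(params, n_particles, n_steps, dt_s, seed = 1L,
                                  origin_box_um = c(10, 10)) {
  stopifnot(inherits(params, "two_population_params"))
  if (n_particles < 1) stop("`n_particles` must be >= 1", call. = FALSE)
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  stop_if_not_scalar_pos(dt_s, "dt_s")
  loc_um <- params$loc_error_nm / 1000
  with_seed(seed, {
    mobile <- stats::runif(n_particles) < params$alpha_mobile
    d <- ifelse(mobile, params$d_mobile_um2_s, params$d_immobile_um2_s)
    step_sd <- sqrt(2 * d * dt_s)
    n_pos <- n_steps + 1L
    out <- vector("list", n_particles)
    true_out <- vector("list", n_particles)
    for (p in seq_len(n_particles)) {
      x0 <- stats::runif(1, 0, origin_box_um[1])
      y0 <- stats::runif(1, 0, origin_box_um[2])
      xt <- x0 + c(0, cumsum(stats::rnorm(n_steps, 0, step_sd[p])))
      yt <- y0 + c(0, cumsum(stats::rnorm(n_steps, 0, step_sd[p])))
      xo <- xt; yo <- yt
      if (loc_um > 0) {
        xo <- xo + stats::rnorm(n_pos, 0, loc_um)
        yo <- yo + stats::rnorm(n_pos, 0, loc_um)
      }
      out[[p]] <- data.frame(trajectory_id = p, frame = seq_len(n_pos) - 1L,
                             x_um = xo, y_um = yo, intensity = NA_real_)
      true_out[[p]] <- data.frame(trajectory_id = p, frame = seq_len(n_pos) - 1L,
                                  x_um = xt, y_um = yt)
    }
    list(
      trajectories = do.call(rbind, out),
      ground_truth = list(
        kind = "two_population_trajectories",
        mobile = mobile, true_positions = do.call(rbind, true_out),
        params = unclass(params), dt_s = dt_s, seed = seed))
  })
}

#' Render trajectories into a fluorescence movie
#'
#' Each localization becomes an isotropic Gaussian spot of standard deviation
#' `psf_sigma_px`, pixel-integrated (so a noise-free isolated spot sums to
#' `intensity` up to truncation at the frame edge), plus additive Gaussian
#' camera noise.
#'
#' @param trajectories Data frame with `trajectory_id`, `frame`, `x_um`,
#'   `y_um` (um, pixel-center origin).
#' @param config A [sim_config()]; `n_frames` frames are rendered.
#' @param intensity Integrated spot intensity in camera counts.
#' @param baseline Constant camera offset in counts (default 0). A positive
#'   baseline keeps additive noise symmetric after the non-negativity clamp,
#'   as on a real EMCCD.
#' @return An [image_stack()].
#' @export
render_particle_movie <- function(trajectories, config, intensity = 1000,
                                  baseline = 0) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(trajectories))
  h <- config$image_shape[1]; w <- config$image_shape[2]
  px_um <- config$pixel_size_nm / 1000
  sig_um <- config$psf_sigma_px * px_um
  xmax <- (w - 0.5) * px_um; ymax <- (h - 0.5) * px_um
  oob <- trajectories$x_um < -0.5 * px_um | trajectories$x_um > xmax |
    trajectories$y_um < -0.5 * px_um | trajectories$y_um > ymax
  if (any(oob)) {
    i <- which(oob)[1]
    stop(sprintf(
      "emitter out of image bounds: trajectory %s, frame %s at (%.3f, %.3f) um",
      trajectories$trajectory_id[i], trajectories$frame[i],
      trajectories$x_um[i], trajectories$y_um[i]), call. = FALSE)
  }
  # pixel-integrated Gaussian along each axis via the normal CDF
  edges_x <- (seq_len(w + 1L) - 1.5) * px_um   # pixel j covers [edges[j], edges[j+1])
  edges_y <- (seq_len(h + 1L) - 1.5) * px_um
  frames <- vector("list", config$n_frames)
  with_seed(config$seed, {
    for (k in seq_len(config$n_frames)) {
      f <- matrix(baseline, h, w)
      rows_k <- trajectories[trajectories$frame == (k - 1L), , drop = FALSE]
      for (i in seq_len(nrow(rows_k))) {
        px_mass <- diff(stats::pnorm(edges_x, rows_k$x_um[i], sig_um))
        py_mass <- diff(stats::pnorm(edges_y, rows_k$y_um[i], sig_um))
        f <- f + intensity * (py_mass %o% px_mass)
      }
      if (config$noise_sd > 0) {
        f <- f + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
      }
      frames[[k]] <- pmax(f, 0)
    }
  })
  image_stack(frames, config$pixel_size_nm, config$frame_interval_s)
}

#' Simulate a FRAP recovery trace
#'
#' Pre-bleach plateau at `pre_level` for `n_pre` samples, then
#' `F(t) = F0 + (Finf - F0) * (1 - exp(-log(2) * t / t_half_s))` with
#' `F0 = pre_level * (1 - bleach_depth)` and
#' `Finf = F0 + mobile_fraction * (pre_level - F0)`. Time is 0 at the first
#' post-bleach sample and negative before the bleach. Gaussian noise of
#' standard deviation `noise_sd` (same units as `pre_level`) is added to every
#' sample.
#'
#' @param pre_level Pre-bleach fluorescence level.
#' @param bleach_depth Fraction of fluorescence removed by the bleach,
#'   in `(0, 1]`.
#' @param mobile_fraction Recoverable fraction in `[0, 1]`.
#' @param t_half_s Recovery halftime, seconds (> 0).
#' @param n_pre Number of pre-bleach samples (>= 1).
#' @param n_post Number of post-bleach samples (>= 3).
#' @param dt_s Sampling interval, seconds.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer RNG seed.
#' @param roi_radius_um Bleach-spot radius carried on the trace, um.
#' @return A list with `trace` ([frap_trace()]) and `ground_truth`.
#' @export
simulate_frap_trace <- function(pre_level, bleach_depth, mobile_fraction,
                                t_half_s, n_pre = 20L, n_post = 120L,
                                dt_s = 0.05, noise_sd = 0, seed = 1L,
                                roi_radius_um = 0.5) {
  stop_if_not_scalar_pos(t_half_s, "t_half_s")
  stop_if_not_scalar_pos(dt_s, "dt_s")
  if (bleach_depth <= 0 || bleach_depth > 1) {
    stop("`bleach_depth` must lie in (0, 1]", call. = FALSE)
  }
  if (mobile_fraction < 0 || mobile_fraction > 1) {
    stop("`mobile_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (n_pre < 1) stop("`n_pre` must be >= 1", call. = FALSE)
  if (n_post < 3) stop("`n_post` must be >= 3", call. = FALSE)
  f0 <- pre_level * (1 - bleach_depth)
  finf <- f0 + mobile_fraction * (pre_level - f0)
  t_pre <- -rev(seq_len(n_pre)) * dt_s
  t_post <- (seq_len(n_post) - 1L) * dt_s
  f <- c(rep(pre_level, n_pre),
         f0 + (finf - f0) * (1 - exp(-log(2) * t_post / t_half_s)))
  noisy <- with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  list(
    trace = frap_trace(c(t_pre, t_post), noisy, n_pre = n_pre,
                       roi_radius_um = roi_radius_um),
    ground_truth = list(
      kind = "frap", pre_level = pre_level, bleach_depth = bleach_depth,
      f0 = f0, f_inf = finf, mobile_fraction = mobile_fraction,
      t_half_s = t_half_s, noise_sd = noise_sd, seed = seed))
}

#' Simulate an eisosome-marker centroid field with placed molecules
#'
#' Centroids are placed uniformly in the field with a minimum pairwise
#' separation (rejection sampling). Each molecule is assigned a centroid
#' uniformly at random and placed at a distance drawn from `placement`, at a
#' uniform angle.
#'
#' @param n_eisosomes Number of eisosome centroids (>= 1).
#' @param n_molecules Number of molecule localizations.
#' @param field_size_um Pair `(width, height)` in um.
#' @param placement Distance distribution, one of
#'   `list(type = "fixed", distance_um = d)`,
#'   `list(type = "ring", min_um = a, max_um = b)` (uniform on the annulus
#'   radius), or `list(type = "gaussian", mean_um = m, sd_um = s)` (negative
#'   draws folded to keep distances non-negative).
#' @param min_separation_um Minimum centroid separation (default 0.5 um,
#'   roughly two eisosome diameters).
#' @param seed Integer RNG seed.
#' @param max_attempts Rejection-sampling attempts per centroid before the
#'   packing is declared infeasible.
#' @return A list with `centroids` (data frame `x_um`, `y_um`), `molecules`
#'   (localization data frame) and `ground_truth` (assigned centroid index and
#'   true distance per molecule).
#' @export
simulate_eisosome_field <- function(n_eisosomes, n_molecules,
                                    field_size_um = c(10, 10),
                                    placement = list(type = "fixed",
                                                     distance_um = 0.2),
                                    min_separation_um = 0.5, seed = 1L,
                                    max_attempts = 1000L) {
  if (n_eisosomes < 1) stop("`n_eisosomes` must be >= 1", call. = FALSE)
  with_seed(seed, {
    cx <- numeric(0); cy <- numeric(0)
    for (i in seq_len(n_eisosomes)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        px <- stats::runif(1, 0, field_size_um[1])
        py <- stats::runif(1, 0, field_size_um[2])
        if (!length(cx) ||
            min(sqrt((cx - px)^2 + (cy - py)^2)) >= min_separation_um) {
          cx <- c(cx, px); cy <- c(cy, py); placed <- TRUE; break
        }
      }
      if (!placed) {
        stop(sprintf(
          "could not place centroid %d with min separation %.3f um after %d attempts",
          i, min_separation_um, max_attempts), call. = FALSE)
      }
    }
    idx <- sample.int(n_eisosomes, n_molecules, replace = TRUE)
    dist <- switch(placement$type,
      fixed = rep(placement$distance_um, n_molecules),
      ring = stats::runif(n_molecules, placement$min_um, placement$max_um),
      gaussian = abs(stats::rnorm(n_molecules, placement$mean_um,
                                  placement$sd_um)),
      stop("unknown placement type: ", placement$type, call. = FALSE))
    ang <- stats::runif(n_molecules, 0, 2 * pi)
    molecules <- data.frame(
      trajectory_id = seq_len(n_molecules), frame = 0L,
      x_um = cx[idx] + dist * cos(ang),
      y_um = cy[idx] + dist * sin(ang),
      intensity = 1)
    list(
      centroids = data.frame(x_um = cx, y_um = cy),
      molecules = molecules,
      ground_truth = list(
        kind = "eisosome_field", assigned_centroid = idx,
        true_distance_um = dist, placement = placement, seed = seed))
  })
}

#' Serialize a ground-truth record as JSON
#'
#' Written next to each generated artifact so every simulation is
#' reconstructible and testable against its generating parameters.
#'
#' @param ground_truth A ground-truth list from a generator.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
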