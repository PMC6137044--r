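# Generators: determinism contracts, trivial identities, and the Brownian
# step-variance law that every downstream analysis relies on.

test_that("drifting-cell generator: identity, shift definition, determinism", {
  cfg <- sim_config(seed = 7, n_frames = 4, image_shape = c(32, 32),
                    noise_sd = 0)
  still <- simulate_drifting_cells(cfg, matrix(0, 3, 2))
  expect_identical(still$stack$frames[[1]], still$stack$frames[[3]])

  cfg2 <- sim_config(seed = 7, n_frames = 2, image_shape = c(32, 32),
                     noise_sd = 0)
  moved <- simulate_drifting_cells(cfg2, matrix(c(3, -2), 1))
  expect_equal(moved$stack$frames[[2]],
               oracle_roll(moved$stack$frames[[1]], 3, -2))

  noisy_cfg <- sim_config(seed = 7, n_frames = 4, image_shape = c(32, 32),
                          noise_sd = 10)
  sh <- matrix(c(1, 0, 0, 2, -1, -1), ncol = 2, byrow = TRUE)
  a <- simulate_drifting_cells(noisy_cfg, sh)
  b <- simulate_drifting_cells(noisy_cfg, sh)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_equal(a$ground_truth$shifts, sh)
})

test_that("drifting-cell generator rejects out-of-bound shifts naming the pair", {
  cfg <- sim_config(seed = 1, n_frames = 3, image_shape = c(32, 32))
  expect_error(
    simulate_drifting_cells(cfg, matrix(c(0, 0, 9, 0), ncol = 2, byrow = TRUE)),
    "frame pair 2")
})

test_that("trajectory generator: degenerate case, determinism, validation", {
  p0 <- two_population_params(0.5, 0, 0, loc_error_nm = 0)
  sim <- simulate_trajectories(p0, 5, 10, 1, seed = 3)
  for (id in 1:5) {
    tr <- sim$trajectories[sim$trajectories$trajectory_id == id, ]
    expect_equal(diff(range(tr$x_um)), 0)
    expect_equal(diff(range(tr$y_um)), 0)
  }

  p <- two_population_params(0.6, 1e-3, 1e-5, loc_error_nm = 20)
  a <- simulate_trajectories(p, 20, 5, 0.5, seed = 11)
  b <- simulate_trajectories(p, 20, 5, 0.5, seed = 11)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$ground_truth$mobile, b$ground_truth$mobile)

  expect_error(two_population_params(0.5, -1, 0), "d_mobile")
  expect_error(two_population_params(0.5, 1e-5, 1e-3), "faster")
  expect_error(simulate_trajectories(p, 10, 5, -1), "dt_s")
})

test_that("mean squared step matches 4*D*dt for a pure mobile population", {
  # D = 5.1e-4 um^2/s at 10 s lag: E[r^2] = 4*D*dt = 0.0204 um^2
  p <- two_population_params(1, 5.1e-4, 1e-5, loc_error_nm = 0)
  sim <- simulate_trajectories(p, 4000, 1, 10, seed = 9)
  steps <- step_sizes(sim$trajectories, 1, 10)
  expect_equal(nrow(steps), 4000)
  r2 <- steps$r_um^2
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 0.0204), 3 * se)
})

test_that("per-population step variance follows 4*D*dt + 4*sigma_loc^2", {
  p <- two_population_params(0.5, 8e-4, 2e-5, loc_error_nm = 30)
  dt <- 5
  sim <- simulate_trajectories(p, 600, 8, dt, seed = 21)
  sig_um <- 30 / 1000
  for (mob in c(TRUE, FALSE)) {
    ids <- which(sim$ground_truth$mobile == mob)
    sub <- sim$trajectories[sim$trajectories$trajectory_id %in% ids, ]
    r2 <- step_sizes(sub, 1, dt)$r_um^2
    expected <- 4 * (if (mob) p$d_mobile_um2_s else p$d_immobile_um2_s) * dt +
      4 * sig_um^2
    se <- sd(r2) / sqrt(length(r2))
    expect_lt(abs(mean(r2) - expected), 3 * se)
  }
})

test_that("rendered movies place, separate and conserve spot intensity", {
  cfg <- sim_config(seed = 2, pixel_size_nm = 100, n_frames = 3,
                    image_shape = c(21, 21), noise_sd = 0, psf_sigma_px = 1.2)
  # one static emitter at pixel (row 8, col 12) = (x 1.2, y 0.8) um
  tr <- data.frame(trajectory_id = 1, frame = 0:2, x_um = 1.2, y_um = 0.8,
                   intensity = NA)
  mv <- render_particle_movie(tr, cfg, intensity = 1000)
  for (f in mv$frames) {
    expect_equal(unname(which(f == max(f), arr.ind = TRUE)[1, ]), c(9, 13))
    expect_gt(sum(f), 990)
    expect_lt(sum(f), 1010)
  }

  two <- data.frame(trajectory_id = c(1, 2), frame = 0,
                    x_um = c(0.5, 1.5), y_um = 1.0, intensity = NA)
  cfg1 <- sim_config(seed = 2, pixel_size_nm = 100, n_frames = 2,
                     image_shape = c(21, 21), noise_sd = 0, psf_sigma_px = 0.9)
  mv2 <- render_particle_movie(two, cfg1, intensity = 500)
  f <- mv2$frames[[1]]
  peaks <- which(f >= 0.99 * max(f), arr.ind = TRUE)
  expect_gte(nrow(peaks), 2)

  oob <- data.frame(trajectory_id = 7, frame = 1, x_um = 99, y_um = 1,
                    intensity = NA)
  expect_error(render_particle_movie(oob, cfg), "trajectory 7, frame 1")
})

test_that("FRAP trace generator matches its stated closed form", {
  sim <- simulate_frap_trace(1000, 0.6, 0, 0.2, n_pre = 5, n_post = 20,
                             dt_s = 0.05, noise_sd = 0, seed = 1)
  post <- sim$trace$intensity[sim$trace$time_s >= 0]
  expect_equal(post, rep(400, 20))  # F0 = pre * (1 - depth), no recovery

  sim2 <- simulate_frap_trace(1000, 0.6, 1, 0.1, n_pre = 5, n_post = 400,
                              dt_s = 0.05, noise_sd = 0, seed = 1)
  expect_lt(abs(tail(sim2$trace$intensity, 1) - 1000), 1e-6)

  # value at t = t_half sits exactly halfway between F0 and Finf
  sim3 <- simulate_frap_trace(1000, 0.5, 0.8, 0.25, n_pre = 5, n_post = 30,
                              dt_s = 0.05, noise_sd = 0, seed = 1)
  gt <- sim3$ground_truth
  at_half <- sim3$trace$intensity[abs(sim3$trace$time_s - 0.25) < 1e-9]
  expect_equal(at_half, gt$f0 + 0.5 * (gt$f_inf - gt$f0))

  expect_error(simulate_frap_trace(1000, 0.6, 0.8, -1), "t_half_s")
})

test_that("eisosome field generator honors placement spec and determinism", {
  at0 <- simulate_eisosome_field(3, 30, placement = list(type = "fixed",
                                                         distance_um = 0),
                                 seed = 4)
  expect_equal(at0$molecules$x_um, at0$centroids$x_um[at0$ground_truth$assigned_centroid])

  one <- simulate_eisosome_field(1, 50, placement = list(type = "fixed",
                                                         distance_um = 0.2),
                                 seed = 4)
  d <- sqrt((one$molecules$x_um - one$centroids$x_um)^2 +
              (one$molecules$y_um - one$centroids$y_um)^2)
  expect_equal(d, rep(0.2, 50))

  a <- simulate_eisosome_field(8, 100, seed = 12)
  b <- simulate_eisosome_field(8, 100, seed = 12)
  expect_identical(a$molecules, b$molecules)
  expect_identical(a$centroids, b$centroids)

  expect_error(
    simulate_eisosome_field(500, 10, field_size_um = c(2, 2),
                            min_separation_um = 1, seed = 1,
                            max_attempts = 50),
    "attempts")
})
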