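# Detection, linking, CPD construction and the two-population fit.

test_that("discoidal filter: sign structure and brute-force equivalence", {
  expect_equal(discoidal_filter(matrix(7, 16, 16)), matrix(0, 16, 16))

  img <- matrix(0, 16, 16); img[8, 8] <- 100
  f <- discoidal_filter(img)
  expect_gt(f[8, 8], 0)
  expect_lt(f[8, 11], 0)  # inside the annulus of the bright pixel

  set.seed(41)
  for (k in 1:3) {
    img <- matrix(rnorm(256, 50, 10), 16, 16)
    expect_equal(discoidal_filter(img, 1, 3), oracle_discoidal(img, 1, 3))
  }
  # a different radius pair exercises the kernel construction
  img <- matrix(runif(256), 16, 16)
  expect_equal(discoidal_filter(img, 2, 4), oracle_discoidal(img, 2, 4))

  expect_error(discoidal_filter(matrix(0, 5, 5), 1, 3), "smaller")
  expect_error(discoidal_filter(matrix(0, 16, 16), 3, 3), "exceed")
})

test_that("detection localizes a noise-free emitter to sub-pixel accuracy", {
  cfg <- sim_config(seed = 1, pixel_size_nm = 100, n_frames = 2,
                    image_shape = c(25, 25), noise_sd = 0, psf_sigma_px = 1.3)
  truth <- data.frame(trajectory_id = 1, frame = 0, x_um = 1.23, y_um = 1.41,
                      intensity = NA)
  mv <- render_particle_movie(truth, cfg, intensity = 2000)
  locs <- detect_and_localize(mv, threshold = 5)
  expect_equal(nrow(locs), 1)
  expect_lt(abs(locs$x_um - 1.23), 0.1 * 0.1)  # 0.1 px of 100 nm
  expect_lt(abs(locs$y_um - 1.41), 0.1 * 0.1)
})

test_that("detections closer than r_outer merge, keeping one spot", {
  cfg <- sim_config(seed = 1, pixel_size_nm = 100, n_frames = 2,
                    image_shape = c(25, 25), noise_sd = 0, psf_sigma_px = 1.0)
  pair <- data.frame(trajectory_id = 1:2, frame = 0,
                     x_um = c(1.2, 1.3), y_um = 1.2, intensity = NA)
  mv <- render_particle_movie(pair, cfg, intensity = 1500)
  locs <- detect_and_localize(mv, threshold = 5)
  expect_equal(nrow(locs), 1)
})

test_that("blank noisy frames yield few false positives at 5 sigma", {
  cfg <- sim_config(seed = 19, n_frames = 50, image_shape = c(32, 32),
                    noise_sd = 10, psf_sigma_px = 1.3)
  blank <- render_particle_movie(
    data.frame(trajectory_id = integer(0), frame = integer(0),
               x_um = numeric(0), y_um = numeric(0), intensity = numeric(0)),
    cfg, baseline = 100)
  locs <- detect_and_localize(blank, threshold = 5)
  expect_lte(nrow(locs), 2)  # <= ~1 false positive per 25 frames
})

test_that("linking produces correct trajectories in unambiguous geometries", {
  # one emitter per frame -> one full-length trajectory
  one <- data.frame(trajectory_id = NA, frame = 0:9,
                    x_um = 5 + cumsum(rnorm(10, 0, 0.05)),
                    y_um = 5 + cumsum(rnorm(10, 0, 0.05)), intensity = 1)
  linked <- link_trajectories(one, max_step_um = 0.5)
  expect_equal(length(unique(linked$trajectory_id)), 1)
  expect_equal(nrow(linked), 10)

  # two static emitters 10 um apart never swap
  two <- rbind(
    data.frame(trajectory_id = NA, frame = rep(0:4, each = 1), x_um = 1,
               y_um = 1, intensity = 1),
    data.frame(trajectory_id = NA, frame = rep(0:4, each = 1), x_um = 11,
               y_um = 1, intensity = 1))
  linked2 <- link_trajectories(two, max_step_um = 1)
  expect_equal(length(unique(linked2$trajectory_id)), 2)
  for (id in unique(linked2$trajectory_id)) {
    expect_equal(diff(range(linked2$x_um[linked2$trajectory_id == id])), 0)
  }

  # a gap of one missed frame is bridged when allowed
  gappy <- data.frame(trajectory_id = NA, frame = c(0, 1, 3, 4), x_um = 2,
                      y_um = 2, intensity = 1)
  expect_equal(length(unique(link_trajectories(gappy, 0.5,
                                               max_gap_frames = 1)$trajectory_id)), 1)
  expect_equal(length(unique(link_trajectories(gappy, 0.5,
                                               max_gap_frames = 0)$trajectory_id)), 2)
})

test_that("linking matches ground-truth identities at tracking density", {
  pre <- sim_preset("aptes_yeast")
  sim <- simulate_trajectories(pre$params, 20, 30, pre$dt_s, seed = 33,
                               origin_box_um = c(40, 40))
  shuffled <- sim$trajectories[order(sim$trajectories$frame,
                                     sim$trajectories$x_um), ]
  shuffled$true_id <- shuffled$trajectory_id
  shuffled$trajectory_id <- NA
  linked <- link_trajectories(shuffled, max_step_um = 1)
  # a link is correct when consecutive members share the true identity
  agree <- unlist(lapply(split(linked, linked$trajectory_id), function(tr) {
    if (nrow(tr) < 2) return(logical(0))
    tr <- tr[order(tr$frame), ]
    tr$true_id[-1] == tr$true_id[-nrow(tr)]
  }))
  expect_gte(mean(agree), 0.95)
})

test_that("step sizes follow their definitions", {
  static <- data.frame(trajectory_id = 1, frame = 0:5, x_um = 3, y_um = 4)
  expect_equal(step_sizes(static, 1, 1)$r_um, rep(0, 5))

  tri <- data.frame(trajectory_id = 1, frame = 0:1, x_um = c(0, 3),
                    y_um = c(0, 4))
  s <- step_sizes(tri, 1, 0.5)
  expect_equal(s$r_um, 5)
  expect_equal(s$lag_s, 0.5)

  # gapped frames contribute no step at lag 1
  gap <- data.frame(trajectory_id = 1, frame = c(0, 2, 3), x_um = 0:2,
                    y_um = 0)
  expect_equal(nrow(step_sizes(gap, 1, 1)), 1)
  expect_equal(nrow(step_sizes(gap, 2, 1)), 1)  # 0 -> 2
})

test_that("empirical CPD is a valid CDF estimate", {
  steps <- data.frame(r_um = c(1, 2, 3, runif(7, 4, 5)), lag_s = 1)
  cpd <- empirical_cpd(steps)
  expect_equal(cpd$p[cpd$r2_um2 == 4], 0.2)  # 2 of 10 samples have r^2 <= 4
  expect_equal(max(cpd$p), 1)
  expect_true(all(diff(cpd$p) >= 0))
  expect_error(empirical_cpd(steps[1:5, ]), "10 steps")
})

test_that("empirical CPD lies in the DKW band of the Rayleigh model", {
  d_true <- 5.1e-4; dt <- 10
  p <- two_population_params(1, d_true, 0)
  sim <- simulate_trajectories(p, 500, 1, dt, seed = 55)
  cpd <- empirical_cpd(step_sizes(sim$trajectories, 1, dt))
  eps <- sqrt(log(2 / 0.05) / (2 * nrow(cpd)))
  analytic <- 1 - exp(-cpd$r2_um2 / (4 * d_true * dt))
  expect_lt(max(abs(cpd$p - analytic)), eps)
})

test_that("two-population fit recovers itself and simulated truth", {
  t <- 10
  # noise-free: tabulate the model and refit -> 4 significant figures
  r2 <- seq(1e-4, 0.12, length.out = 400)
  p <- 1 - 0.57 * exp(-r2 / (4 * 5.1e-4 * t)) -
    0.43 * exp(-r2 / (4 * 1e-5 * t))
  fit0 <- fit_cpd_two_population(data.frame(r2_um2 = r2, p = p), lag_s = t,
                                 n_boot = 0)
  expect_equal(fit0$alpha_mobile, 0.57, tolerance = 1e-4)
  expect_equal(fit0$d_mobile, 5.1e-4, tolerance = 1e-4)
  expect_equal(fit0$d_immobile, 1e-5, tolerance = 1e-3)

  # single-population data: D within 10% at n = 2000
  sim1 <- simulate_trajectories(two_population_params(1, 5.1e-4, 0), 2000, 1,
                                t, seed = 61)
  cpd1 <- empirical_cpd(step_sizes(sim1$trajectories, 1, t))
  fit1 <- fit_cpd_two_population(cpd1, fix_alpha = 1, n_boot = 0)
  expect_lt(abs(fit1$d_mobile - 5.1e-4) / 5.1e-4, 0.10)

  # with alpha free but truth single-population, the fit agrees with the
  # constrained single-population form
  fit1b <- fit_cpd_two_population(cpd1, n_boot = 0)
  expect_lt(abs(fit1b$alpha_mobile * fit1b$d_mobile +
                  (1 - fit1b$alpha_mobile) * fit1b$d_immobile -
                  fit1$d_mobile) / fit1$d_mobile, 0.05)

  # two-population preset: alpha within 0.03 of the generating 0.57
  pre <- sim_preset("aptes_yeast")
  sim2 <- simulate_trajectories(pre$params, 5000, 1, pre$dt_s, seed = 62)
  fit2 <- fit_cpd_two_population(
    empirical_cpd(step_sizes(sim2$trajectories, 1, pre$dt_s)), n_boot = 0)
  expect_lt(abs(fit2$alpha_mobile - 0.57), 0.03)

  expect_error(fit_cpd_two_population(data.frame(r2_um2 = r2[1:20],
                                                 p = p[1:20]), lag_s = t),
               ">= 50")
})

test_that("fit bias of alpha and D shrinks as n grows", {
  pre <- sim_preset("aptes_yeast")
  err <- vapply(c(500, 2000, 8000), function(n) {
    fits <- vapply(1:3, function(s) {
      sim <- simulate_trajectories(pre$params, n, 1, pre$dt_s,
                                   seed = 100 * n + s)
      f <- fit_cpd_two_population(
        empirical_cpd(step_sizes(sim$trajectories, 1, pre$dt_s)), n_boot = 0)
      c(f$alpha_mobile, f$d_mobile)
    }, numeric(2))
    c(abs(mean(fits[1, ]) - 0.57), abs(mean(fits[2, ]) - 5.1e-4) / 5.1e-4)
  }, numeric(2))
  expect_lt(err[1, 3], err[1, 1] + 0.01)  # alpha error non-increasing
  expect_lt(err[1, 3], 0.02)
  expect_lt(err[2, 3], 0.05)
})

test_that("bootstrap standard errors are reproducible and plausible", {
  pre <- sim_preset("aptes_yeast")
  sim <- simulate_trajectories(pre$params, 1000, 1, pre$dt_s, seed = 71)
  cpd <- empirical_cpd(step_sizes(sim$trajectories, 1, pre$dt_s))
  f1 <- fit_cpd_two_population(cpd, n_boot = 50, boot_seed = 7)
  f2 <- fit_cpd_two_population(cpd, n_boot = 50, boot_seed = 7)
  expect_identical(f1$se, f2$se)
  expect_gt(f1$se[["alpha_mobile"]], 0.003)
  expect_lt(f1$se[["alpha_mobile"]], 0.1)
})

test_that("rendered-movie pipeline recovers the generating mixture", {
  pre <- sim_preset("aptes_yeast")
  n_part <- 20
  cfg <- sim_config(seed = 83, pixel_size_nm = 80, frame_interval_s = pre$dt_s,
                    n_frames = 50, image_shape = c(128, 128), noise_sd = 2,
                    psf_sigma_px = 1.3)
  field_um <- 128 * 0.08
  sim <- simulate_trajectories(pre$params, n_part, cfg$n_frames - 1, pre$dt_s,
                               seed = 84, origin_box_um = c(1, 1))
  g <- grid_origins(n_part, field_um, margin_um = 1.6)
  for (p in seq_len(n_part)) {
    rows <- sim$trajectories$trajectory_id == p
    first <- which(rows)[1]
    sim$trajectories$x_um[rows] <- sim$trajectories$x_um[rows] -
      sim$trajectories$x_um[first] + g$x[p]
    sim$trajectories$y_um[rows] <- sim$trajectories$y_um[rows] -
      sim$trajectories$y_um[first] + g$y[p]
  }
  mv <- render_particle_movie(sim$trajectories, cfg, intensity = 1000,
                              baseline = 100)
  locs <- detect_and_localize(mv, threshold = 5)
  linked <- link_trajectories(locs, max_step_um = 0.6)
  steps <- step_sizes(linked, 1, pre$dt_s)
  fit <- fit_cpd_two_population(empirical_cpd(steps), n_boot = 0)
  alpha_true <- mean(sim$ground_truth$mobile)
  expect_lt(abs(fit$alpha_mobile - alpha_true), 0.05)
  expect_lt(abs(fit$d_mobile - pre$params$d_mobile_um2_s) /
              pre$params$d_mobile_um2_s, 0.15)
})
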