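# Single-particle detection, localization, linking and the two-population
# cumulative-probability-distribution (CPD) analysis of step sizes.
#
# The CPD of squared displacements r^2 at lag t for a two-population mixture of
# 2D Brownian walkers is
#   P(r^2, t) = 1 - alpha * exp(-r^2 / (4 D1 t)) - (1 - alpha) * exp(-r^2 / (4 D2 t))
# with mobile fraction alpha and apparent diffusion coefficients D1 >= D2.
# Localization error is not a separate fit parameter; it is absorbed into the
# apparent D (4 D t + 4 sigma^2 per step).

#' Discoidal averaging filter
#'
#' Band-pass spot-enhancement filter: each output pixel is the mean over the
#' inner disk (pixel-center distance `<= r_inner_px`) minus the mean over the
#' surrounding annulus (`r_inner_px <` distance `<= r_outer_px`). Borders are
#' handled by mirror reflection.
#'
#' @param image Numeric matrix, larger than `2 * r_outer_px + 1` on both axes.
#' @param r_inner_px Inner disk radius in pixels (default 1).
#' @param r_outer_px Outer annulus radius in pixels (default 3, must exceed
#'   `r_inner_px`).
#' @return Filtered matrix of the same shape.
#' @export
discoidal_filter <- function(image, r_inner_px = 1L, r_outer_px = 3L) {
  stopifnot(is.matrix(image))
  if (r_outer_px <= r_inner_px) {
    stop("`r_outer_px` must exceed `r_inner_px`", call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  k <- 2L * r_outer_px + 1L
  if (h < k || w < k) {
    stop(sprintf("image (%d x %d) smaller than filter kernel (%d x %d)",
                 h, w, k, k), call. = FALSE)
  }
  offs <- expand.grid(di = -r_outer_px:r_outer_px, dj = -r_outer_px:r_outer_px)
  dd <- sqrt(offs$di^2 + offs$dj^2)
  inner <- offs[dd <= r_inner_px, ]
  annulus <- offs[dd > r_inner_px & dd <= r_outer_px, ]
  pad <- pad_reflect(image, r_outer_px)
  acc <- function(set) {
    s <- matrix(0, h, w)
    for (i in seq_len(nrow(set))) {
      ri <- (1 + r_outer_px + set$di[i]):(h + r_outer_px + set$di[i])
      ci <- (1 + r_outer_px + set$dj[i]):(w + r_outer_px + set$dj[i])
      s <- s + pad[ri, ci]
    }
    s / nrow(set)
  }
  acc(inner) - acc(annulus)
}

# Mirror-pad a matrix by `r` pixels (edge pixel mirrored: d c b a | a b c d).
pad_reflect <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  idx <- function(n) {
    i <- (-r):(n - 1L + r)
    i[i < 0] <- -1L - i[i < 0]
    i[i >= n] <- 2L * n - 1L - i[i >= n]
    i + 1L
  }
  m[idx(h), idx(w), drop = FALSE]
}

#' Detect and localize fluorescent spots in an image stack
#'
#' Per frame: the image is discoidal-filtered; candidate spots are local
#' maxima of the filtered image exceeding `threshold` robust standard
#' deviations (MAD) above the filtered frame's median; candidates closer than
#' `r_outer_px` pixels are merged keeping the brighter; each survivor is
#' refined to sub-pixel precision by an intensity-weighted centroid over a
#' `(2 r_outer_px + 1)^2` window of the raw frame (window minimum subtracted
#' as local background).
#'
#' @param stack An [image_stack()].
#' @param r_inner_px,r_outer_px Discoidal filter radii (defaults 1 and 3).
#' @param threshold Detection threshold in robust-SD units (> 0, default 5).
#' @return Localization data frame (`trajectory_id` = `NA`, `frame`, `x_um`,
#'   `y_um`, `intensity`); possibly empty.
#' @export
detect_and_localize <- function(stack, r_inner_px = 1L, r_outer_px = 3L,
                                threshold = 5) {
  stopifnot(inherits(stack, "image_stack"))
  stop_if_not_scalar_pos(threshold, "threshold")
  px_um <- stack$pixel_size_nm / 1000
  out <- vector("list", n_frames(stack))
  for (k in seq_len(n_frames(stack))) {
    raw <- stack$frames[[k]]
    f <- discoidal_filter(raw, r_inner_px, r_outer_px)
    robust_sd <- stats::mad(f)
    if (robust_sd == 0) next  # blank/constant frame: no threshold definable
    cutoff <- stats::median(f) + threshold * robust_sd
    cand <- local_maxima(f, cutoff)
    if (!nrow(cand)) next
    # merge duplicates within r_outer, keeping the brighter filtered response
    cand <- cand[order(-cand$value), , drop = FALSE]
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!keep[i]) next
      if (i < nrow(cand)) {
        j <- (i + 1L):nrow(cand)
        d <- sqrt((cand$row[j] - cand$row[i])^2 + (cand$col[j] - cand$col[i])^2)
        keep[j[d < r_outer_px]] <- FALSE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    loc <- lapply(seq_len(nrow(cand)), function(i) {
      centroid_refine(raw, cand$row[i], cand$col[i], r_outer_px)
    })
    loc <- do.call(rbind, loc)
    out[[k]] <- data.frame(
      trajectory_id = NA_integer_, frame = k - 1L,
      x_um = (loc[, "col"] - 1) * px_um,
      y_um = (loc[, "row"] - 1) * px_um,
      intensity = loc[, "mass"])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(trajectory_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  }
  do.call(rbind, out)
}

# Local maxima (8-neighborhood, >= all neighbors) above `cutoff`.
local_maxima <- function(f, cutoff) {
  h <- nrow(f); w <- ncol(f)
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- f
  is_max <- f >= cutoff
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    is_max <- is_max & (f >= pad[(2:(h + 1L)) + di, (2:(w + 1L)) + dj])
  }
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2], value = f[idx])
}

# Intensity-weighted centroid in a (2r+1)^2 window of the raw frame,
# window minimum subtracted. Returns fractional 1-based (row, col) and mass.
centroid_refine <- function(raw, row, col, r) {
  h <- nrow(raw); w <- ncol(raw)
  ri <- max(1L, row - r):min(h, row + r)
  ci <- max(1L, col - r):min(w, col + r)
  win <- raw[ri, ci, drop = FALSE] - min(raw[ri, ci])
  mass <- sum(win)
  if (mass <= 0) {
    return(c(row = row, col = col, mass = 0))
  }
  c(row = sum(rowSums(win) * ri) / mass,
    col = sum(colSums(win) * ci) / mass,
    mass = mass)
}

#' Link localizations into trajectories
#'
#' Greedy nearest-neighbour linking: for each frame, candidate links between
#' open trajectories and new localizations are resolved globally in ascending
#' order of distance; links longer than `max_step_um` are forbidden; gaps of
#' up to `max_gap_frames` missed frames are bridged. Every localization joins
#' at most one trajectory.
#'
#' @param localizations Localization data frame (`frame`, `x_um`, `y_um`, ...).
#' @param max_step_um Maximum link distance, um.
#' @param max_gap_frames Maximum number of bridged missed frames (default 0).
#' @return The localization data frame with `trajectory_id` assigned, sorted
#'   by trajectory then frame.
#' @export
link_trajectories <- function(localizations, max_step_um, max_gap_frames = 0L) {
  stopifnot(is.data.frame(localizations))
  stop_if_not_scalar_pos(max_step_um, "max_step_um")
  locs <- localizations[order(localizations$frame), , drop = FALSE]
  n <- nrow(locs)
  locs$trajectory_id <- rep(NA_integer_, n)
  if (!n) return(locs)
  track_last <- integer(0)   # row index of each track's last localization
  next_id <- 1L
  for (f in sort(unique(locs$frame))) {
    rows_f <- which(locs$frame == f)
    open_idx <- which(locs$frame[track_last] < f &
                        f - locs$frame[track_last] <= max_gap_frames + 1L)
    if (length(open_idx) && length(rows_f)) {
      open_rows <- track_last[open_idx]
      dx <- outer(locs$x_um[open_rows], locs$x_um[rows_f], "-")
      dy <- outer(locs$y_um[open_rows], locs$y_um[rows_f], "-")
      d <- sqrt(dx^2 + dy^2)
      pairs <- which(d <= max_step_um, arr.ind = TRUE)
      if (nrow(pairs)) {
        pairs <- pairs[order(d[pairs]), , drop = FALSE]
        used_track <- logical(length(open_idx))
        used_loc <- logical(length(rows_f))
        for (p in seq_len(nrow(pairs))) {
          ti <- pairs[p, 1]; li <- pairs[p, 2]
          if (used_track[ti] || used_loc[li]) next
          used_track[ti] <- TRUE; used_loc[li] <- TRUE
          row_new <- rows_f[li]
          locs$trajectory_id[row_new] <- locs$trajectory_id[open_rows[ti]]
          track_last[open_idx[ti]] <- row_new
        }
      }
    }
    for (row_new in rows_f[is.na(locs$trajectory_id[rows_f])]) {
      locs$trajectory_id[row_new] <- next_id
      next_id <- next_id + 1L
      track_last <- c(track_last, row_new)
    }
  }
  locs[order(locs$trajectory_id, locs$frame), , drop = FALSE]
}

#' Step sizes at a fixed lag
#'
#' Euclidean displacement between localizations of the same trajectory whose
#' frame indices differ by exactly `lag_frames` (gapless pairs only).
#'
#' @param trajectories Trajectory data frame (`trajectory_id`, `frame`,
#'   `x_um`, `y_um`).
#' @param lag_frames Lag in frames (>= 1, default 1).
#' @param frame_interval_s Time between consecutive frames, seconds.
#' @return Data frame of `StepSample`s: `r_um`, `lag_s`.
#' @export
step_sizes <- function(trajectories, lag_frames = 1L, frame_interval_s) {
  stopifnot(is.data.frame(trajectories))
  if (lag_frames < 1) stop("`lag_frames` must be >= 1", call. = FALSE)
  stop_if_not_scalar_pos(frame_interval_s, "frame_interval_s")
  parts <- split(trajectories, trajectories$trajectory_id)
  r <- unlist(lapply(parts, function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2L) return(numeric(0))
    j <- match(tr$frame + lag_frames, tr$frame)
    ok <- !is.na(j)
    sqrt((tr$x_um[j[ok]] - tr$x_um[ok])^2 + (tr$y_um[j[ok]] - tr$y_um[ok])^2)
  }), use.names = FALSE)
  data.frame(r_um = r, lag_s = rep(lag_frames * frame_interval_s, length(r)))
}

#' Empirical cumulative probability distribution of squared step sizes
#'
#' `P(r^2)` evaluated at the sorted squared displacements (no binning):
#' the fraction of samples with squared step `<=` each sample value.
#'
#' @param steps Step data frame from [step_sizes()] (all rows must share one
#'   lag), with at least 10 steps.
#' @return Data frame `r2_um2` (sorted), `p` (non-decreasing, ending at 1),
#'   with the common lag as attribute `lag_s`.
#' @export
empirical_cpd <- function(steps) {
  stopifnot(is.data.frame(steps))
  n <- nrow(steps)
  if (n < 10L) {
    stop("need at least 10 steps for a CPD, got ", n, call. = FALSE)
  }
  if (length(unique(steps$lag_s)) != 1L) {
    stop("all steps in one CPD must share the same lag", call. = FALSE)
  }
  r2 <- sort(steps$r_um^2)
  # findInterval on the sorted sample gives, for each value, the index of the
  # last tied occurrence, i.e. n * P(X <= r2)
  p <- findInterval(r2, r2) / n
  structure(data.frame(r2_um2 = r2, p = p), lag_s = steps$lag_s[1])
}

cpd_model <- function(r2, t, alpha, d1, d2) {
  1 - alpha * exp(-r2 / (4 * d1 * t)) - (1 - alpha) * exp(-r2 / (4 * d2 * t))
}

# Box-bounded minimization: L-BFGS-B then a Nelder-Mead polish with penalty
# bounds, which also rescues occasional L-BFGS-B line-search failures.
opt_box <- function(par, fn, lower, upper) {
  o <- tryCatch(
    stats::optim(par, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = 1e7, maxit = 500)),
    error = function(e) list(par = par, value = fn(par), convergence = 99L))
  fn_pen <- function(th) {
    if (any(th < lower) || any(th > upper)) return(Inf)
    fn(th)
  }
  polish <- stats::optim(o$par, fn_pen, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 5000,
                                        warn.1d.NelderMead = FALSE))
  if (polish$value <= o$value) o <- polish
  o
}

#' Fit the two-population diffusion model to a CPD
#'
#' Bounded least squares of
#' `P(r^2, t) = 1 - a exp(-r^2/(4 D1 t)) - (1 - a) exp(-r^2/(4 D2 t))`
#' with `a` in `[0, 1]` and `D1 >= D2 >= 0` (enforced by parameterizing
#' `D2 = D1 * s`, `s` in `(0, 1]`, on a log10 scale). Fitted from several
#' starting points; standard errors by a seeded bootstrap over the squared
#' displacements.
#'
#' @param cpd CPD data frame from [empirical_cpd()] (needs >= 50 steps).
#' @param lag_s Lag time in seconds; defaults to the CPD's `lag_s` attribute.
#' @param init Optional list with `alpha`, `d1`, `d2` starting values.
#' @param fix_alpha Optionally fix the mobile fraction. `fix_alpha = 1`
#'   reduces the model to the single-population form
#'   `1 - exp(-r^2/(4 D t))`.
#' @param n_boot Bootstrap resamples for standard errors (default 200;
#'   0 skips the bootstrap and returns `NA` errors).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return An object of class `cpd_fit`: `alpha_mobile`, `d_mobile`,
#'   `d_immobile` (um^2/s), `se` (named vector), `residual_norm`, `n_steps`,
#'   `lag_s`, `convergence`.
#' @export
fit_cpd_two_population <- function(cpd, lag_s = attr(cpd, "lag_s"),
                                   init = NULL, fix_alpha = NULL,
                                   n_boot = 200L, boot_seed = 1L) {
  stopifnot(is.data.frame(cpd))
  if (is.null(lag_s)) stop("`lag_s` must be supplied", call. = FALSE)
  n <- nrow(cpd)
  if (n < 50L) {
    stop("two-population fit needs >= 50 steps, got ", n, call. = FALSE)
  }
  r2 <- cpd$r2_um2; p <- cpd$p; t <- lag_s

  fit_once <- function(r2, p, starts) {
    obj <- function(th) {
      a <- th[1]; d1 <- 10^th[2]; d2 <- d1 * 10^th[3]
      sum((p - cpd_model(r2, t, a, d1, d2))^2)
    }
    obj1 <- function(th) { # single population (alpha fixed at 1)
      sum((p - (1 - exp(-r2 / (4 * 10^th[1] * t))))^2)
    }
    if (!is.null(fix_alpha) && fix_alpha == 1) {
      best <- NULL
      for (s in starts) {
        o <- opt_box(s[2], obj1, lower = -10, upper = 3)
        if (is.null(best) || o$value < best$value) best <- o
      }
      return(list(alpha = 1, d1 = 10^best$par[1], d2 = NA_real_,
                  value = best$value, convergence = best$convergence))
    }
    lower <- c(0, -10, -8); upper <- c(1, 3, 0)
    if (!is.null(fix_alpha)) {
      objf <- function(th2) obj(c(fix_alpha, th2))
      best <- NULL
      for (s in starts) {
        o <- opt_box(s[2:3], objf, lower = lower[2:3], upper = upper[2:3])
        if (is.null(best) || o$value < best$value) best <- o
      }
      return(list(alpha = fix_alpha, d1 = 10^best$par[1],
                  d2 = 10^(best$par[1] + best$par[2]),
                  value = best$value, convergence = best$convergence))
    }
    best <- NULL
    for (s in starts) {
      o <- opt_box(s, obj, lower = lower, upper = upper)
      if (is.null(best) || o$value < best$value) best <- o
    }
    list(alpha = best$par[1], d1 = 10^best$par[2],
         d2 = 10^(best$par[2] + best$par[3]),
         value = best$value, convergence = best$convergence)
  }

  # data-driven starts: single-population estimate of the apparent D
  d_hat <- max(mean(r2) / (4 * t), 1e-9)
  starts <- list(c(0.5, log10(2 * d_hat), -2),
                 c(0.3, log10(3 * d_hat), -1.5),
                 c(0.8, log10(1.2 * d_hat), -2.5))
  if (!is.null(init)) {
    starts <- c(list(c(init$alpha, log10(init$d1),
                       log10(max(init$d2 / init$d1, 1e-8)))), starts)
  }
  fit <- fit_once(r2, p, starts)
  if (fit$convergence != 0) {
    stop(sprintf(
      paste0("CPD fit did not converge (code %d); best iterate: alpha = %.4f, ",
             "D1 = %.3e, D2 = %.3e, SSR = %.3e"),
      fit$convergence, fit$alpha, fit$d1, fit$d2, fit$value), call. = FALSE)
  }

  se <- c(alpha_mobile = NA_real_, d_mobile = NA_real_, d_immobile = NA_real_)
  if (n_boot > 0) {
    start_hat <- list(c(fit$alpha, log10(fit$d1),
                        log10(max(ifelse(is.na(fit$d2), 1e-8, fit$d2) / fit$d1,
                                  1e-8))))
    boots <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        rb <- sort(sample(r2, n, replace = TRUE))
        pb <- findInterval(rb, rb) / n
        fb <- fit_once(rb, pb, start_hat)
        c(fb$alpha, fb$d1, fb$d2)
      }, numeric(3))
    })
    se <- c(alpha_mobile = stats::sd(boots[1, ]),
            d_mobile = stats::sd(boots[2, ]),
            d_immobile = stats::sd(boots[3, ]))
  }

  structure(
    list(alpha_mobile = fit$alpha, d_mobile = fit$d1, d_immobile = fit$d2,
         se = se, residual_norm = sqrt(fit$value), n_steps = n, lag_s = t,
         convergence = fit$convergence),
    class = "cpd_fit")
}

#' @export
print.cpd_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<cpd_fit> n = %d steps, lag %g s\n",
           "  mobile fraction: %.3f (SE %.3g)\n",
           "  D_mobile:   %.4g um^2/s (SE %.3g)\n",
           "  D_immobile: %.4g um^2/s (SE %.3g)\n",
           "  residual norm: %.4g\n"),
    x$n_steps, x$lag_s, x$alpha_mobile, x$se[["alpha_mobile"]],
    x$d_mobile, x$se[["d_mobile"]], x$d_immobile, x$se[["d_immobile"]],
    x$residual_norm))
  invisible(x)
}
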