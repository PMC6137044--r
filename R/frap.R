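# FRAP: normalization, single-exponential recovery fitting, and conversion of
# the recovery halftime into a lateral diffusion coefficient.
#
# The recovery model is F(t) = F0 + (Finf - F0) * (1 - exp(-ln2 * t / t_half)),
# parameterized directly in the halftime so the headline quantity is a fit
# parameter. With the pre-bleach level normalized to 1, the mobile fraction is
# (Finf - F0) / (1 - F0). D follows from the uniform-disk bleach geometry as
# D = gamma * w^2 / (4 * t_half).

#' FRAP trace container
#'
#' @param time_s Strictly increasing times in seconds, 0 at the first
#'   post-bleach sample and negative before the bleach.
#' @param intensity Fluorescence intensities (arbitrary units).
#' @param n_pre Number of pre-bleach samples (>= 1).
#' @param roi_radius_um Bleach-spot radius, um (> 0).
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(time_s, intensity, n_pre, roi_radius_um = 0.5) {
  stopifnot(length(time_s) == length(intensity))
  if (any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  if (n_pre < 1) stop("`n_pre` must be >= 1", call. = FALSE)
  stop_if_not_scalar_pos(roi_radius_um, "roi_radius_um")
  structure(
    list(time_s = as.numeric(time_s), intensity = as.numeric(intensity),
         n_pre = as.integer(n_pre), roi_radius_um = roi_radius_um),
    class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf(
    "<frap_trace> %d samples (%d pre-bleach), t in [%.3g, %.3g] s, ROI radius %.2g um\n",
    length(x$time_s), x$n_pre, min(x$time_s), max(x$time_s), x$roi_radius_um))
  invisible(x)
}

#' Normalize a FRAP trace to its pre-bleach level
#'
#' Divides all intensities by the mean of the `n_pre` pre-bleach samples, so
#' the pre-bleach mean of the output is exactly 1. Optionally corrects a
#' linear acquisition-photobleaching trend estimated from the pre-bleach
#' samples before normalizing (off by default; no reference ROI is assumed).
#'
#' @param trace A [frap_trace()].
#' @param bleach_correct Apply the linear pre-bleach trend correction
#'   (default `FALSE`).
#' @return A normalized [frap_trace()].
#' @export
normalize_trace <- function(trace, bleach_correct = FALSE) {
  stopifnot(inherits(trace, "frap_trace"))
  pre <- seq_len(trace$n_pre)
  intensity <- trace$intensity
  if (bleach_correct && trace$n_pre >= 2) {
    fitln <- stats::lm(intensity[pre] ~ trace$time_s[pre])
    slope <- stats::coef(fitln)[2]
    intensity <- intensity - slope * (trace$time_s - mean(trace$time_s[pre]))
  }
  m <- mean(intensity[pre])
  if (!is.finite(m) || m <= 0) {
    stop("pre-bleach mean is zero or negative; cannot normalize", call. = FALSE)
  }
  frap_trace(trace$time_s, intensity / m, trace$n_pre, trace$roi_radius_um)
}

#' Fit the single-exponential FRAP recovery
#'
#' Bounded least squares of
#' `F(t) = f0 + (f_inf - f0) * (1 - exp(-ln2 * t / t_half))` over the
#' post-bleach samples (`time_s >= 0`) of a normalized trace (`f_pre = 1` is
#' fixed by the normalization, not co-fitted). The mobile fraction is
#' `(f_inf - f0) / (1 - f0)`; the diffusion coefficient follows via
#' [diffusion_from_halftime()] with the trace's ROI radius.
#'
#' @param trace A normalized [frap_trace()] with >= 10 post-bleach samples.
#' @param gamma Bleach-geometry factor for the halftime-to-D conversion
#'   (default 0.88, uniform circular beam).
#' @return An object of class `frap_fit` with `f_pre`, `f0`, `f_inf`,
#'   `t_half_s`, `mobile_fraction`, `d_um2_s`, `residual_norm`, `n_post`,
#'   `flat_model_preferred` (TRUE when a constant model beats the recovery
#'   model by AIC, flagging non-monotone or absent recovery).
#' @export
fit_recovery <- function(trace, gamma = 0.88) {
  stopifnot(inherits(trace, "frap_trace"))
  post <- trace$time_s >= 0
  tt <- trace$time_s[post]; ff <- trace$intensity[post]
  if (length(tt) < 10L) {
    stop("recovery fit needs >= 10 post-bleach samples, got ", length(tt),
         call. = FALSE)
  }
  pre_mean <- mean(trace$intensity[seq_len(trace$n_pre)])
  if (abs(pre_mean - 1) > 1e-6) {
    stop("trace is not normalized (pre-bleach mean ", format(pre_mean),
         "); call normalize_trace() first", call. = FALSE)
  }
  model <- function(t, f0, finf, th) f0 + (finf - f0) * (1 - exp(-log(2) * t / th))
  # theta = (f0, gain = finf - f0, t_half); box bounds keep f0 <= finf <= 1.2
  obj <- function(th) sum((ff - model(tt, th[1], th[1] + th[2], th[3]))^2)
  f0_init <- ff[1]
  finf_init <- mean(utils::tail(ff, max(3L, length(ff) %/% 10L)))
  mid <- (f0_init + finf_init) / 2
  th_init <- tt[which(ff >= mid)[1]]
  if (!length(th_init) || is.na(th_init) || th_init <= 0) {
    th_init <- max(diff(tt)[1], 1e-3)
  }
  starts <- list(c(f0_init, max(finf_init - f0_init, 0.01), th_init),
                 c(f0_init, max(finf_init - f0_init, 0.01), th_init / 4),
                 c(f0_init, max(finf_init - f0_init, 0.01), th_init * 4))
  lower <- c(-0.5, 0, 1e-5); upper <- c(1.2, 2, 1e4)
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    o <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e7, maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    stop("FRAP fit failed from every starting point", call. = FALSE)
  }
  # Nelder-Mead polish (bounds enforced by penalty) tightens the optimum and
  # rescues occasional L-BFGS-B line-search failures
  obj_pen <- function(th) {
    if (any(th < lower) || any(th > upper)) return(Inf)
    obj(th)
  }
  polish <- stats::optim(best$par, obj_pen, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 5000))
  if (polish$value <= best$value) {
    best <- polish
  }
  if (best$convergence != 0) {
    stop(sprintf(
      "FRAP fit did not converge (code %d); best iterate f0 = %.4f, f_inf = %.4f, t_half = %.4g s",
      best$convergence, best$par[1], best$par[1] + best$par[2], best$par[3]),
      call. = FALSE)
  }
  f0 <- best$par[1]; finf <- best$par[1] + best$par[2]; th <- best$par[3]
  n <- length(ff)
  ssr_flat <- sum((ff - mean(ff))^2)
  aic_fit <- n * log(best$value / n) + 2 * 3
  aic_flat <- n * log(ssr_flat / n) + 2 * 1
  mobile <- if (abs(1 - f0) < 1e-12) NA_real_ else (finf - f0) / (1 - f0)
  structure(
    list(f_pre = 1, f0 = f0, f_inf = finf, t_half_s = th,
         mobile_fraction = mobile,
         d_um2_s = diffusion_from_halftime(th, trace$roi_radius_um, gamma),
         residual_norm = sqrt(best$value), n_post = n,
         flat_model_preferred = aic_flat < aic_fit),
    class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<frap_fit> %d post-bleach samples\n",
           "  mobile fraction: %.3f   t_half: %.1f ms   D: %.3g um^2/s\n",
           "  f0 = %.3f, f_inf = %.3f, residual norm %.3g%s\n"),
    x$n_post, x$mobile_fraction, 1000 * x$t_half_s, x$d_um2_s,
    x$f0, x$f_inf, x$residual_norm,
    if (x$flat_model_preferred) "  [warning: flat model preferred]" else ""))
  invisible(x)
}

#' Lateral diffusion coefficient from a recovery halftime
#'
#' Uniform-disk bleach geometry: `D = gamma * w^2 / (4 * t_half)` for a
#' circular bleach spot of radius `w`.
#'
#' @param t_half_s Recovery halftime, seconds (> 0).
#' @param w_um Bleach-spot radius, um (> 0).
#' @param gamma Geometry factor (default 0.88 for a uniform circular beam).
#' @return Diffusion coefficient in um^2/s.
#' @examples
#' diffusion_from_halftime(1, 1) # 0.22
#' @export
diffusion_from_halftime <- function(t_half_s, w_um, gamma = 0.88) {
  stop_if_not_scalar_pos(t_half_s, "t_half_s")
  stop_if_not_scalar_pos(w_um, "w_um")
  stop_if_not_scalar_pos(gamma, "gamma")
  gamma * w_um^2 / (4 * t_half_s)
}
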