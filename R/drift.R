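# Frame-to-frame cell-movement quantification by FFT cross-correlation.
#
# Movement is reported in whole pixels, matching how immobilization quality is
# assessed: the circular cross-correlation of each consecutive frame pair is
# computed via forward/inverse FFT and the integer shift at its peak is the
# detected movement. No sub-pixel interpolation is performed in this module.

#' Integer shift between two frames by FFT cross-correlation
#'
#' Computes the circular cross-correlation of `frame_a` and `frame_b` via FFT
#' and returns the signed integer shift `(dx, dy)` at the correlation peak,
#' i.e. the shift by which `frame_a` must be rolled to best match `frame_b`.
#' Both frames are mean-subtracted first to suppress the DC peak. Shifts are
#' reported in `(-N/2, N/2]` per axis. When several pixels tie for the peak,
#' the smallest `(dy, dx)` in lexicographic order is returned.
#'
#' @param frame_a,frame_b Numeric matrices of identical shape.
#' @param mean_subtract Subtract each frame's mean before the FFT
#'   (default `TRUE`).
#' @return Named numeric vector `c(dx = ..., dy = ...)` in pixels.
#' @examples
#' m <- matrix(stats::rnorm(64), 8, 8)
#' cross_correlate_pair(m, m) # c(dx = 0, dy = 0)
#' @export
cross_correlate_pair <- function(frame_a, frame_b, mean_subtract = TRUE) {
  if (!identical(dim(frame_a), dim(frame_b))) {
    stop("frames must have identical shapes", call. = FALSE)
  }
  a <- frame_a; b <- frame_b
  if (mean_subtract) { a <- a - mean(a); b <- b - mean(b) }
  if (all(a == 0) || all(b == 0)) {
    stop("no correlation peak: constant frame(s)", call. = FALSE)
  }
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  h <- nrow(cc); w <- ncol(cc)
  peak <- max(cc)
  tol <- 1e-8 * max(abs(peak), 1)
  cand <- which(cc >= peak - tol, arr.ind = TRUE)
  # 0-based circular indices -> signed shifts in (-N/2, N/2]
  sy <- cand[, 1] - 1L; sx <- cand[, 2] - 1L
  sy <- sy - h * (sy > h / 2)
  sx <- sx - w * (sx > w / 2)
  ord <- order(sy, sx)
  c(dx = unname(sx[ord[1]]), dy = unname(sy[ord[1]]))
}

#' Quantify cell movement across an image stack
#'
#' Applies [cross_correlate_pair()] to every consecutive frame pair of the
#' stack, restricted to a rectangular region of interest (typically one cell).
#'
#' @param stack An [image_stack()] with at least 2 frames.
#' @param roi Rectangle `c(x0, y0, w, h)` in 0-based pixel coordinates, or
#'   `NULL` for the full frame.
#' @param mean_subtract Passed to [cross_correlate_pair()].
#' @return An object of class `movement_trace`: a list with `trace`
#'   (data frame `pair_index`, `dx_px`, `dy_px`), `roi`, `n_pairs`.
#' @export
quantify_movement <- function(stack, roi = NULL, mean_subtract = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  if (nf < 2L) {
    stop("movement quantification needs >= 2 frames, got ", nf, call. = FALSE)
  }
  fh <- nrow(stack$frames[[1]]); fw <- ncol(stack$frames[[1]])
  if (is.null(roi)) roi <- c(0L, 0L, fw, fh)
  x0 <- roi[1]; y0 <- roi[2]; rw <- roi[3]; rh <- roi[4]
  if (x0 < 0 || y0 < 0 || x0 + rw > fw || y0 + rh > fh || rw < 2 || rh < 2) {
    stop(sprintf("ROI (%d,%d,%d,%d) outside frame bounds %d x %d px",
                 x0, y0, rw, rh, fw, fh), call. = FALSE)
  }
  ri <- (y0 + 1L):(y0 + rh); ci <- (x0 + 1L):(x0 + rw)
  crop <- lapply(stack$frames, function(f) f[ri, ci, drop = FALSE])
  res <- t(vapply(seq_len(nf - 1L), function(k) {
    cross_correlate_pair(crop[[k]], crop[[k + 1L]], mean_subtract)
  }, numeric(2)))
  structure(
    list(trace = data.frame(pair_index = seq_len(nf - 1L),
                            dx_px = res[, 1], dy_px = res[, 2]),
         roi = c(x0 = x0, y0 = y0, w = rw, h = rh),
         n_pairs = nf - 1L),
    class = "movement_trace")
}

#' @export
print.movement_trace <- function(x, ...) {
  s <- movement_summary(x)
  cat(sprintf(
    "<movement_trace> %d frame pairs; max |dx| %g px, max |dy| %g px, %.0f%% pairs static\n",
    x$n_pairs, s$max_abs_dx, s$max_abs_dy, 100 * s$zero_fraction))
  invisible(x)
}

#' Summarize a movement trace
#'
#' @param trace A `movement_trace` from [quantify_movement()], or a data frame
#'   with `dx_px`, `dy_px`.
#' @return A list with `max_abs_dx`, `max_abs_dy`, `zero_fraction` (fraction
#'   of frame pairs with zero shift on both axes) and the per-pair `trace`.
#' @export
movement_summary <- function(trace) {
  df <- if (inherits(trace, "movement_trace")) trace$trace else trace
  stopifnot(is.data.frame(df), nrow(df) >= 1)
  list(max_abs_dx = max(abs(df$dx_px)),
       max_abs_dy = max(abs(df$dy_px)),
       zero_fraction = mean(df$dx_px == 0 & df$dy_px == 0),
       trace = df)
}
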