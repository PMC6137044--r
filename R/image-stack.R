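#' Image stack container
#'
#' An ordered set of 2D grayscale frames with acquisition metadata. The
#' coordinate convention used throughout the package: `x` runs along matrix
#' columns, `y` along matrix rows, and the origin is the *center* of pixel
#' (0, 0). Physical coordinates are micrometers; pixels appear only inside
#' image-processing internals.
#'
#' @param frames List of numeric matrices, all of identical dimensions, with
#'   non-negative intensities.
#' @param pixel_size_nm Physical pixel size in nanometers (default 80, the
#'   EMCCD pixel size of the reference TIRF setup).
#' @param frame_interval_s Time between consecutive frames in seconds.
#' @return An object of class `image_stack`.
#' @examples
#' s <- image_stack(list(matrix(0, 8, 8), matrix(1, 8, 8)),
#'                  pixel_size_nm = 80, frame_interval_s = 0.1)
#' dim(s$frames[[1]])
#' @export
image_stack <- function(frames, pixel_size_nm = 80, frame_interval_s = 0.1) {
  if (!is.list(frames) || length(frames) < 1L) {
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stop("every frame must be a numeric matrix", call. = FALSE)
  }
  d0 <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d0), logical(1))
  if (!all(same)) {
    stop("all frames must share one shape; frame ",
         which(!same)[1], " differs", call. = FALSE)
  }
  stop_if_not_scalar_pos(pixel_size_nm, "pixel_size_nm")
  stop_if_not_scalar_pos(frame_interval_s, "frame_interval_s")
  structure(
    list(frames = frames,
         pixel_size_nm = pixel_size_nm,
         frame_interval_s = frame_interval_s),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<image_stack> %d frame(s), %d x %d px, pixel %.1f nm, interval %g s\n",
    length(x$frames), d[1], d[2], x$pixel_size_nm, x$frame_interval_s))
  invisible(x)
}

#' Number of frames in an image stack
#' @param stack An [image_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  length(stack$frames)
}

# pixel (0-based col/row index) -> micrometer coordinate of the pixel center
px_to_um <- function(px, pixel_size_nm) px * pixel_size_nm / 1000

um_to_px <- function(um, pixel_size_nm) um * 1000 / pixel_size_nm
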