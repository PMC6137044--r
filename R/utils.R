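# Internal helpers shared across modules.

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific child seed from a global seed
#'
#' Deterministic counter scheme used by [run_pipeline()] and the acceptance
#' tooling: adding a new stage (a new counter value) never perturbs the random
#' stream of existing stages. Results stay below 2^31 so they are valid R seeds.
#'
#' @param seed Integer global seed.
#' @param counter Non-negative integer stage counter.
#' @return An integer seed.
#' @export
child_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), is.numeric(counter), counter >= 0)
  as.integer((((abs(seed) %% 1000003) * 2048) + (counter %% 2048)) %% 2147483647L)
}

stop_if_not_scalar_pos <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (allow_zero) x >= 0 else x > 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single %s number, got: %s", name,
                 if (allow_zero) "non-negative" else "positive",
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Circularly roll a matrix: content moves `dx` columns right and `dy` rows down.
roll_matrix <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  ri <- ((seq_len(h) - 1L - dy) %% h) + 1L
  ci <- ((seq_len(w) - 1L - dx) %% w) + 1L
  m[ri, ci, drop = FALSE]
}

# Shift with zero padding instead of wrap-around.
shift_matrix_zero <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  keep_r <- src_r >= 1L & src_r <= h
  keep_c <- src_c >= 1L & src_c <= w
  out[keep_r, keep_c] <- m[src_r[keep_r], src_c[keep_c], drop = FALSE]
  out
}
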