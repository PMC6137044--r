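# Brute-force oracles and small fixture builders shared across tests.
# Each oracle is deliberately written as a direct double loop or exhaustive
# search, independent of the implementation path it checks.

# Circular roll of a matrix: content moves +dx columns, +dy rows (same
# convention as the package, re-derived independently via modular indexing).
oracle_roll <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[((i - 1 + dy) %% h) + 1, ((j - 1 + dx) %% w) + 1] <- m[i, j]
    }
  }
  out
}

# Exhaustive spatial-domain circular cross-correlation: returns the signed
# integer shift maximizing sum(roll(a, shift) * b), ties by smallest (dy, dx).
oracle_shift <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  h <- nrow(a); w <- ncol(a)
  sx_all <- integer(0); sy_all <- integer(0); v_all <- numeric(0)
  for (sy0 in 0:(h - 1)) {
    for (sx0 in 0:(w - 1)) {
      v_all <- c(v_all, sum(oracle_roll(a, sx0, sy0) * b))
      sy_all <- c(sy_all, if (sy0 > h / 2) sy0 - h else sy0)
      sx_all <- c(sx_all, if (sx0 > w / 2) sx0 - w else sx0)
    }
  }
  peak <- max(v_all)
  keep <- v_all >= peak - 1e-8 * max(abs(peak), 1)
  ord <- order(sy_all[keep], sx_all[keep])
  c(dx = sx_all[keep][ord[1]], dy = sy_all[keep][ord[1]])
}

# Double-loop discoidal filter with the same mirror boundary rule, computed
# per output pixel from scratch.
oracle_discoidal <- function(img, r_in, r_out) {
  h <- nrow(img); w <- ncol(img)
  mirror <- function(i, n) {
    if (i < 0) i <- -1 - i
    if (i >= n) i <- 2 * n - 1 - i
    i
  }
  out <- matrix(0, h, w)
  for (i in 0:(h - 1)) {
    for (j in 0:(w - 1)) {
      inner <- c(); ann <- c()
      for (di in -r_out:r_out) {
        for (dj in -r_out:r_out) {
          d <- sqrt(di^2 + dj^2)
          if (d > r_out) next
          v <- img[mirror(i + di, h) + 1, mirror(j + dj, w) + 1]
          if (d <= r_in) inner <- c(inner, v) else ann <- c(ann, v)
        }
      }
      out[i + 1, j + 1] <- mean(inner) - mean(ann)
    }
  }
  out
}

# Exhaustive nearest-centroid search, one molecule at a time.
oracle_nearest <- function(molecules, centroids) {
  t(vapply(seq_len(nrow(molecules)), function(i) {
    d <- sqrt((centroids$x_um - molecules$x_um[i])^2 +
                (centroids$y_um - molecules$y_um[i])^2)
    k <- which(d == min(d))[1]
    c(distance_um = d[k], centroid_index = k)
  }, numeric(2)))
}

# A well-separated grid of particle start positions inside a margin, used by
# the rendered-movie pipeline test so linking identity is unambiguous.
grid_origins <- function(n, field_um, margin_um) {
  k <- ceiling(sqrt(n))
  gx <- seq(margin_um, field_um - margin_um, length.out = k)
  gy <- seq(margin_um, field_um - margin_um, length.out = k)
  g <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  g
}
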