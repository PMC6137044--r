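# Nearest-eisosome distance mapping.
#
# Eisosome-marker blink localizations are condensed to one centroid per
# eisosome; the distance from each protein localization to the centroid of
# the nearest eisosome characterizes protein distribution relative to the
# membrane microdomains.

#' Condense blink localizations into eisosome centroids
#'
#' Single-linkage clustering: localizations closer than `radius_um` (by chains
#' of such links) form one group; groups with at least `min_points` members
#' yield their mean position as a centroid, smaller groups are discarded as
#' stray blinks.
#'
#' @param localizations Localization data frame (`x_um`, `y_um`); may be empty.
#' @param radius_um Linkage radius, um (> 0).
#' @param min_points Minimum localizations per retained cluster (default 1).
#' @param source Free-text provenance label (e.g. `"Sur7-YPet"`).
#' @return A data frame of centroids (`x_um`, `y_um`, `n_points`) with
#'   attribute `source`.
#' @export
cluster_centroids <- function(localizations, radius_um, min_points = 1L,
                              source = "") {
  stopifnot(is.data.frame(localizations))
  stop_if_not_scalar_pos(radius_um, "radius_um")
  empty <- structure(
    data.frame(x_um = numeric(0), y_um = numeric(0), n_points = integer(0)),
    source = source)
  n <- nrow(localizations)
  if (!n) return(empty)
  groups <- if (n == 1L) 1L else {
    stats::cutree(stats::hclust(stats::dist(
      cbind(localizations$x_um, localizations$y_um)), method = "single"),
      h = radius_um)
  }
  cent <- lapply(split(seq_len(n), groups), function(idx) {
    if (length(idx) < min_points) return(NULL)
    data.frame(x_um = mean(localizations$x_um[idx]),
               y_um = mean(localizations$y_um[idx]),
               n_points = length(idx))
  })
  cent <- cent[!vapply(cent, is.null, logical(1))]
  if (!length(cent)) return(empty)
  out <- do.call(rbind, cent)
  rownames(out) <- NULL
  structure(out, source = source)
}

#' Distance from each molecule to the nearest centroid
#'
#' Minimum Euclidean distance over all centroids, with the index of the
#' nearest centroid; ties resolved to the lowest centroid index.
#'
#' @param molecules Localization data frame (`x_um`, `y_um`).
#' @param centroids Centroid data frame from [cluster_centroids()] (non-empty).
#' @return Data frame `molecule_id`, `distance_um`, `centroid_index`.
#' @export
nearest_centroid_distances <- function(molecules, centroids) {
  stopifnot(is.data.frame(molecules), is.data.frame(centroids))
  if (!nrow(centroids)) {
    stop("centroid set is empty: no distances can be computed", call. = FALSE)
  }
  if (!nrow(molecules)) {
    return(data.frame(molecule_id = integer(0), distance_um = numeric(0),
                      centroid_index = integer(0)))
  }
  dx <- outer(molecules$x_um, centroids$x_um, "-")
  dy <- outer(molecules$y_um, centroids$y_um, "-")
  d <- sqrt(dx^2 + dy^2)
  nearest <- apply(d, 1L, which.min)  # which.min ties -> lowest index
  data.frame(molecule_id = seq_len(nrow(molecules)),
             distance_um = d[cbind(seq_len(nrow(molecules)), nearest)],
             centroid_index = nearest)
}

#' Histogram of nearest-centroid distances
#'
#' Left-closed, right-open bins of width `bin_width_um` starting at 0. When
#' `labels` are supplied (e.g. mobile/immobile), one histogram per label is
#' returned and all share the same bin edges so panels stay comparable.
#'
#' @param distances_um Non-negative distances, um.
#' @param bin_width_um Bin width, um (default 0.05: no finer binning is
#'   meaningful below the 20-50 nm localization accuracy).
#' @param labels Optional per-distance population labels.
#' @param max_um Upper edge of the last bin; defaults to the smallest
#'   multiple of the bin width covering the data (1 um for empty input).
#' @return A `distance_distribution` (list with `distances_um`,
#'   `bin_edges_um`, `counts`, `label`), or a named list of them when
#'   `labels` is given.
#' @export
distance_histogram <- function(distances_um, bin_width_um = 0.05,
                               labels = NULL, max_um = NULL) {
  stop_if_not_scalar_pos(bin_width_um, "bin_width_um")
  if (any(distances_um < 0)) stop("distances must be >= 0", call. = FALSE)
  if (is.null(max_um)) {
    max_um <- if (length(distances_um)) {
      bin_width_um * max(1, ceiling(max(distances_um) / bin_width_um + 1e-12))
    } else 1
  }
  edges <- seq(0, max_um, by = bin_width_um)
  if (edges[length(edges)] < max_um) edges <- c(edges, max_um)
  one <- function(d, label) {
    bins <- findInterval(d, edges, rightmost.closed = FALSE)
    bins[bins > length(edges) - 1L] <- length(edges) - 1L
    counts <- tabulate(bins, nbins = length(edges) - 1L)
    structure(list(distances_um = d, bin_edges_um = edges, counts = counts,
                   label = label),
              class = "distance_distribution")
  }
  if (is.null(labels)) return(one(distances_um, NA_character_))
  stopifnot(length(labels) == length(distances_um))
  out <- lapply(split(distances_um, labels), function(d) one(d, NA_character_))
  for (lbl in names(out)) out[[lbl]]$label <- lbl
  out
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf(
    "<distance_distribution>%s n = %d, %d bins of %.3g um, range [0, %.3g] um\n",
    if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
    length(x$distances_um), length(x$counts), diff(x$bin_edges_um[1:2]),
    max(x$bin_edges_um)))
  invisible(x)
}
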