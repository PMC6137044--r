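# CSV interchange for localizations, trajectories, centroids and FRAP traces.
# Documented headers: trajectory_id, frame, x_um, y_um, intensity (localizations
# and trajectories); x_um, y_um (centroids); time_s, intensity (FRAP traces).
# Coordinates are written with 6 decimal places (micrometer resolution 1e-6,
# i.e. 1 pm — far below any localization accuracy).

LOC_COLUMNS <- c("trajectory_id", "frame", "x_um", "y_um", "intensity")

#' Read a localization table
#'
#' Expected columns: `frame`, `x_um`, `y_um`, and optionally `trajectory_id`
#' and `intensity`. Frame indices are 0-based. Duplicate
#' `(trajectory_id, frame)` pairs violate the trajectory invariant and are
#' rejected.
#'
#' @param path CSV file path.
#' @return A `data.frame` with columns `trajectory_id`, `frame`, `x_um`,
#'   `y_um`, `intensity` (missing optional columns filled with `NA`).
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("frame", "x_um", "y_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  if (!"trajectory_id" %in% names(df)) df$trajectory_id <- NA_integer_
  if (!"intensity" %in% names(df)) df$intensity <- NA_real_
  df <- df[, LOC_COLUMNS]
  if (nrow(df)) {
    if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um))) {
      stop("non-finite coordinates in ", path, call. = FALSE)
    }
    with_id <- !is.na(df$trajectory_id)
    if (any(with_id)) {
      key <- paste(df$trajectory_id[with_id], df$frame[with_id])
      if (anyDuplicated(key)) {
        stop("duplicate (trajectory_id, frame) rows in ", path,
             ": a trajectory visits each frame at most once", call. = FALSE)
      }
    }
  }
  df
}

#' Write a localization table
#'
#' @param locs Data frame with at least `frame`, `x_um`, `y_um`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  stopifnot(is.data.frame(locs))
  df <- locs
  if (!"trajectory_id" %in% names(df)) df$trajectory_id <- NA_integer_
  if (!"intensity" %in% names(df)) df$intensity <- NA_real_
  df <- df[, LOC_COLUMNS]
  for (col in c("x_um", "y_um", "intensity")) df[[col]] <- round(df[[col]], 6)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a FRAP intensity trace
#'
#' Trace CSVs have columns `time_s` (0 at the bleach, negative before it) and
#' `intensity`. `n_pre` and `roi_radius_um` are recovered from the sign of
#' `time_s` and a JSON sidecar written by [write_frap_trace()], if present.
#'
#' @param path CSV file path.
#' @param roi_radius_um Bleach-spot radius in micrometers; overrides any
#'   sidecar value.
#' @return A [frap_trace()].
#' @export
read_frap_trace <- function(path, roi_radius_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("time_s", "intensity"), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  side <- paste0(path, ".json")
  radius <- roi_radius_um
  if (is.null(radius) && file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    radius <- meta$roi_radius_um
  }
  if (is.null(radius)) radius <- 0.5
  frap_trace(df$time_s, df$intensity, n_pre = sum(df$time_s < 0),
             roi_radius_um = radius)
}

#' @rdname read_frap_trace
#' @param trace A [frap_trace()].
#' @export
write_frap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  utils::write.csv(
    data.frame(time_s = round(trace$time_s, 6),
               intensity = round(trace$intensity, 6)),
    path, row.names = FALSE)
  jsonlite::write_json(
    list(n_pre = trace$n_pre, roi_radius_um = trace$roi_radius_um),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate a trajectory table
#'
#' Checks the trajectory invariants: strictly increasing frame indices within
#' each trajectory and finite coordinates.
#'
#' @param trajs Data frame with `trajectory_id`, `frame`, `x_um`, `y_um`.
#' @return `trajs`, invisibly; errors on violation.
#' @export
validate_trajectories <- function(trajs) {
  stopifnot(is.data.frame(trajs))
  required <- c("trajectory_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(required, names(trajs))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(trajs$x_um)) || any(!is.finite(trajs$y_um))) {
    stop("non-finite coordinates in trajectory table", call. = FALSE)
  }
  for (id in unique(trajs$trajectory_id)) {
    fr <- trajs$frame[trajs$trajectory_id == id]
    if (any(diff(sort(fr)) == 0)) {
      stop("trajectory ", id, " has duplicate frame indices", call. = FALSE)
    }
  }
  invisible(trajs)
}
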