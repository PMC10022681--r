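#' Construct a locus trajectory
#'
#' A `locus_trajectory` is the atom of all downstream analyses: the
#' time-stamped 2D positions (in micrometres) of one fluorescently labeled
#' genomic locus in one cell, sampled at a constant frame interval.
#'
#' Frames must be complete: the constructor rejects trajectories whose time
#' stamps are not strictly increasing with constant spacing (tolerance
#' 1e-9 s). Missing frames are rejected rather than interpolated, because
#' interpolation would bias the step-size regression used for spring-constant
#' estimation.
#'
#' @param cell_id Cell identifier.
#' @param locus_id Locus identifier (e.g. `"PR1"`, `"T2"`).
#' @param times Numeric vector of acquisition times in seconds, one per frame.
#' @param x,y Numeric vectors of positions in micrometres.
#' @param condition Optional free-form condition label (cell-cycle stage,
#'   drug treatment, ...). Carried as grouping metadata, never a code path.
#' @param frames Optional integer frame indices (0-based). Defaults to
#'   `0:(n-1)`.
#' @param meta Optional named list of per-trajectory metadata (e.g.
#'   `focus_count`, `nucleus_class`, `genomic_coord_mb`) used by
#'   [filter_ensemble()] and the tethering analysis.
#' @return An object of class `locus_trajectory` with fields `cell_id`,
#'   `locus_id`, `condition`, `frame_interval` (s), `frames`, `times` and the
#'   n x 2 `positions` matrix (columns `x_um`, `y_um`).
#' @seealso [trajectory_ensemble()], [read_trajectories()]
#' @export
locus_trajectory <- function(cell_id, locus_id, times, x, y,
                             condition = NA_character_, frames = NULL,
                             meta = list()) {
  times <- as.numeric(times)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(times)
  if (length(x) != n || length(y) != n) {
    stop("times, x and y must have equal length", call. = FALSE)
  }
  if (n < 2L) {
    stop(sprintf("trajectory (cell %s, locus %s) needs at least 2 positions",
                 cell_id, locus_id), call. = FALSE)
  }
  if (!all(is.finite(times)) || !all(is.finite(x)) || !all(is.finite(y))) {
    stop(sprintf("non-finite coordinates in trajectory (cell %s, locus %s)",
                 cell_id, locus_id), call. = FALSE)
  }
  dts <- diff(times)
  if (any(dts <= 0)) {
    stop(sprintf("times must be strictly increasing (cell %s, locus %s)",
                 cell_id, locus_id), call. = FALSE)
  }
  dt <- dts[[1L]]
  if (any(abs(dts - dt) > 1e-9)) {
    stop(sprintf(
      "non-uniform frame spacing in trajectory (cell %s, locus %s); missing frames are not interpolated",
      cell_id, locus_id), call. = FALSE)
  }
  if (is.null(frames)) {
    frames <- seq_len(n) - 1L
  } else {
    frames <- as.integer(frames)
    if (length(frames) != n || any(diff(frames) <= 0L)) {
      stop(sprintf("invalid frame indices (cell %s, locus %s)",
                   cell_id, locus_id), call. = FALSE)
    }
  }
  structure(
    list(cell_id = as.character(cell_id),
         locus_id = as.character(locus_id),
         condition = as.character(condition),
         frame_interval = dt,
         frames = frames,
         times = times,
         positions = cbind(x_um = x, y_um = y),
         meta = meta),
    class = "locus_trajectory")
}

#' Number of frames in a trajectory
#' @param traj A [locus_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "locus_trajectory"))
  nrow(traj$positions)
}

#' @export
print.locus_trajectory <- function(x, ...) {
  cat(sprintf("<locus_trajectory> cell %s, locus %s (%s): %d frames, dt = %g s\n",
              x$cell_id, x$locus_id,
              if (is.na(x$condition)) "no condition" else x$condition,
              nrow(x$positions), x$frame_interval))
  invisible(x)
}

#' Bundle locus trajectories into an ensemble
#'
#' @param trajectories List of [locus_trajectory()] objects.
#' @return An object of class `trajectory_ensemble` (a list of trajectories).
#' @export
trajectory_ensemble <- function(trajectories = list()) {
  ok <- vapply(trajectories, inherits, logical(1), "locus_trajectory")
  if (!all(ok)) {
    stop("all members must be locus_trajectory objects", call. = FALSE)
  }
  structure(unname(trajectories), class = c("trajectory_ensemble", "list"))
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d trajectories", length(x)))
  if (length(x)) {
    cat(sprintf(" (%d loci, %d cells)",
                length(unique(vapply(x, `[[`, "", "locus_id"))),
                length(unique(vapply(x, `[[`, "", "cell_id")))))
  }
  cat("\n")
  invisible(x)
}

#' @export
`[.trajectory_ensemble` <- function(x, i) {
  trajectory_ensemble(unclass(x)[i])
}

#' Flatten an ensemble to the tabular trajectory schema
#'
#' @param x A [trajectory_ensemble()].
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return A data.frame with columns `cell_id`, `locus_id`, `condition`,
#'   `frame`, `t_s`, `x_um`, `y_um`.
#' @export
as.data.frame.trajectory_ensemble <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  if (!length(x)) {
    return(data.frame(cell_id = character(), locus_id = character(),
                      condition = character(), frame = integer(),
                      t_s = numeric(), x_um = numeric(), y_um = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- lapply(x, function(tr) {
    data.frame(cell_id = tr$cell_id, locus_id = tr$locus_id,
               condition = tr$condition, frame = tr$frames,
               t_s = tr$times, x_um = tr$positions[, 1L],
               y_um = tr$positions[, 2L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Group an ensemble by a metadata key
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param by `"locus_id"`, `"condition"` or `"cell_id"`.
#' @return Named list of `trajectory_ensemble` objects.
#' @export
split_ensemble <- function(ensemble, by = c("locus_id", "condition", "cell_id")) {
  by <- match.arg(by)
  keys <- vapply(ensemble, `[[`, "", by)
  lapply(split(seq_along(ensemble), keys), function(i) ensemble[i])
}
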