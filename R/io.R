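# Tabular trajectory and nuclear-geometry readers/writers.
# Dialect: comma-separated, UTF-8, "." decimal; a tab-separated file with the
# same header is accepted transparently.

required_cols <- c("cell_id", "locus_id", "frame", "t_s", "x_um", "y_um")

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read locus trajectories from a tabular text file
#'
#' Expects header columns `cell_id,locus_id,frame,t_s,x_um,y_um` with an
#' optional `condition` column; either comma- or tab-separated. One
#' trajectory is built per `(cell_id, locus_id)` group, rows sorted by frame.
#' Validation failures (duplicate frames, missing frames, non-uniform time
#' spacing) are reported with the offending cell/locus and row numbers.
#'
#' @param path File path.
#' @param sep Field separator; sniffed from the header line by default.
#' @return A [trajectory_ensemble()].
#' @export
read_trajectories <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop(sprintf("trajectory table %s is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!"condition" %in% names(df)) df$condition <- NA_character_
  if (nrow(df) == 0L) return(trajectory_ensemble())

  key <- paste(df$cell_id, df$locus_id, df$frame, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    rows <- which(dup) + 1L  # +1 for the header line
    stop(sprintf("duplicate (cell_id, locus_id, frame) rows at file line(s) %s: %s",
                 paste(rows, collapse = ", "),
                 paste(unique(sub("\r", "/", sub("\r[^\r]*$", "", key[dup]))),
                       collapse = "; ")),
         call. = FALSE)
  }

  groups <- split(df, list(df$cell_id, df$locus_id), drop = TRUE)
  trajs <- lapply(groups, function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    cond <- unique(g$condition)
    if (length(cond) > 1L) {
      stop(sprintf("inconsistent condition labels for cell %s, locus %s",
                   g$cell_id[[1L]], g$locus_id[[1L]]), call. = FALSE)
    }
    locus_trajectory(g$cell_id[[1L]], g$locus_id[[1L]],
                     times = g$t_s, x = g$x_um, y = g$y_um,
                     condition = cond, frames = g$frame)
  })
  trajectory_ensemble(trajs)
}

#' Write an ensemble to the tabular trajectory schema
#'
#' Values are written with 17 significant digits so that
#' `read_trajectories(write_trajectories(e, f))` reproduces `e` to full
#' double precision. An empty ensemble yields a header-only file.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ensemble, path, sep = ",") {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  df <- as.data.frame(ensemble)
  out <- data.frame(cell_id = df$cell_id, locus_id = df$locus_id,
                    condition = df$condition, frame = df$frame,
                    t_s = sprintf("%.17g", df$t_s),
                    x_um = sprintf("%.17g", df$x_um),
                    y_um = sprintf("%.17g", df$y_um),
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("cannot write %s: %s", path,
                                conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Calibrate a trajectory for nuclear motion
#'
#' Subtracts the nuclear centroid from every locus position, eliminating
#' whole-cell movement so that only motion relative to the nucleus remains.
#' With `reference = "per_frame"` (default) the matching per-frame centroid
#' is subtracted; with `"first_frame"` a single reference centroid (the first
#' available frame) is used, which removes the static offset but no drift.
#'
#' @param traj A [locus_trajectory()].
#' @param geometry A [nucleus_geometry()] whose centroid series covers every
#'   frame of `traj`.
#' @param reference `"per_frame"` or `"first_frame"`.
#' @return The calibrated `locus_trajectory`; times and frame interval are
#'   unchanged.
#' @export
correct_nuclear_motion <- function(traj, geometry,
                                   reference = c("per_frame", "first_frame")) {
  stopifnot(inherits(traj, "locus_trajectory"),
            inherits(geometry, "nucleus_geometry"))
  reference <- match.arg(reference)
  cen <- centroid_at_frames(geometry, traj$frames)
  if (reference == "first_frame") {
    cen <- matrix(cen[1L, ], nrow = nrow(cen), ncol = 2L, byrow = TRUE)
  }
  out <- traj
  out$positions <- traj$positions - cen
  colnames(out$positions) <- c("x_um", "y_um")
  out
}

# Resolve the centroid series of a geometry at given frame indices.
centroid_at_frames <- function(geometry, frames) {
  cen <- geometry$centroid_series
  if (nrow(cen) == 1L) {
    return(matrix(cen[1L, ], nrow = length(frames), ncol = 2L, byrow = TRUE))
  }
  idx <- match(frames, geometry$centroid_frames)
  if (anyNA(idx)) {
    stop(sprintf("no nuclear centroid for frame(s) %s of cell %s",
                 paste(frames[is.na(idx)], collapse = ", "),
                 geometry$cell_id), call. = FALSE)
  }
  cen[idx, , drop = FALSE]
}

#' Filter an ensemble by the study's inclusion rules
#'
#' Applies the trajectory-level inclusion criteria used for live-cell locus
#' tracking: a minimum trajectory length, exclusion of cells with too many
#' labeled foci (late S/G2/M, after replication) and exclusion of flagged
#' nucleus classes (e.g. small early-G1 nuclei). Metadata flags are read from
#' each trajectory's `meta` list (`focus_count`, `nucleus_class`); members
#' without a flag pass that rule.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param min_length Minimum number of frames, or `NULL` to skip.
#' @param max_focus_count Maximum allowed `meta$focus_count`; e.g. 3 removes
#'   cells with four or more foci. `NULL` to skip.
#' @param exclude_nucleus_class Character vector of `meta$nucleus_class`
#'   values to remove (e.g. `"small"`).
#' @return A list with the surviving `ensemble` and a named integer `report`
#'   counting removals per rule (`short`, `focus_count`, `nucleus_class`).
#' @export
filter_ensemble <- function(ensemble, min_length = NULL,
                            max_focus_count = NULL,
                            exclude_nucleus_class = character()) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  report <- c(short = 0L, focus_count = 0L, nucleus_class = 0L)
  keep <- logical(length(ensemble))
  for (i in seq_along(ensemble)) {
    tr <- ensemble[[i]]
    if (!is.null(min_length) && n_frames(tr) < min_length) {
      report[["short"]] <- report[["short"]] + 1L
      next
    }
    fc <- tr$meta$focus_count
    if (!is.null(max_focus_count) && !is.null(fc) && fc > max_focus_count) {
      report[["focus_count"]] <- report[["focus_count"]] + 1L
      next
    }
    nc <- tr$meta$nucleus_class
    if (length(exclude_nucleus_class) && !is.null(nc) &&
        nc %in% exclude_nucleus_class) {
      report[["nucleus_class"]] <- report[["nucleus_class"]] + 1L
      next
    }
    keep[i] <- TRUE
  }
  list(ensemble = ensemble[keep], report = report)
}

#' Read nuclear geometry records
#'
#' Two on-disk representations are supported:
#' * CSV: a per-frame centroid table (`cell_id,frame,cx_um,cy_um`; a single
#'   row per cell means a static centroid) plus an optional polygon vertex
#'   table (`cell_id,vertex_index,x_um,y_um`).
#' * JSON: an array of records
#'   `{"cell_id": ..., "centroid": [cx, cy], "ellipse": {"cx":..,"cy":..,"a_um":..,"b_um":..,"theta_rad":..}}`
#'   (or `"polygon": [[x,y], ...]` in place of `"ellipse"`).
#'
#' @param centroid_file CSV centroid table (CSV mode).
#' @param polygon_file Optional CSV polygon vertex table (CSV mode).
#' @param json_file JSON record file (JSON mode).
#' @return Named list of [nucleus_geometry()] objects, keyed by `cell_id`.
#' @export
read_nucleus_geometry <- function(centroid_file = NULL, polygon_file = NULL,
                                  json_file = NULL) {
  if (!is.null(json_file)) {
    recs <- jsonlite::fromJSON(json_file, simplifyDataFrame = FALSE)
    out <- lapply(recs, function(r) {
      boundary <- if (!is.null(r$ellipse)) {
        e <- r$ellipse
        ellipse_boundary(center = c(e$cx, e$cy), a = e$a_um, b = e$b_um,
                         theta = if (is.null(e$theta_rad)) 0 else e$theta_rad)
      } else {
        polygon_boundary(do.call(rbind, lapply(r$polygon, as.numeric)))
      }
      cen <- matrix(as.numeric(unlist(r$centroid)), ncol = 2L, byrow = TRUE)
      nucleus_geometry(r$cell_id, centroid = cen, boundary = boundary)
    })
    names(out) <- vapply(out, `[[`, "", "cell_id")
    return(out)
  }
  if (is.null(centroid_file)) {
    stop("provide either json_file or centroid_file", call. = FALSE)
  }
  cen <- utils::read.csv(centroid_file, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "cx_um", "cy_um")
  if (!all(need %in% names(cen))) {
    stop(sprintf("centroid table needs columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  polys <- NULL
  if (!is.null(polygon_file)) {
    polys <- utils::read.csv(polygon_file, stringsAsFactors = FALSE)
    needp <- c("cell_id", "vertex_index", "x_um", "y_um")
    if (!all(needp %in% names(polys))) {
      stop(sprintf("polygon table needs columns %s", paste(needp, collapse = ", ")),
           call. = FALSE)
    }
  }
  out <- lapply(split(cen, cen$cell_id), function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    boundary <- NULL
    if (!is.null(polys)) {
      pg <- polys[polys$cell_id == g$cell_id[[1L]], , drop = FALSE]
      if (nrow(pg)) {
        pg <- pg[order(pg$vertex_index), , drop = FALSE]
        boundary <- polygon_boundary(cbind(pg$x_um, pg$y_um))
      }
    }
    nucleus_geometry(g$cell_id[[1L]],
                     centroid = cbind(g$cx_um, g$cy_um),
                     boundary = boundary,
                     centroid_frames = g$frame)
  })
  names(out) <- vapply(out, `[[`, "", "cell_id")
  out
}
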