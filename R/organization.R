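# Locus-pair distances, compaction exponents, variation decomposition,
# and nuclear radiality (normalized radial distance, NRD).

#' Locus-pair distance series
#'
#' @param cell_id Cell identifier.
#' @param pair Pair label (e.g. `"LH/LA"`).
#' @param genomic_distance Genomic separation s of the pair, Mb.
#' @param distances Per-frame spatial distances R(t), um (>= 0).
#' @return Object of class `locus_pair_series`.
#' @export
locus_pair_series <- function(cell_id, pair, genomic_distance, distances) {
  distances <- as.numeric(distances)
  stopifnot(all(is.finite(distances)), all(distances >= 0),
            genomic_distance > 0)
  structure(list(cell_id = as.character(cell_id), pair = as.character(pair),
                 genomic_distance = genomic_distance, distances = distances),
            class = "locus_pair_series")
}

#' Per-frame distance between two loci in the same cell
#'
#' @param trajA,trajB [locus_trajectory()] objects from the same cell with
#'   identical frames.
#' @param genomic_distance Genomic separation of the pair, Mb; taken from
#'   `meta$genomic_coord_mb` of the two trajectories when `NULL`.
#' @return A [locus_pair_series()].
#' @export
compute_pair_distance_series <- function(trajA, trajB,
                                         genomic_distance = NULL) {
  stopifnot(inherits(trajA, "locus_trajectory"),
            inherits(trajB, "locus_trajectory"))
  if (trajA$cell_id != trajB$cell_id) {
    stop("loci must come from the same cell", call. = FALSE)
  }
  if (n_frames(trajA) != n_frames(trajB) ||
      any(trajA$frames != trajB$frames)) {
    stop(sprintf("frame mismatch between loci %s and %s in cell %s",
                 trajA$locus_id, trajB$locus_id, trajA$cell_id),
         call. = FALSE)
  }
  if (is.null(genomic_distance)) {
    ca <- trajA$meta$genomic_coord_mb
    cb <- trajB$meta$genomic_coord_mb
    if (is.null(ca) || is.null(cb)) {
      stop("genomic_distance not given and not present in trajectory meta",
           call. = FALSE)
    }
    genomic_distance <- abs(ca - cb)
  }
  d <- trajA$positions - trajB$positions
  locus_pair_series(trajA$cell_id,
                    paste(trajA$locus_id, trajB$locus_id, sep = "/"),
                    genomic_distance, sqrt(rowSums(d * d)))
}

#' Population-averaged locus-pair distance
#'
#' The per-cell time average `<R(t)>_t` over the first `n_frames_avg` frames
#' (default 30), followed by the cell-population average:
#' `<R> = <<R>_t>_cell`.
#'
#' @param series_list List of [locus_pair_series()] for one pair.
#' @param n_frames_avg Averaging window in frames.
#' @return A list: `per_cell` (data.frame `cell_id`, `mean_r_um`), `mean_r`
#'   (um), `sd_r` (s.d. across cells), `n_cells`.
#' @export
mean_pair_distance <- function(series_list, n_frames_avg = 30L) {
  stopifnot(length(series_list) >= 1L)
  per <- vapply(series_list, function(s) {
    stopifnot(inherits(s, "locus_pair_series"))
    if (length(s$distances) < n_frames_avg) {
      stop(sprintf("cell %s has fewer than %d frames", s$cell_id,
                   n_frames_avg), call. = FALSE)
    }
    mean(s$distances[seq_len(n_frames_avg)])
  }, numeric(1))
  list(per_cell = data.frame(
         cell_id = vapply(series_list, `[[`, "", "cell_id"),
         mean_r_um = per, stringsAsFactors = FALSE),
       mean_r = mean(per),
       sd_r = if (length(per) > 1L) stats::sd(per) else NA_real_,
       n_cells = length(per))
}

#' Fit the compaction exponent
#'
#' Log-log ordinary least squares of the population-mean spatial distance
#' `<R>` on genomic distance `s`: `<R> = prefactor * s^delta`. Smaller
#' `delta` means tighter packing. `spans` requests nested fits over subsets
#' of pairs with `s` up to each span limit (the way compaction is compared
#' across genomic scales).
#'
#' @param s Genomic distances, Mb (>= 2 distinct, positive).
#' @param r Matched mean spatial distances, um (positive).
#' @param spans Optional named numeric vector of span limits in Mb, e.g.
#'   `c("4.6Mb" = 4.7, "29Mb" = 30)`.
#' @return A `compaction_fit` list: `delta`, `prefactor`, `r_squared`,
#'   `points` (data.frame), and `span_fits` (list of `compaction_fit`, when
#'   `spans` given).
#' @export
fit_compaction <- function(s, r, spans = NULL) {
  stopifnot(length(s) == length(r))
  if (any(s <= 0) || any(r <= 0)) {
    stop("genomic and spatial distances must be positive", call. = FALSE)
  }
  if (length(unique(s)) < 2L) stop("need >= 2 distinct genomic distances",
                                   call. = FALSE)
  fit <- stats::lm(log(r) ~ log(s))
  out <- structure(list(delta = unname(stats::coef(fit)[[2L]]),
                        prefactor = exp(unname(stats::coef(fit)[[1L]])),
                        r_squared = rsq(log(r), stats::residuals(fit)),
                        points = data.frame(s_mb = s, mean_r_um = r),
                        span_fits = NULL),
                   class = "compaction_fit")
  if (!is.null(spans)) {
    out$span_fits <- lapply(spans, function(lim) {
      keep <- s <= lim
      if (length(unique(s[keep])) < 2L) return(NULL)
      fit_compaction(s[keep], r[keep])
    })
  }
  out
}

#' @export
print.compaction_fit <- function(x, ...) {
  cat(sprintf("<compaction_fit> <R> = %.3f * s^%.3f um (R^2 = %.3f, %d pairs)\n",
              x$prefactor, x$delta, x$r_squared, nrow(x$points)))
  if (!is.null(x$span_fits)) {
    for (nm in names(x$span_fits)) {
      f <- x$span_fits[[nm]]
      if (!is.null(f)) cat(sprintf("  span %s: delta = %.3f\n", nm, f$delta))
    }
  }
  invisible(x)
}

#' Decompose locus-pair distance variation
#'
#' Separates the two sources of spread in pair distances: cell-to-cell
#' variation (the spread of the per-cell time means `<R>_t` across cells)
#' and temporal variation (the pooled distribution of the absolute
#' deviations `deltaR(t) = |R(t) - <R>_t|` within cells). For additive
#' Gaussian jitter of s.d. `sigma_t`, `mean(deltaR)` converges to
#' `sigma_t * sqrt(2/pi)` (half-normal mean), which `implied_temporal_sd`
#' inverts.
#'
#' @param series_list List of [locus_pair_series()] for one pair/condition
#'   (>= 1 cell; cell-to-cell s.d. needs >= 2).
#' @return A list: `per_cell_means`, `cell_sd`, `temporal_deviations`
#'   (pooled), `mean_temporal_dev`, `implied_temporal_sd`, `n_cells`.
#' @export
decompose_variation <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  means <- vapply(series_list, function(s) mean(s$distances), numeric(1))
  devs <- unlist(lapply(series_list, function(s) {
    abs(s$distances - mean(s$distances))
  }))
  list(per_cell_means = means,
       cell_sd = if (length(means) > 1L) stats::sd(means) else NA_real_,
       temporal_deviations = devs,
       mean_temporal_dev = mean(devs),
       implied_temporal_sd = mean(devs) * sqrt(pi / 2),
       n_cells = length(means))
}

#' Normalized nuclear radial distance of a locus
#'
#' `NRD = d / rho`, where `d` is the distance from the nuclear centroid to
#' the locus and `rho` the distance from the centroid to the nuclear
#' boundary along the same ray. 0 marks the nuclear center, 1 the periphery.
#' Raw values in (1, 1.05] (segmentation jitter placing a locus marginally
#' outside) are clipped to 1 and flagged; values beyond 1.05 are an error.
#'
#' @param point Length-2 locus position, um.
#' @param geometry A [nucleus_geometry()] with a boundary.
#' @param frame Frame index selecting the centroid (default first available).
#' @return A list: `nrd` (clipped to \[0, 1\]), `raw`, `clipped`, `d_um`,
#'   `rho_um`.
#' @export
compute_nrd <- function(point, geometry, frame = NULL) {
  stopifnot(inherits(geometry, "nucleus_geometry"))
  if (is.null(geometry$boundary)) stop("geometry has no boundary", call. = FALSE)
  point <- as.numeric(point)
  cen <- if (is.null(frame)) {
    geometry$centroid_series[1L, ]
  } else {
    centroid_at_frames(geometry, frame)[1L, ]
  }
  v <- point - cen
  d <- sqrt(sum(v * v))
  if (d == 0) {
    return(list(nrd = 0, raw = 0, clipped = FALSE, d_um = 0,
                rho_um = NA_real_))
  }
  rho <- ray_boundary_distance(geometry$boundary, cen, v)
  raw <- d / rho
  if (raw > 1.05) {
    stop(sprintf("locus lies outside the nuclear boundary (raw NRD %.3f > 1.05)",
                 raw), call. = FALSE)
  }
  list(nrd = min(raw, 1), raw = raw, clipped = raw > 1, d_um = d,
       rho_um = rho)
}

#' Histogram and empirical CDF of NRD values
#'
#' @param nrd Numeric vector of NRD values in \[0, 1\].
#' @param bin_width Histogram bin width (default 0.1).
#' @return A list: `histogram` (data.frame `bin_low`, `bin_high`, `count`),
#'   `cdf` (a right-continuous [stats::ecdf()] function), `n`.
#' @export
nrd_distribution <- function(nrd, bin_width = 0.1) {
  stopifnot(length(nrd) >= 1L, all(nrd >= 0 & nrd <= 1))
  breaks <- seq(0, 1, by = bin_width)
  if (max(breaks) < 1) breaks <- c(breaks, 1)
  nb <- length(breaks) - 1L
  # right-closed bins (lo, hi], with 0 folded into the first bin
  idx <- pmin(pmax(ceiling((nrd - breaks[1L]) / bin_width), 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  list(histogram = data.frame(bin_low = breaks[-length(breaks)],
                              bin_high = breaks[-1L], count = counts),
       cdf = stats::ecdf(nrd),
       n = length(nrd))
}

#' Correlate locus mobility with nuclear radial position
#'
#' Pearson correlation between NRD and the short-time effective diffusion
#' constant, with the descriptive class used for radiality analyses:
#' `|r| < 0.2` negligible, `0.2 <= |r| < 0.4` weak, otherwise moderate or
#' stronger.
#'
#' @param nrd,deff Matched numeric vectors (>= 3 finite pairs).
#' @return A `correlation_result` list: `r`, `n`, `class`.
#' @export
correlate_mobility_position <- function(nrd, deff) {
  stopifnot(length(nrd) == length(deff))
  ok <- is.finite(nrd) & is.finite(deff)
  if (sum(ok) < 3L) stop("need >= 3 finite records", call. = FALSE)
  if (stats::var(nrd[ok]) == 0 || stats::var(deff[ok]) == 0) {
    stop("zero variance in NRD or D_eff", call. = FALSE)
  }
  r <- stats::cor(nrd[ok], deff[ok])
  cls <- if (abs(r) < 0.2) "negligible" else if (abs(r) < 0.4) "weak"
         else "moderate+"
  structure(list(r = r, n = sum(ok), class = cls),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f (n = %d, %s)\n",
              x$r, x$n, x$class))
  invisible(x)
}
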