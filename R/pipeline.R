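# End-to-end orchestration: filter -> motion correction -> dynamics ->
# mechanics -> organization -> group comparisons, with tidy output tables.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the locus-tracking analysis pipeline
#'
#' Executes the full trajectory analysis on an ensemble: inclusion
#' filtering, nuclear-motion calibration, per-trajectory dynamics (TA-MSD
#' power-law fit, short-time D_eff, gyration radius), spring-constant
#' estimation, nuclear radiality (when geometry is available) and
#' per-group comparisons of D_eff and R_g. Deterministic given its inputs.
#'
#' @param config A named list:
#' \describe{
#'   \item{trajectories}{Path to a trajectory table or a
#'     [trajectory_ensemble()] (required).}
#'   \item{geometry}{Named list of [nucleus_geometry()] keyed by cell id,
#'     or `NULL`.}
#'   \item{min_length, max_focus_count, exclude_nucleus_class}{Filter rules,
#'     see [filter_ensemble()].}
#'   \item{motion_reference}{`"per_frame"` (default) or `"first_frame"`;
#'     only used when geometry is present.}
#'   \item{deff_lags}{Lags for [estimate_deff()] (default 4).}
#'   \item{msd_fit_lags}{Lag indices for the power-law fit (default first
#'     quarter).}
#'   \item{with_offset}{Fit the localization-noise offset (default FALSE).}
#'   \item{keff_method}{`"linear"` or `"exact"` (see [estimate_keff()]).}
#'   \item{group_by}{Grouping key for comparisons: `"locus_id"` (default)
#'     or `"condition"`.}
#'   \item{out_dir}{Optional directory for CSV/JSON outputs.}
#' }
#' @return A list of tidy tables: `per_trajectory`, `eamsd`,
#'   `group_summary`, `comparisons` (pairwise Welch tests plus an overall
#'   ANOVA per measure), `radiality`, `correlations`, `filter_report`, and
#'   the resolved `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$trajectories)) {
    stop("config error: 'trajectories' (path or ensemble) is required",
         call. = FALSE)
  }
  defaults <- list(geometry = NULL, min_length = NULL,
                   max_focus_count = NULL,
                   exclude_nucleus_class = character(),
                   motion_reference = "per_frame", deff_lags = 4L,
                   msd_fit_lags = NULL, with_offset = FALSE,
                   keff_method = "linear", group_by = "locus_id",
                   out_dir = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }

  ensemble <- with_stage("input", {
    tr <- config$trajectories
    if (inherits(tr, "trajectory_ensemble")) tr else read_trajectories(tr)
  })

  filtered <- with_stage("filter", filter_ensemble(
    ensemble, min_length = config$min_length,
    max_focus_count = config$max_focus_count,
    exclude_nucleus_class = config$exclude_nucleus_class))
  ensemble <- filtered$ensemble
  if (!length(ensemble)) stop("no trajectories survive filtering",
                              call. = FALSE)

  geometry <- config$geometry
  if (!is.null(geometry)) {
    ensemble <- with_stage("motion_correction", trajectory_ensemble(
      lapply(ensemble, function(tr) {
        g <- geometry[[tr$cell_id]]
        if (is.null(g)) stop(sprintf("no geometry for cell %s", tr$cell_id))
        correct_nuclear_motion(tr, g, reference = config$motion_reference)
      })))
  }

  per <- with_stage("dynamics", do.call(rbind, lapply(ensemble, function(tr) {
    fit <- fit_msd_power_law(compute_tamsd(tr), lags = config$msd_fit_lags,
                             with_offset = config$with_offset)
    deff <- estimate_deff(tr, n_lags = config$deff_lags)
    shape <- compute_rg(tr)
    data.frame(cell_id = tr$cell_id, locus_id = tr$locus_id,
               condition = tr$condition, n_frames = n_frames(tr),
               D_app = fit$D_app, beta = fit$beta, sigma_um = fit$sigma,
               D_eff = deff$D_eff, R_g_um = shape$R_g,
               stringsAsFactors = FALSE)
  })))
  rownames(per) <- NULL

  per$k_eff <- with_stage("mechanics", vapply(seq_along(ensemble), function(i) {
    tr <- ensemble[[i]]
    if (n_frames(tr) < 10L || per$D_eff[i] <= 0) return(NA_real_)
    estimate_keff(tr, method = config$keff_method)$k_eff
  }, numeric(1)))

  groups <- split(seq_len(nrow(per)), per[[config$group_by]])
  eamsd <- with_stage("dynamics", do.call(rbind, lapply(names(groups), function(g) {
    curve <- compute_eamsd(ensemble[groups[[g]]])
    data.frame(group = g, lag_s = curve$lag_s, msd_um2 = curve$msd_um2,
               n = curve$n_pairs, stringsAsFactors = FALSE)
  })))

  radiality <- NULL
  correlations <- NULL
  if (!is.null(geometry)) {
    radiality <- with_stage("organization", do.call(rbind,
      lapply(seq_along(ensemble), function(i) {
        tr <- ensemble[[i]]
        g <- geometry[[tr$cell_id]]
        if (is.null(g$boundary)) return(NULL)
        rec <- compute_nrd(colMeans(tr$positions), g)
        data.frame(cell_id = tr$cell_id, locus_id = tr$locus_id,
                   condition = tr$condition, nrd = rec$nrd,
                   clipped = rec$clipped, D_eff = per$D_eff[i],
                   stringsAsFactors = FALSE)
      })))
    if (!is.null(radiality) && nrow(radiality)) {
      correlations <- with_stage("organization", do.call(rbind,
        lapply(split(radiality, radiality$locus_id), function(d) {
          if (nrow(d) < 3L || stats::var(d$nrd) == 0 ||
              stats::var(d$D_eff) == 0) return(NULL)
          cr <- correlate_mobility_position(d$nrd, d$D_eff)
          data.frame(locus_id = d$locus_id[[1L]], r = cr$r, n = cr$n,
                     class = cr$class, stringsAsFactors = FALSE)
        })))
      if (!is.null(correlations)) rownames(correlations) <- NULL
    }
  }

  group_summary <- do.call(rbind, lapply(names(groups), function(g) {
    d <- per[groups[[g]], ]
    kpos <- d$k_eff[is.finite(d$k_eff) & d$k_eff > 0]
    data.frame(group = g, n = nrow(d),
               mean_D_eff = mean(d$D_eff), sd_D_eff = stats::sd(d$D_eff),
               mean_R_g_um = mean(d$R_g_um), sd_R_g_um = stats::sd(d$R_g_um),
               mean_beta = mean(d$beta),
               mean_k_eff = if (length(kpos)) mean(kpos) else NA_real_,
               n_k_eff_excluded = sum(is.finite(d$k_eff) & d$k_eff <= 0),
               stringsAsFactors = FALSE)
  }))

  comparisons <- with_stage("comparisons", {
    out <- list()
    for (measure in c("D_eff", "R_g_um")) {
      vals <- lapply(groups, function(i) per[[measure]][i])
      vals <- vals[vapply(vals, length, 0L) >= 2L]
      if (length(vals) >= 2L) {
        out[[paste0("anova_", measure)]] <- one_way_anova(vals)
        nms <- names(vals)
        for (i in seq_len(length(nms) - 1L)) {
          for (j in (i + 1L):length(nms)) {
            out[[sprintf("welch_%s_%s_vs_%s", measure, nms[i], nms[j])]] <-
              welch_ttest(vals[[i]], vals[[j]], labels = c(nms[i], nms[j]))
          }
        }
      }
    }
    out
  })
  comparison_table <- do.call(rbind, lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    data.frame(comparison = nm, test = cmp$test, statistic = cmp$statistic,
               p_value = cmp$p_value, stars = cmp$stars,
               stringsAsFactors = FALSE)
  }))

  result <- list(per_trajectory = per, eamsd = eamsd,
                 group_summary = group_summary,
                 comparisons = comparisons,
                 comparison_table = comparison_table,
                 radiality = radiality, correlations = correlations,
                 filter_report = filtered$report,
                 config = config[setdiff(names(config), "trajectories")])

  if (!is.null(config$out_dir)) {
    with_stage("output", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      wr <- function(df, name) {
        if (!is.null(df)) {
          utils::write.csv(df, file.path(config$out_dir, name),
                           row.names = FALSE)
        }
      }
      wr(per, "per_trajectory.csv")
      wr(eamsd, "eamsd.csv")
      wr(group_summary, "group_summary.csv")
      wr(comparison_table, "comparisons.csv")
      wr(radiality, "radiality.csv")
      wr(correlations, "correlations.csv")
      stamp <- c(result$config,
                 list(package_version =
                        as.character(utils::packageVersion("chromotrace"))))
      jsonlite::write_json(stamp, file.path(config$out_dir, "run_config.json"),
                           auto_unbox = TRUE, null = "null", force = TRUE)
    })
  }
  result
}
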