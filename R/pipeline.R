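#' Configuration for the array-to-calls workflow
#'
#' @param arrays data.frame describing the input arrays: `name`,
#'   `condition` (`"A"`/`"B"`), `pair` (induction pair index) and either a
#'   `path` column (probe TSVs on disk) or an `id` into the `probes` list.
#' @param probes optional named list of in-memory probe tables (keyed by
#'   `arrays$name`); when given, `path` is not read.
#' @param intervals_path,calibration_path paths to the hotspot BED and the
#'   Southern calibration TSV (ignored when `intervals` / `calibration`
#'   data.frames are supplied directly).
#' @param intervals,calibration in-memory alternatives to the paths.
#' @param refset names of the reference hotspots used for cross-array
#'   scaling (must be present in the intervals).
#' @param pi_level prediction-interval level (in (0,1); default 0.95).
#' @param breakage_threshold percent-breakage threshold (default 0.3).
#' @param log10 fit comparisons on the log10 scale.
#' @param seed integer seed recorded in the report.
#' @param out_dir output directory (created if missing); NULL to skip
#'   writing.
#' @return list of class `dsb_config`.
#' @export
pipeline_config <- function(arrays, probes = NULL, intervals_path = NULL,
                            calibration_path = NULL, intervals = NULL,
                            calibration = NULL, refset, pi_level = 0.95,
                            breakage_threshold = 0.3, log10 = TRUE,
                            seed = 1, out_dir = NULL) {
  if (pi_level <= 0 || pi_level >= 1) stop("pi_level must be in (0,1)")
  if (breakage_threshold <= 0) stop("breakage_threshold must be > 0")
  stopifnot(all(c("name", "condition", "pair") %in% names(arrays)))
  structure(
    list(arrays = arrays, probes = probes, intervals_path = intervals_path,
         calibration_path = calibration_path, intervals = intervals,
         calibration = calibration, refset = refset, pi_level = pi_level,
         breakage_threshold = breakage_threshold, log10 = log10,
         seed = seed, out_dir = out_dir),
    class = "dsb_config"
  )
}

#' Run the full array workflow: normalize, scale, integrate, calibrate,
#' call differentials
#'
#' Stage order: median normalization of every array; selection of the
#' reference array (highest signal over the reference hotspots) and
#' cross-array log-scale fitting; integration over hotspot intervals;
#' Southern calibration to percent breakage; per-induction-pair comparison
#' of condition A against condition B with the 95% prediction interval;
#' intersection of the per-pair calls; de novo detection on the
#' per-condition mean breakage tables.  Hotspots below half the breakage
#' threshold in either condition are excluded from the regression and
#' handled by the de novo rule.
#'
#' @param config a `dsb_config`.
#' @return list of class `dsb_report`: per-stage outputs plus the run
#'   report (counts, correlation coefficients, scale factors, seed and the
#'   full configuration echo).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "dsb_config"))
  arrays <- config$arrays

  intervals <- if (!is.null(config$intervals)) config$intervals
               else read_intervals_bed(config$intervals_path)
  if (is.null(intervals) || nrow(intervals) == 0) stop("empty hotspot interval set")
  calibration <- if (!is.null(config$calibration)) config$calibration
                 else read_calibration_pairs(config$calibration_path)
  if (!all(config$refset %in% intervals$name)) {
    stop("refset hotspots missing from the interval set")
  }
  refset_iv <- intervals[match(config$refset, intervals$name), , drop = FALSE]

  probes <- lapply(seq_len(nrow(arrays)), function(i) {
    if (!is.null(config$probes)) config$probes[[arrays$name[i]]]
    else read_probe_table(arrays$path[i])
  })
  names(probes) <- arrays$name

  profiles <- lapply(probes, normalize_profile)
  ref_idx <- select_reference_profile(profiles, refset_iv)
  scale_factors <- vapply(seq_along(profiles), function(i) {
    if (i == ref_idx) return(1)
    fit_scale_factor(profiles[[i]], profiles[[ref_idx]], refset_iv)
  }, numeric(1))
  profiles <- mapply(set_scale_factor, profiles, scale_factors,
                     SIMPLIFY = FALSE)

  tables <- lapply(profiles, integrate_hotspots, intervals = intervals)
  calibrated <- lapply(tables, calibrate_breakage, southern_pairs = calibration,
                       threshold = config$breakage_threshold)
  tables <- lapply(calibrated, `[[`, "table")

  cond_mean <- function(cond) {
    sel <- which(arrays$condition == cond)
    if (!length(sel)) stop("no arrays for condition ", cond)
    tab <- tables[[sel[1]]]
    tab$integrated_signal <- rowMeans(
      vapply(sel, function(i) tables[[i]]$integrated_signal,
             numeric(nrow(tab))))
    tab$percent_breakage <- rowMeans(
      vapply(sel, function(i) tables[[i]]$percent_breakage,
             numeric(nrow(tab))))
    tab$passes_threshold <- tab$percent_breakage > config$breakage_threshold
    tab
  }
  mean_A <- cond_mean("A")
  mean_B <- cond_mean("B")

  guard <- config$breakage_threshold / 2
  keep <- mean_A$percent_breakage >= guard & mean_B$percent_breakage >= guard
  pairs <- sort(unique(arrays$pair))
  comparisons <- list()
  for (j in pairs) {
    ia <- which(arrays$condition == "A" & arrays$pair == j)
    ib <- which(arrays$condition == "B" & arrays$pair == j)
    if (length(ia) != 1 || length(ib) != 1) next
    fit <- fit_comparison(
      x = tables[[ib]]$integrated_signal[keep],
      y = tables[[ia]]$integrated_signal[keep],
      names = tables[[ia]]$name[keep],
      log10 = config$log10, level = config$pi_level
    )
    comparisons[[paste0("pair", j)]] <- list(fit = fit,
                                             calls = classify_outliers(fit))
  }
  if (length(comparisons) < 1) stop("no complete condition pairs to compare")

  reproducible <- if (length(comparisons) >= 2) {
    intersect_reproducible(lapply(comparisons, `[[`, "calls"))
  } else {
    cl <- comparisons[[1]]$calls
    list(increased = cl$name[cl$class == "increased"],
         decreased = cl$name[cl$class == "decreased"],
         provenance = NULL)
  }
  de_novo <- detect_de_novo(mean_A, mean_B,
                            threshold = config$breakage_threshold)

  report <- list(
    n_hotspots = nrow(intervals),
    n_passing_A = sum(mean_A$passes_threshold),
    n_passing_B = sum(mean_B$passes_threshold),
    n_compared = sum(keep),
    n_increased = length(reproducible$increased),
    n_decreased = length(reproducible$decreased),
    n_de_novo = length(de_novo),
    pearson_r = vapply(comparisons, function(cmp) cmp$fit$pearson_r,
                       numeric(1)),
    scale_factors = stats::setNames(scale_factors, arrays$name),
    reference_array = arrays$name[ref_idx],
    calibration_slope = calibrated[[1]]$model$slope,
    seed = config$seed,
    config = config[c("refset", "pi_level", "breakage_threshold", "log10")]
  )

  result <- structure(
    list(report = report, tables = tables, mean_A = mean_A, mean_B = mean_B,
         comparisons = comparisons, reproducible = reproducible,
         de_novo = de_novo),
    class = "dsb_report"
  )

  if (!is.null(config$out_dir)) .write_pipeline_outputs(result, config)
  result
}

#' @export
print.dsb_report <- function(x, ...) {
  r <- x$report
  cat("dsb pipeline report\n",
      sprintf("  hotspots: %d (%d pass >%.2g%% in A, %d in B)\n",
              r$n_hotspots, r$n_passing_A, r$config$breakage_threshold,
              r$n_passing_B),
      sprintf("  compared: %d; reproducibly increased %d, decreased %d, de novo %d\n",
              r$n_compared, r$n_increased, r$n_decreased, r$n_de_novo),
      sprintf("  Pearson r: %s\n",
              paste(sprintf("%.3f", r$pearson_r), collapse = ", ")),
      sep = "")
  invisible(x)
}

.write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$tables)) {
    write_hotspot_table(result$tables[[nm]],
                        file.path(config$out_dir, paste0("hotspots_", nm, ".tsv")))
  }
  calls <- lapply(names(result$comparisons), function(nm) {
    cl <- result$comparisons[[nm]]$calls
    cl$comparison <- nm
    cl
  })
  calls <- do.call(rbind, calls)
  calls$reproducible <- calls$name %in%
    c(result$reproducible$increased, result$reproducible$decreased)
  utils::write.table(calls,
                     file.path(config$out_dir, "differential_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    result$report, file.path(config$out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = 10, null = "null", force = TRUE
  )
  invisible(NULL)
}
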