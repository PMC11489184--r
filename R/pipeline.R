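#' Read and write spike-list and plate-map tables
#'
#' The pipeline's canonical input is a spike-list CSV with columns
#' `experiment`, `plate`, `well`, `electrode`, `time_s` (and `div` when a
#' file spans several recording days), plus a plate-map CSV with columns
#' `experiment`, `plate`, `well`, `compound`, `concentration_uM`, `sex`.
#' Reading validates column presence and spike-time sanity, sorts spikes
#' within electrode, and collapses exact duplicate rows with a warning.
#'
#' @param path File path.
#' @param plate_map Optional plate map; when given, spike rows referencing
#'   unknown wells raise an error.
#' @return `read_spike_list()`: a validated spike tibble.
#'   `read_plate_map()`: a plate-map tibble.
#' @export
read_spike_list <- function(path, plate_map = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("experiment", "plate", "well", "electrode", "time_s")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("spike list lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(x) > 0 && (any(!is.finite(x$time_s)) || any(x$time_s < 0)))
    stop("spike times must be finite and >= 0", call. = FALSE)
  ndup <- sum(duplicated(x))
  if (ndup > 0) {
    warning(sprintf("collapsed %d duplicate spike row(s)", ndup),
            call. = FALSE)
    x <- dplyr::distinct(x)
  }
  if (!is.null(plate_map)) {
    known <- paste(plate_map$plate, plate_map$well)
    bad <- setdiff(unique(paste(x$plate, x$well)), known)
    if (length(bad))
      stop("spike list references wells absent from the plate map: ",
           paste(bad, collapse = "; "), call. = FALSE)
  }
  ord <- c("experiment", "plate", "well", "electrode", "time_s")
  dplyr::arrange(x, dplyr::across(dplyr::any_of(c(ord, "div"))))
}

#' @rdname read_spike_list
#' @export
read_plate_map <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("experiment", "plate", "well", "compound", "concentration_uM",
            "sex")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("plate map lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(x[c("experiment", "plate", "well")]))
    stop("plate map assigns more than one condition to a well",
         call. = FALSE)
  x
}

#' @rdname read_spike_list
#' @param spikes Spike tibble to write.
#' @export
write_spike_list <- function(spikes, path) {
  readr::write_csv(spikes, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param recording_duration_s Full recording length, seconds (default 1800).
#' @param window_s Analysis-window length, seconds (default 1200).
#' @param final_div Normalization day (default 28).
#' @param baseline_div Baseline / well-inclusion day (default 7).
#' @param alpha Significance level (default 0.05).
#' @param min_bursting_electrodes Well-inclusion threshold at baseline
#'   (default 4).
#' @param min_rate_per_min Electrode-inclusion threshold (default 6).
#' @param bmr_mode `"per_div"` or `"time_averaged"` (see [bmr_band()]).
#' @param burst_cfg,nb_cfg Detection configurations.
#' @param control_compound Solvent-control label.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(recording_duration_s = 1800, window_s = 1200,
                            final_div = 28, baseline_div = 7, alpha = 0.05,
                            min_bursting_electrodes = 4, min_rate_per_min = 6,
                            bmr_mode = "per_div",
                            burst_cfg = burst_config(),
                            nb_cfg = network_burst_config(),
                            control_compound = "DMSO control") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Composes the stages on a spike-list dataset: detection and per-well
#' metrics ([mea_metrics()]), baseline well inclusion ([include_wells()]),
#' cumulative treatment ratios ([cumulative_ratios()]), per-condition
#' outlier exclusion ([exclude_outliers()]), the benchmark-response band
#' ([bmr_band()]) and the effect report ([effect_report()]). Deterministic
#' given its inputs. A stage log records counts in and out of every filter.
#'
#' @param spikes Spike-list tibble (see [read_spike_list()]).
#' @param plate_map Plate-map tibble (see [read_plate_map()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, the metrics, ratio
#'   and BMR tables are written as CSV and the effect report as JSON-ready
#'   CSV tables.
#' @return A `mea_pipeline` list: `metrics`, `ratios`, `band`, `effects`,
#'   `log` (named list of stage counts), `config`.
#' @export
#' @examples
#' cfg <- sim_config(wells_per_plate = 4, recording_days = c(7L, 10L), seed = 3)
#' ex <- simulate_experiment(cfg)
#' res <- run_pipeline(ex$spikes, ex$plate_map,
#'                     pipeline_config(final_div = 10))
#' res$log$wells_retained
run_pipeline <- function(spikes, plate_map, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()

  metrics <- mea_metrics(spikes, plate_map,
                         recording_duration_s = config$recording_duration_s,
                         window_s = config$window_s,
                         burst_cfg = config$burst_cfg,
                         nb_cfg = config$nb_cfg,
                         min_rate_per_min = config$min_rate_per_min)
  log$wells_total <- dplyr::n_distinct(paste(metrics$plate, metrics$well))

  kept <- include_wells(metrics, baseline_div = config$baseline_div,
                        min_bursting_electrodes =
                          config$min_bursting_electrodes)
  log$wells_retained <- dplyr::n_distinct(paste(kept$plate, kept$well))

  ratios <- cumulative_ratios(kept, final_div = config$final_div,
                              control_compound = config$control_compound)
  ratios <- exclude_outliers(ratios)
  log$outlier_fraction <- attr(ratios, "excluded_fraction")
  log$outliers_flagged <- sum(ratios$outlier, na.rm = TRUE)
  log$ratio_rows <- sum(!is.na(ratios$ratio_pct))

  band <- bmr_band(ratios, mode = config$bmr_mode)
  effects <- effect_report(ratios, band, alpha = config$alpha,
                           baseline_div = config$baseline_div)
  log$cells_tested <- nrow(effects$cells)
  log$cells_significant <- if (nrow(effects$cells))
    sum(effects$cells$significant, na.rm = TRUE) else 0L

  res <- structure(list(metrics = metrics, ratios = ratios, band = band,
                        effects = effects, log = log, config = config),
                   class = "mea_pipeline")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(metrics, file.path(out_dir, "well_metrics.csv"))
    readr::write_csv(tibble::as_tibble(ratios),
                     file.path(out_dir, "treatment_ratios.csv"))
    readr::write_csv(band, file.path(out_dir, "bmr_band.csv"))
    if (nrow(effects$cells))
      readr::write_csv(effects$cells, file.path(out_dir, "effect_cells.csv"))
    readr::write_csv(effects$loec, file.path(out_dir, "loec_summary.csv"))
  }
  res
}

#' @export
print.mea_pipeline <- function(x, ...) {
  cat("<MEA pipeline run>\n")
  cat(sprintf("  wells: %d total, %d retained at baseline\n",
              x$log$wells_total, x$log$wells_retained))
  cat(sprintf("  outliers: %d flagged (%.2f%% of ratio values)\n",
              x$log$outliers_flagged, 100 * x$log$outlier_fraction))
  cat(sprintf("  effect cells: %d tested, %d significant\n",
              x$log$cells_tested, x$log$cells_significant))
  invisible(x)
}
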