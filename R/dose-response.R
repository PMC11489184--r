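#' Baseline well inclusion
#'
#' A well enters the experiment only if its baseline recording (DIV 7 by
#' default) shows at least `min_bursting_electrodes` electrodes with at
#' least one detected burst; the decision applies to all of the well's
#' recording days.
#'
#' @param metrics A [mea_metrics()] table.
#' @param baseline_div Baseline day (default 7).
#' @param min_bursting_electrodes Inclusion threshold (default 4,
#'   inclusive).
#' @return The metrics table restricted to retained wells, with the same
#'   class.
#' @export
include_wells <- function(metrics, baseline_div = 7,
                          min_bursting_electrodes = 4) {
  base <- dplyr::filter(metrics, .data$div == baseline_div)
  ok <- base[base$n_bursting_electrodes >= min_bursting_electrodes,
             c("experiment", "plate", "well")]
  out <- dplyr::semi_join(metrics, ok,
                          by = c("experiment", "plate", "well"))
  class(out) <- class(metrics)
  out
}

#' Cumulative treatment ratios
#'
#' Converts per-well parameter values into developmental treatment ratios by
#' the cumulative approach: within each well and parameter, the raw values
#' are summed over recording days from the first day up to each DIV
#' (undefined values are skipped, so the running sum stays monotone); the
#' cumulative value is then expressed as a percentage of the mean cumulative
#' value of the same-sex solvent-control wells at the final DIV. The control
#' curve therefore ends at 100\% at the final DIV by construction.
#'
#' Call [exclude_outliers()] afterwards to apply the per-condition
#' mean +/- 2 SD exclusion and restore the exact 100\% control endpoint on
#' the retained wells.
#'
#' @param metrics A (well-included) [mea_metrics()] table.
#' @param final_div Normalization day (default 28).
#' @param control_compound Label of the solvent control (default
#'   `"DMSO control"`).
#' @return A `mea_ratios` tibble: one row per (experiment, plate, well, div,
#'   parameter) with `compound`, `concentration_uM`, `sex`,
#'   `cumulative_raw`, `ratio_pct` and `outlier` (all `FALSE` until
#'   [exclude_outliers()] runs).
#' @export
cumulative_ratios <- function(metrics, final_div = 28,
                              control_compound = "DMSO control") {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(metrics)[c("experiment", "plate", "well", "compound",
                                 "concentration_uM", "sex", "div",
                                 metric_names())],
    cols = dplyr::all_of(metric_names()),
    names_to = "parameter", values_to = "raw"
  )
  long <- dplyr::arrange(long, .data$experiment, .data$plate, .data$well,
                         .data$parameter, .data$div)
  long <- dplyr::mutate(
    long,
    cumulative_raw = cumsum(tidyr::replace_na(.data$raw, 0)) +
      ifelse(cumsum(!is.na(.data$raw)) == 0, NA_real_, 0),
    .by = c("experiment", "plate", "well", "parameter")
  )

  ctrl <- dplyr::filter(long, .data$compound == control_compound,
                        .data$div == final_div)
  if (nrow(ctrl) == 0)
    stop("no solvent-control wells at the final DIV", call. = FALSE)
  ref <- dplyr::summarise(ctrl,
                          ref = mean(.data$cumulative_raw, na.rm = TRUE),
                          .by = c("sex", "parameter"))
  if (!all(unique(long$sex) %in% ref$sex[!is.na(ref$ref)]))
    warning("some sexes lack control wells; their ratios are undefined",
            call. = FALSE)

  out <- dplyr::left_join(long, ref, by = c("sex", "parameter"))
  out <- dplyr::mutate(out,
                       ratio_pct = 100 * .data$cumulative_raw /
                         ifelse(.data$ref > 0, .data$ref, NA_real_),
                       outlier = FALSE)
  out$ref <- NULL
  structure(out, class = c("mea_ratios", class(tibble::tibble())),
            final_div = final_div, control_compound = control_compound)
}

#' Per-condition outlier exclusion
#'
#' Flags, within every (parameter, compound, concentration, sex, div) group,
#' ratio values farther than `k` sample standard deviations from the group
#' mean (single pass, no re-iteration). Groups smaller than 3 are never
#' flagged (the SD is unstable). After flagging, the solvent-control
#' normalization is recomputed on the retained control wells so the mean
#' retained-control ratio at the final DIV is exactly 100\% for every
#' parameter and sex.
#'
#' @param ratios A [cumulative_ratios()] table.
#' @param k SD multiplier (default 2).
#' @return The table with `outlier` flags set and `ratio_pct` renormalized;
#'   attribute `excluded_fraction` carries the overall flagged fraction.
#' @export
exclude_outliers <- function(ratios, k = 2) {
  stopifnot(inherits(ratios, "mea_ratios"))
  final_div <- attr(ratios, "final_div")
  control_compound <- attr(ratios, "control_compound")

  out <- dplyr::mutate(
    ratios,
    outlier = flag_outliers(.data$ratio_pct, k),
    .by = c("parameter", "compound", "concentration_uM", "sex", "div")
  )
  n_val <- sum(!is.na(out$ratio_pct))
  n_fl <- sum(out$outlier, na.rm = TRUE)

  # renormalize so retained control wells average exactly 100% at final DIV
  ref <- dplyr::summarise(
    dplyr::filter(out, .data$compound == control_compound,
                  .data$div == final_div, !.data$outlier),
    factor = 100 / mean(.data$ratio_pct, na.rm = TRUE),
    .by = c("sex", "parameter"))
  if (nrow(ref) > 0) {
    out <- dplyr::left_join(out, ref, by = c("sex", "parameter"))
    out <- dplyr::mutate(
      out,
      ratio_pct = .data$ratio_pct *
        ifelse(is.na(.data$factor) | !is.finite(.data$factor), 1,
               .data$factor))
    out$factor <- NULL
  }

  structure(out, class = class(ratios), final_div = final_div,
            control_compound = control_compound,
            excluded_fraction = if (n_val > 0) n_fl / n_val else 0)
}

# mean +/- k*SD rule on one group; NA values never flagged, groups of
# fewer than 3 finite values left untouched
flag_outliers <- function(x, k = 2) {
  ok <- is.finite(x)
  if (sum(ok) < 3) return(rep(FALSE, length(x)))
  m <- mean(x[ok]); s <- sd(x[ok])
  fl <- rep(FALSE, length(x))
  if (is.finite(s) && s > 0) fl[ok] <- abs(x[ok] - m) > k * s
  fl
}

#' Benchmark-response band
#'
#' The benchmark response (BMR) summarizes the variation of the pooled
#' solvent-control experiments: at each (parameter, DIV) the band is the
#' control mean ratio +/- the SD of the retained control ratios pooled
#' across experiments (and sexes, since ratios are sex-normalized).
#' Statistically significant deviations smaller than the band's half-width
#' are considered of limited toxicological relevance.
#'
#' @param ratios An outlier-excluded [cumulative_ratios()] table.
#' @param mode `"per_div"` (default: per-DIV control SD) or
#'   `"time_averaged"` (the per-DIV SDs are averaged over DIVs and the
#'   common half-width applied everywhere).
#' @return A `mea_bmr` tibble: `parameter`, `div`, `control_mean`,
#'   `half_width`, `lower_pct`, `upper_pct`.
#' @export
bmr_band <- function(ratios, mode = c("per_div", "time_averaged")) {
  stopifnot(inherits(ratios, "mea_ratios"))
  mode <- match.arg(mode)
  control_compound <- attr(ratios, "control_compound")
  ctrl <- dplyr::filter(ratios, .data$compound == control_compound,
                        !.data$outlier, !is.na(.data$ratio_pct))
  band <- dplyr::summarise(ctrl,
                           control_mean = mean(.data$ratio_pct),
                           half_width = ifelse(dplyr::n() > 1,
                                               sd(.data$ratio_pct), 0),
                           .by = c("parameter", "div"))
  if (mode == "time_averaged") {
    band <- dplyr::mutate(band, half_width = mean(.data$half_width),
                          .by = "parameter")
  }
  band <- dplyr::mutate(band,
                        lower_pct = .data$control_mean - .data$half_width,
                        upper_pct = .data$control_mean + .data$half_width)
  structure(band, class = c("mea_bmr", class(tibble::tibble())))
}
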