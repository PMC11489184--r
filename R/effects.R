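#' Effect flags, sex specificity and LOEC summary
#'
#' The pipeline's decision layer. For every (parameter, compound, DIV) a
#' two-way ANOVA (concentration x sex, Type-II, Tukey post-hoc) is fitted on
#' the retained treatment ratios of the compound's wells plus the solvent
#' controls. A (concentration, sex, DIV) cell is flagged *significant* when
#' its Tukey-adjusted p-value against control is at most `alpha` AND the
#' condition mean deviates from the sex-matched control mean by more than
#' the benchmark-response half-width (deviations inside the band are of
#' limited toxicological relevance, however small their p-value). The
#' direction of a significant cell is excitation (above control) or
#' inhibition (below). A cell is *sex-specific* when the sex contrast within
#' its concentration has p at most `alpha`. The lowest concentration with at
#' least one significant cell across parameters and DIVs is the compound's
#' (per-sex) LOEC.
#'
#' @param ratios An outlier-excluded [cumulative_ratios()] table.
#' @param band A [bmr_band()] table (computed from `ratios` when `NULL`).
#' @param alpha Significance level (default 0.05).
#' @param baseline_div Baseline day excluded from testing (exposure starts
#'   only after it); default 7. Use `NULL` to test all days.
#' @param parameters Optional character vector restricting the tested
#'   parameters (default: all present).
#' @return A `mea_effects` object: list with `cells` (per parameter /
#'   compound / concentration / sex / div flags), `anova` (per parameter /
#'   compound / div model summaries), `loec` (per compound / sex summary)
#'   and `alpha`.
#' @export
effect_report <- function(ratios, band = NULL, alpha = 0.05,
                          baseline_div = 7, parameters = NULL) {
  stopifnot(inherits(ratios, "mea_ratios"))
  control_compound <- attr(ratios, "control_compound")
  if (is.null(band)) band <- bmr_band(ratios)

  dat <- dplyr::filter(ratios, !.data$outlier, !is.na(.data$ratio_pct))
  if (!is.null(parameters))
    dat <- dplyr::filter(dat, .data$parameter %in% parameters)
  if (!is.null(baseline_div)) dat <- dplyr::filter(dat,
                                                   .data$div != baseline_div)
  compounds <- setdiff(unique(dat$compound), control_compound)
  ctrl <- dplyr::filter(dat, .data$compound == control_compound)

  ctrl_means <- dplyr::summarise(ctrl, control_mean = mean(.data$ratio_pct),
                                 .by = c("parameter", "sex", "div"))

  cells_list <- list(); anova_list <- list()
  for (cmp in compounds) {
    sub_cmp <- dplyr::filter(dat, .data$compound == cmp)
    for (par in unique(sub_cmp$parameter)) {
      for (dv in sort(unique(sub_cmp$div))) {
        d <- dplyr::bind_rows(
          dplyr::filter(ctrl, .data$parameter == par, .data$div == dv),
          dplyr::filter(sub_cmp, .data$parameter == par, .data$div == dv))
        fit <- tryCatch(suppressWarnings(anova_twoway(d)),
                        error = function(e) NULL)
        if (is.null(fit)) next
        gm <- dplyr::summarise(
          dplyr::filter(d, .data$compound == cmp),
          group_mean = mean(.data$ratio_pct), n = dplyr::n(),
          .by = c("concentration_uM", "sex"))
        hw <- band$half_width[band$parameter == par & band$div == dv]
        if (length(hw) == 0) hw <- NA_real_
        cc <- dplyr::left_join(fit$conc_contrasts, gm,
                               by = c("concentration_uM", "sex"))
        cc <- dplyr::left_join(
          cc, ctrl_means[ctrl_means$parameter == par & ctrl_means$div == dv,
                         c("sex", "control_mean")],
          by = "sex")
        sexp <- fit$sex_contrasts[c("concentration_uM", "p_adj")]
        names(sexp)[2] <- "sex_p"
        cc <- dplyr::left_join(cc, sexp, by = "concentration_uM")
        cc <- dplyr::mutate(
          cc,
          parameter = par, compound = cmp, div = dv,
          deviation = .data$group_mean - .data$control_mean,
          bmr_half_width = hw,
          exceeds_bmr = !is.na(hw) & abs(.data$deviation) > hw,
          significant = !is.na(.data$p_adj) & .data$p_adj <= alpha &
            .data$exceeds_bmr,
          below_bmr_significant = !is.na(.data$p_adj) &
            .data$p_adj <= alpha & !.data$exceeds_bmr,
          direction = dplyr::case_when(
            !significant ~ NA_character_,
            deviation > 0 ~ "excitation",
            TRUE ~ "inhibition"),
          sex_specific = !is.na(.data$sex_p) & .data$sex_p <= alpha)
        cells_list[[length(cells_list) + 1]] <- cc
        anova_list[[length(anova_list) + 1]] <- dplyr::mutate(
          glance(fit), parameter = par, compound = cmp, div = dv)
      }
    }
  }
  cells <- dplyr::bind_rows(cells_list)
  if (nrow(cells)) {
    cells <- dplyr::relocate(cells, "parameter", "compound",
                             "concentration_uM", "sex", "div")
  }
  loec <- loec_summary(cells, compounds,
                       sexes = unique(dat$sex))
  structure(list(cells = cells, anova = dplyr::bind_rows(anova_list),
                 loec = loec, alpha = alpha),
            class = "mea_effects")
}

# Lowest concentration with >= 1 significant (parameter, DIV) cell, per
# compound and sex; direction taken from the flagged cells at the LOEC.
loec_summary <- function(cells, compounds, sexes) {
  out <- tidyr::expand_grid(compound = compounds, sex = sexes)
  if (nrow(out) == 0) return(tibble::tibble(
    compound = character(0), sex = character(0), loec_uM = numeric(0),
    direction = character(0)))
  sig <- if (nrow(cells)) dplyr::filter(cells, .data$significant) else cells
  out <- dplyr::rowwise(out)
  out <- dplyr::mutate(out, {
    s <- sig[nrow(sig) > 0 & sig$compound == .data$compound &
             sig$sex == .data$sex, , drop = FALSE]
    if (nrow(s) == 0) {
      tibble::tibble(loec_uM = NA_real_, direction = "no effect")
    } else {
      lo <- min(s$concentration_uM)
      dirs <- s$direction[s$concentration_uM == lo]
      tibble::tibble(loec_uM = lo,
                     direction = names(sort(table(dirs), decreasing = TRUE))[1])
    }
  })
  dplyr::ungroup(out)
}

#' @export
tidy.mea_effects <- function(x, ...) tibble::as_tibble(x$cells)

#' @export
glance.mea_effects <- function(x, ...) {
  has <- nrow(x$cells) > 0
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_significant = if (has) sum(x$cells$significant, na.rm = TRUE) else 0L,
    n_sex_specific = if (has) sum(x$cells$sex_specific &
                                    x$cells$significant, na.rm = TRUE)
                     else 0L,
    alpha = x$alpha)
}

#' @export
print.mea_effects <- function(x, ...) {
  cat("<MEA effect report>\n")
  cat(sprintf("  %d tested cells, %d significant (alpha = %g, BMR-filtered)\n",
              nrow(x$cells), glance(x)$n_significant, x$alpha))
  cat("  LOEC summary:\n")
  print(as.data.frame(x$loec), row.names = FALSE)
  invisible(x)
}
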