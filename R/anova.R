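#' One-way ANOVA with Tukey HSD
#'
#' Classical fixed-effects one-way ANOVA ([stats::aov()]) with Tukey honest
#' significant differences on the studentized range, as used to
#' characterize control development over time. Returns a `mea_anova1`
#' object with [tidy()] and [glance()] methods.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping factor.
#' @return An object of class `mea_anova1`: list with `fit` (the aov),
#'   `table` (F, df, p) and `tukey` (pairwise comparisons tibble).
#' @export
#' @examples
#' d <- data.frame(y = rnorm(30), g = rep(letters[1:3], 10))
#' glance(anova_oneway(d, "y", "g"))
anova_oneway <- function(data, value, group) {
  d <- data.frame(y = data[[value]], g = factor(data[[group]]))
  d <- d[complete.cases(d), ]
  if (nlevels(droplevels(d$g)) < 2)
    stop("one-way ANOVA needs at least 2 groups", call. = FALSE)
  if (any(table(droplevels(d$g)) < 2))
    stop("every group needs at least 2 observations", call. = FALSE)
  fit <- aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  tuk <- TukeyHSD(fit)$g
  structure(list(
    fit = fit,
    table = tibble::tibble(F = an$`F value`[1], df1 = an$Df[1],
                           df2 = an$Df[2], p = an$`Pr(>F)`[1]),
    tukey = tibble::tibble(comparison = rownames(tuk),
                           estimate = tuk[, "diff"],
                           p_adj = tuk[, "p adj"])
  ), class = "mea_anova1")
}

#' @export
tidy.mea_anova1 <- function(x, ...) x$tukey

#' @export
glance.mea_anova1 <- function(x, ...) x$table

#' @export
print.mea_anova1 <- function(x, ...) {
  cat(sprintf("<one-way ANOVA> F(%d, %d) = %.3f, p = %.4g\n",
              x$table$df1, x$table$df2, x$table$F, x$table$p))
  invisible(x)
}

#' Two-way ANOVA (concentration x sex) with Tukey contrasts
#'
#' Fixed-effects two-way ANOVA with interaction on treatment ratios, the
#' model behind the effect flags: factors are exposure concentration
#' (control = 0 as reference) and sex. Unbalanced designs use Type-II sums
#' of squares ([car::Anova()]); empty factor cells are dropped with a
#' warning. Tukey-adjusted contrasts of every concentration against the
#' control are computed within each sex, and the sex contrast within each
#' concentration quantifies sex specificity.
#'
#' @param data Data frame with columns `ratio_pct`, `concentration_uM`,
#'   `sex` (additional columns ignored).
#' @return An object of class `mea_anova2`: `fit` (lm), `anova_table`
#'   (Type-II F tests), `conc_contrasts` (vs control, per sex, Tukey
#'   adjusted), `sex_contrasts` (male - female per concentration).
#' @export
anova_twoway <- function(data) {
  d <- data.frame(ratio = data$ratio_pct,
                  conc = factor(data$concentration_uM),
                  sex = factor(data$sex))
  d <- d[complete.cases(d), ]
  d$conc <- droplevels(d$conc)
  d$sex <- droplevels(d$sex)
  if (nlevels(d$conc) < 2 || nlevels(d$sex) < 2)
    stop("two-way ANOVA needs >= 2 levels of both factors", call. = FALSE)
  cells <- table(d$conc, d$sex)
  if (any(cells == 0)) {
    warning("dropping empty concentration x sex cells", call. = FALSE)
    keep_c <- rownames(cells)[rowSums(cells > 0) == ncol(cells)]
    d <- droplevels(d[d$conc %in% keep_c, ])
    if (nlevels(d$conc) < 2)
      stop("not enough complete cells for the two-way model", call. = FALSE)
  }
  fit <- lm(ratio ~ conc * sex, data = d)
  an <- car::Anova(fit, type = 2)
  an_tbl <- tibble::tibble(term = rownames(an),
                           sum_sq = an$`Sum Sq`,
                           df = an$Df,
                           F = an$`F value`,
                           p = an$`Pr(>F)`)

  emm <- emmeans::emmeans(fit, ~ conc * sex)
  pc <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        by = "sex", adjust = "tukey"))
  ctrl_lab <- levels(d$conc)[1]
  pat <- paste0("^conc", ctrl_lab, " - | - conc", ctrl_lab, "$")
  pc <- pc[grepl(pat, pc$contrast), ]
  pc$concentration_uM <- as.numeric(gsub(
    "^conc| - .*$", "",
    ifelse(grepl(paste0("^conc", ctrl_lab, " - "), pc$contrast),
           sub(paste0("^conc", ctrl_lab, " - "), "", pc$contrast),
           pc$contrast)))
  # estimate oriented as condition - control
  flip <- grepl(paste0(" - conc", ctrl_lab, "$"), pc$contrast)
  pc$estimate <- ifelse(flip, pc$estimate, -pc$estimate)
  conc_contrasts <- tibble::tibble(concentration_uM = pc$concentration_uM,
                                   sex = as.character(pc$sex),
                                   estimate = pc$estimate,
                                   p_adj = pc$p.value)

  ps <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        by = "conc", adjust = "tukey"))
  sex_contrasts <- tibble::tibble(
    concentration_uM = as.numeric(as.character(ps$conc)),
    contrast = as.character(ps$contrast),
    estimate = ps$estimate,
    p_adj = ps$p.value)

  structure(list(fit = fit, anova_table = an_tbl,
                 conc_contrasts = conc_contrasts,
                 sex_contrasts = sex_contrasts),
            class = "mea_anova2")
}

#' @export
tidy.mea_anova2 <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$conc_contrasts, type = "concentration_vs_control"),
    dplyr::mutate(x$sex_contrasts, type = "sex_within_concentration")
  )
}

#' @export
glance.mea_anova2 <- function(x, ...) {
  tidyr::pivot_wider(x$anova_table[x$anova_table$term != "Residuals",
                                   c("term", "F", "p")],
                     names_from = "term", values_from = c("F", "p"))
}

#' @export
print.mea_anova2 <- function(x, ...) {
  cat("<two-way ANOVA: concentration x sex (Type II)>\n")
  print(as.data.frame(x$anova_table), row.names = FALSE)
  invisible(x)
}
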