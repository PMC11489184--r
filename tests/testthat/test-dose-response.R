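test_that("baseline well inclusion requires four bursting electrodes at DIV 7", {
  m <- synthetic_metrics(1:4, c(7L, 10L), c("male", "female"),
                         function(w, d) 10)
  m$n_bursting_electrodes <- ifelse(m$well == 1 & m$div == 7, 3L,
                                    ifelse(m$well == 2 & m$div == 7, 4L, 16L))
  kept <- include_wells(m)
  expect_false(1 %in% kept$well)        # excluded for the whole experiment
  expect_true(all(c(2, 3, 4) %in% kept$well))
  expect_equal(sort(unique(kept$div[kept$well == 2])), c(7L, 10L))
})

test_that("cumulative ratios normalize to the DIV-28 control mean with exact linear scaling", {
  divs <- c(7L, 10L, 14L, 28L)
  # controls constant 10 per day; treated wells exactly double
  m <- dplyr::bind_rows(
    synthetic_metrics(1:4, divs, c("male", "female"), function(w, d) 10),
    synthetic_metrics(5:8, divs, c("male", "female"), function(w, d) 20,
                      compound = "drugA", concentration = 10))
  r <- cumulative_ratios(m, final_div = 28)
  ctrl28 <- dplyr::filter(r, compound == "DMSO control", div == 28)
  expect_true(all(abs(ctrl28$ratio_pct - 100) < 1e-9))
  # doubled raw values give exactly twice the control curve at every DIV,
  # reaching 200% at the normalization day
  joined <- dplyr::summarise(r, m = mean(ratio_pct),
                             .by = c(compound, div, parameter, sex))
  wide <- tidyr::pivot_wider(joined, names_from = compound,
                             values_from = m)
  expect_true(all(abs(wide$drugA - 2 * wide$`DMSO control`) < 1e-9))
  trt28 <- dplyr::filter(r, compound == "drugA", div == 28)
  expect_true(all(abs(trt28$ratio_pct - 200) < 1e-9))
  # cumulative values are monotone within well
  mono <- dplyr::summarise(
    dplyr::arrange(r, div),
    ok = all(diff(cumulative_raw) >= 0),
    .by = c(well, parameter))
  expect_true(all(mono$ok))
  # all-zero condition gives a flat 0% curve
  z <- dplyr::bind_rows(
    synthetic_metrics(1:2, divs, "male", function(w, d) 10),
    synthetic_metrics(3:4, divs, "male", function(w, d) 0,
                      compound = "drugZ", concentration = 100))
  rz <- cumulative_ratios(z, final_div = 28)
  expect_true(all(rz$ratio_pct[rz$compound == "drugZ"] == 0))
})

test_that("outlier rule flags mean +/- 2 SD violations once, then controls end at exactly 100%", {
  divs <- c(7L, 28L)
  m <- synthetic_metrics(1:10, divs, "male", function(w, d) 10)
  # distort one control well strongly at DIV 28
  m[m$well == 10 & m$div == 28, metric_names()] <- 60
  r <- exclude_outliers(cumulative_ratios(m, final_div = 28))
  fl <- dplyr::filter(r, div == 28, parameter == "n_spikes")
  expect_true(fl$outlier[fl$well == 10])
  expect_equal(sum(fl$outlier), 1)
  kept <- dplyr::filter(fl, !outlier)
  expect_equal(mean(kept$ratio_pct), 100, tolerance = 1e-12)
  # identical values: SD 0, nothing excluded
  g <- meadev:::flag_outliers(c(10, 10, 10, 10))
  expect_false(any(g))
  # one value far beyond 2 SD of its group
  expect_true(any(meadev:::flag_outliers(c(rep(10, 8), 30))))
  # groups smaller than 3 are never flagged
  expect_false(any(meadev:::flag_outliers(c(0, 100))))
})

test_that("the BMR band is the pooled control SD around the control mean", {
  divs <- c(7L, 28L)
  m <- synthetic_metrics(1:8, divs, "male", function(w, d) 10 + (w %% 4))
  r <- exclude_outliers(cumulative_ratios(m, final_div = 28))
  band <- bmr_band(r)
  ctrl <- dplyr::filter(r, parameter == "n_spikes", div == 28, !outlier)
  expect_equal(band$half_width[band$parameter == "n_spikes" &
                                 band$div == 28],
               sd(ctrl$ratio_pct))
  expect_equal(band$lower_pct, band$control_mean - band$half_width)
  # zero-variance controls collapse the band onto the control curve
  m0 <- synthetic_metrics(1:6, divs, "male", function(w, d) 10)
  b0 <- bmr_band(exclude_outliers(cumulative_ratios(m0, final_div = 28)))
  expect_true(all(b0$half_width == 0))
  # time-averaged mode gives one half-width per parameter
  bt <- bmr_band(r, mode = "time_averaged")
  hw <- dplyr::n_distinct(bt$half_width[bt$parameter == "n_spikes"])
  expect_equal(hw, 1)
})

test_that("one-way ANOVA matches hand-computed sums of squares and the t-test identity", {
  # classic 3-group worked example, F from first principles
  d <- data.frame(y = c(6, 8, 4, 5, 3, 4,
                        8, 12, 9, 11, 6, 8,
                        13, 9, 11, 8, 7, 12),
                  g = rep(c("a", "b", "c"), each = 6))
  gm <- mean(d$y)
  ssb <- sum(tapply(d$y, d$g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(d$y, d$g, function(v) sum((v - mean(v))^2)))
  f_hand <- (ssb / 2) / (ssw / 15)
  fit <- anova_oneway(d, "y", "g")
  expect_equal(glance(fit)$F, f_hand, tolerance = 1e-3)
  expect_equal(glance(fit)$df1, 2)
  expect_equal(glance(fit)$df2, 15)
  expect_equal(nrow(tidy(fit)), 3)
  # two groups: F equals the squared pooled t statistic
  set.seed(99)
  d2 <- data.frame(y = c(rnorm(10), rnorm(12, 1)),
                   g = rep(c("a", "b"), c(10, 12)))
  tt <- t.test(y ~ g, data = d2, var.equal = TRUE)
  expect_equal(glance(anova_oneway(d2, "y", "g"))$F,
               unname(tt$statistic)^2, tolerance = 1e-10)
  # identical means, positive variance: F near zero, p near one
  d3 <- data.frame(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  g3 <- glance(anova_oneway(d3, "y", "g"))
  expect_lt(g3$F, 1e-10)
  expect_gt(g3$p, 0.999)
  expect_error(anova_oneway(data.frame(y = 1:3, g = "a"), "y", "g"),
               "2 groups")
})

test_that("two-way ANOVA handles unbalanced designs and degenerate inputs", {
  set.seed(101)
  d <- tibble::tibble(
    concentration_uM = rep(c(0, 10), c(20, 14)),
    sex = rep(c("male", "female"), 17),
    ratio_pct = rnorm(34, 100, 10))
  fit <- anova_twoway(d)
  expect_s3_class(fit, "mea_anova2")
  expect_true(all(c("conc", "sex", "conc:sex") %in% fit$anova_table$term))
  expect_equal(nrow(fit$conc_contrasts), 2)  # 10 vs 0, per sex
  expect_equal(nrow(fit$sex_contrasts), 2)
  expect_true(all(tidy(fit)$p_adj >= 0 & tidy(fit)$p_adj <= 1, na.rm = TRUE))
  expect_error(anova_twoway(dplyr::filter(d, concentration_uM == 0)),
               "2 levels")
  # an injected sex-by-concentration effect is picked up by the sex contrast
  d2 <- d
  d2$ratio_pct[d2$concentration_uM == 10 & d2$sex == "female"] <-
    d2$ratio_pct[d2$concentration_uM == 10 & d2$sex == "female"] + 40
  fit2 <- anova_twoway(d2)
  p_sex_10 <- fit2$sex_contrasts$p_adj[fit2$sex_contrasts$concentration_uM ==
                                         10]
  expect_lt(p_sex_10, 0.01)
})

test_that("type-I error of the sex contrast is near nominal under the null", {
  set.seed(202)
  n_rep <- 150
  rej <- replicate(n_rep, {
    d <- tibble::tibble(
      concentration_uM = rep(c(0, 10), each = 16),
      sex = rep(rep(c("male", "female"), each = 8), 2),
      ratio_pct = rnorm(32, 100, 15))
    fit <- anova_twoway(d)
    any(fit$sex_contrasts$p_adj <= 0.05)
  })
  # two contrasts per replicate; familywise rate stays in a sane band
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.20)
})

test_that("effect flags honour the BMR filter and the LOEC picks the lowest flagged concentration", {
  divs <- c(7L, 14L, 28L)
  set.seed(303)
  noise <- function(w, d) 10 * exp(rnorm(1, 0, 0.05))
  m <- dplyr::bind_rows(
    synthetic_metrics(1:12, divs, c("male", "female"), noise),
    synthetic_metrics(13:24, divs, c("male", "female"),
                      function(w, d) if (d >= 14) 19 * exp(rnorm(1, 0, 0.05))
                                     else noise(w, d),
                      compound = "drugA", concentration = 10),
    synthetic_metrics(25:36, divs, c("male", "female"),
                      function(w, d) if (d >= 14) 21 * exp(rnorm(1, 0, 0.05))
                                     else noise(w, d),
                      compound = "drugA", concentration = 100),
    synthetic_metrics(37:48, divs, c("male", "female"), noise,
                      compound = "drugA", concentration = 1))
  r <- exclude_outliers(cumulative_ratios(m, final_div = 28))
  rep_ <- effect_report(r, alpha = 0.01, parameters = "n_spikes")
  cells <- rep_$cells
  sig28 <- dplyr::filter(cells, div == 28, significant)
  expect_true(all(sig28$concentration_uM %in% c(10, 100)))
  expect_true(all(sig28$direction == "excitation"))
  loec <- rep_$loec
  expect_equal(unique(loec$loec_uM), 10)
  expect_true(all(loec$direction == "excitation"))
  # a no-effect report yields "no effect"
  m0 <- dplyr::bind_rows(
    synthetic_metrics(1:8, divs, c("male", "female"), noise),
    synthetic_metrics(9:16, divs, c("male", "female"), noise,
                      compound = "drugB", concentration = 10))
  r0 <- exclude_outliers(cumulative_ratios(m0, final_div = 28))
  rep0 <- effect_report(r0, alpha = 0.001, parameters = "n_spikes")
  expect_true(all(rep0$loec$direction == "no effect"))
  expect_true(all(is.na(rep0$loec$loec_uM)))
})

test_that("statistically significant deviations inside the BMR band are not effects", {
  divs <- c(7L, 28L)
  set.seed(404)
  # wide control variation, tiny but consistent treated offset
  m <- dplyr::bind_rows(
    synthetic_metrics(1:16, divs, c("male", "female"),
                      function(w, d) 10 * exp(rnorm(1, 0, 0.2))),
    synthetic_metrics(17:32, divs, c("male", "female"),
                      function(w, d) 10.4 + (w %% 3) * 0.005,
                      compound = "drugC", concentration = 10))
  r <- exclude_outliers(cumulative_ratios(m, final_div = 28))
  band <- bmr_band(r)
  # force a huge band to guarantee the inside-band case, then flag
  band$half_width <- 1e3
  rep_ <- effect_report(r, band = band, parameters = "n_spikes")
  expect_false(any(rep_$cells$significant))
  expect_true(all(rep_$loec$direction == "no effect"))
})
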