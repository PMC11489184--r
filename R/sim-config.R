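#' Configuration for the synthetic MEA experiment generator
#'
#' Defines the generative model of a developing rat cortical culture on a
#' multi-well MEA plate: plate geometry, the recording schedule, the
#' developmental ramp of activity, baseline event rates at the activity
#' plateau, and well-to-well heterogeneity. Defaults emulate a 48-well plate
#' with 16 electrodes per well, 30-minute recordings on days in vitro (DIV)
#' 7, 10, 14, 17, 21, 24 and 28, activity onset at DIV 4 and a stable plateau
#' from DIV 10 onward.
#'
#' Activity is modeled as well-wide network-burst events (a homogeneous point
#' process at `baseline_network_burst_rate`, scaled by the developmental ramp
#' and a per-well log-normal multiplier) that each recruit a random subset of
#' electrodes; each recruited electrode fires a short within-burst spike
#' volley, and every electrode additionally fires tonic background spikes as
#' an independent Poisson process at `background_rate`.
#'
#' A built-in sex contrast mirrors the qualitative observation that male
#' control cultures show more network bursts than female ones during
#' DIV 10-17: male wells get a `sex_nb_boost` (+25\% by default) on the
#' network-burst rate over `sex_nb_div_range`.
#'
#' @param n_plates Number of plates to simulate.
#' @param wells_per_plate Wells per plate (default 48).
#' @param electrodes_per_well Electrodes per well (default 16).
#' @param recording_days Integer DIVs of the recording schedule, strictly
#'   increasing (default `c(7, 10, 14, 17, 21, 24, 28)`).
#' @param recording_duration_s Length of each recording in seconds
#'   (default 1800, i.e. 30 minutes).
#' @param growth_onset_div DIV at which spontaneous activity starts
#'   (default 4).
#' @param growth_plateau_div DIV from which activity is at its stable plateau
#'   (default 10).
#' @param baseline_network_burst_rate Well-wide network-burst events per
#'   minute at the plateau (default 4).
#' @param background_rate Tonic (non-burst) firing rate per electrode at the
#'   plateau, spikes/s (default 0.3).
#' @param within_burst_rate Firing rate of a recruited electrode during a
#'   network-burst volley, spikes/s (default 40).
#' @param burst_duration_s Median duration of a per-electrode burst volley,
#'   seconds (default 0.3); durations are log-normal with `burst_duration_sdlog`.
#' @param burst_duration_sdlog Log-scale SD of volley durations (default 0.4).
#' @param recruitment_fraction Probability that an electrode joins a given
#'   network-burst event, in \[0, 1\] (default 0.6).
#' @param onset_jitter_sd_s SD of the per-electrode onset jitter within a
#'   network-burst event, seconds (default 0.01).
#' @param well_heterogeneity_cv Coefficient of variation of the per-well
#'   log-normal rate multiplier (default 0.2). The multiplier is drawn once
#'   per well and shared across DIVs, so a well keeps its identity over
#'   development.
#' @param sex_nb_boost Extra network-burst rate in male wells over
#'   `sex_nb_div_range`, as a fraction (default 0.25 = +25\%).
#' @param sex_nb_div_range Length-2 DIV range of the male network-burst boost
#'   (default `c(10, 17)`).
#' @param seed Integer seed; together with the config it fixes the dataset
#'   byte-for-byte.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [compound_effect()], [simulate_well()], [simulate_experiment()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' development_curve(cfg, c(0, 4, 7, 10, 28))
sim_config <- function(n_plates = 1,
                       wells_per_plate = 48,
                       electrodes_per_well = 16,
                       recording_days = c(7L, 10L, 14L, 17L, 21L, 24L, 28L),
                       recording_duration_s = 1800,
                       growth_onset_div = 4,
                       growth_plateau_div = 10,
                       baseline_network_burst_rate = 4,
                       background_rate = 0.3,
                       within_burst_rate = 40,
                       burst_duration_s = 0.3,
                       burst_duration_sdlog = 0.4,
                       recruitment_fraction = 0.6,
                       onset_jitter_sd_s = 0.01,
                       well_heterogeneity_cv = 0.2,
                       sex_nb_boost = 0.25,
                       sex_nb_div_range = c(10, 17),
                       seed = 1L) {
  cfg <- list(
    n_plates = as.integer(n_plates),
    wells_per_plate = as.integer(wells_per_plate),
    electrodes_per_well = as.integer(electrodes_per_well),
    recording_days = as.integer(recording_days),
    recording_duration_s = as.numeric(recording_duration_s),
    growth_onset_div = as.numeric(growth_onset_div),
    growth_plateau_div = as.numeric(growth_plateau_div),
    baseline_network_burst_rate = as.numeric(baseline_network_burst_rate),
    background_rate = as.numeric(background_rate),
    within_burst_rate = as.numeric(within_burst_rate),
    burst_duration_s = as.numeric(burst_duration_s),
    burst_duration_sdlog = as.numeric(burst_duration_sdlog),
    recruitment_fraction = as.numeric(recruitment_fraction),
    onset_jitter_sd_s = as.numeric(onset_jitter_sd_s),
    well_heterogeneity_cv = as.numeric(well_heterogeneity_cv),
    sex_nb_boost = as.numeric(sex_nb_boost),
    sex_nb_div_range = as.numeric(sex_nb_div_range),
    seed = as.integer(seed)
  )
  rates <- c(cfg$baseline_network_burst_rate, cfg$background_rate,
             cfg$within_burst_rate)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0", call. = FALSE)
  if (cfg$recruitment_fraction < 0 || cfg$recruitment_fraction > 1)
    stop("recruitment_fraction must lie in [0, 1]", call. = FALSE)
  if (length(cfg$recording_days) < 1 || any(diff(cfg$recording_days) <= 0))
    stop("recording_days must be strictly increasing", call. = FALSE)
  if (cfg$growth_plateau_div <= cfg$growth_onset_div)
    stop("growth_plateau_div must exceed growth_onset_div", call. = FALSE)
  if (cfg$well_heterogeneity_cv < 0)
    stop("well_heterogeneity_cv must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d plate(s) x %d wells x %d electrodes; DIVs %s\n",
              x$n_plates, x$wells_per_plate, x$electrodes_per_well,
              paste(x$recording_days, collapse = ", ")))
  cat(sprintf("  plateau rates: %.2f network bursts/min, %.2f bg spikes/s/el, %.0f spikes/s in-burst\n",
              x$baseline_network_burst_rate, x$background_rate,
              x$within_burst_rate))
  cat(sprintf("  recruitment %.2f, well CV %.2f, seed %d\n",
              x$recruitment_fraction, x$well_heterogeneity_cv, x$seed))
  invisible(x)
}

#' Describe a compound exposure applied to simulated wells
#'
#' A compound effect multiplies selected generative knobs of the simulator
#' from an onset DIV onward, optionally in one sex only. The hard onset
#' models the latency of chronic-exposure effects (often 1-2 weeks after
#' exposure start) as observed on developing cultures.
#'
#' @param compound Compound label.
#' @param concentration Exposure concentration in micromolar; 0 is reserved
#'   for the solvent (DMSO) control.
#' @param sex_scope One of `"both"`, `"male"`, `"female"`: which sex the
#'   effect applies to.
#' @param onset_div DIV at which the multipliers start to apply (inclusive).
#' @param network_burst_rate,within_burst_rate,burst_duration,recruitment,background_rate,onset_jitter
#'   Multiplicative factors (> 0) on the corresponding generator knobs;
#'   default 1 (no change). `recruitment` is clamped so the recruited
#'   fraction stays in \[0, 1\].
#' @return An object of class `compound_effect`.
#' @export
#' @examples
#' eff <- compound_effect("drugA", 10, sex_scope = "female",
#'                        onset_div = 14, network_burst_rate = 1.5)
compound_effect <- function(compound, concentration,
                            sex_scope = c("both", "male", "female"),
                            onset_div = 7,
                            network_burst_rate = 1,
                            within_burst_rate = 1,
                            burst_duration = 1,
                            recruitment = 1,
                            background_rate = 1,
                            onset_jitter = 1) {
  sex_scope <- match.arg(sex_scope)
  mult <- c(network_burst_rate = network_burst_rate,
            within_burst_rate = within_burst_rate,
            burst_duration = burst_duration,
            recruitment = recruitment,
            background_rate = background_rate,
            onset_jitter = onset_jitter)
  if (any(!is.finite(mult)) || any(mult <= 0))
    stop("all effect multipliers must be finite and > 0", call. = FALSE)
  structure(list(compound = as.character(compound),
                 concentration = as.numeric(concentration),
                 sex_scope = sex_scope,
                 onset_div = as.numeric(onset_div),
                 multipliers = as.list(mult)),
            class = "compound_effect")
}

#' Solvent-control "effect" (all multipliers 1)
#' @return A `compound_effect` describing the DMSO control condition.
#' @export
control_condition <- function() {
  compound_effect("DMSO control", 0, sex_scope = "both", onset_div = 0)
}

#' Developmental activity ramp
#'
#' Activity multiplier as a function of culture age: 0 before the onset DIV,
#' 1 at and after the plateau DIV, and a smooth raised-cosine ramp in
#' between (strictly increasing on the open interval). Midway through the
#' ramp the multiplier is exactly 0.5.
#'
#' @param config A [sim_config()].
#' @param div Numeric vector of days in vitro (>= 0).
#' @return Numeric vector of multipliers in \[0, 1\].
#' @export
development_curve <- function(config, div) {
  stopifnot(inherits(config, "sim_config"))
  if (any(div < 0)) stop("div must be >= 0", call. = FALSE)
  a <- config$growth_onset_div
  b <- config$growth_plateau_div
  frac <- pmin(pmax((div - a) / (b - a), 0), 1)
  0.5 * (1 - cos(pi * frac))
}

#' Analytic expectation of the well-wide spike count
#'
#' Closed-form mean of the generative point process: over a recording of
#' length `T` at development multiplier `d(div)`,
#' `E[count] = T * d * (E * bg + r_nb * E * p * w * E[dur])`
#' with `E` electrodes, `bg` the background rate, `r_nb` the network-burst
#' event rate (per second), `p` the recruitment fraction, `w` the
#' within-burst rate and `E[dur]` the log-normal mean volley duration.
#' Used as an independent oracle for the simulator.
#'
#' @inheritParams development_curve
#' @param sex `"male"` or `"female"` (the male network-burst boost applies
#'   inside its DIV range).
#' @return Expected total spike count for one well (control condition,
#'   well multiplier 1).
#' @export
expected_well_spike_count <- function(config, div, sex = "female") {
  stopifnot(inherits(config, "sim_config"))
  d <- development_curve(config, div)
  nb_rate <- config$baseline_network_burst_rate / 60
  if (sex == "male" && div >= config$sex_nb_div_range[1] &&
      div <= config$sex_nb_div_range[2]) {
    nb_rate <- nb_rate * (1 + config$sex_nb_boost)
  }
  mean_dur <- exp(log(config$burst_duration_s) +
                  config$burst_duration_sdlog^2 / 2)
  e <- config$electrodes_per_well
  per_s <- e * config$background_rate +
    nb_rate * e * config$recruitment_fraction *
    config$within_burst_rate * mean_dur
  config$recording_duration_s * d * per_s
}

#' Analytic expected per-electrode firing rate at the plateau
#'
#' @inheritParams expected_well_spike_count
#' @return Expected spikes/s for a single electrode at the activity plateau.
#' @export
expected_electrode_rate <- function(config, sex = "female") {
  expected_well_spike_count(config, config$growth_plateau_div, sex) /
    (config$recording_duration_s * config$electrodes_per_well)
}
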