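# Small configurations and fixtures used across the suite. Detection and
# statistics fixtures are built in code; nothing is read from disk.

# compact plate for structural tests: 8 wells, 2 recording days
tiny_config <- function(seed = 1, ...) {
  sim_config(wells_per_plate = 8, recording_days = c(7L, 10L), seed = seed,
             ...)
}

# a homogeneous Poisson train over [0, duration]
poisson_train <- function(rate, duration) {
  sort(runif(rpois(1, rate * duration), 0, duration))
}

# a dense spike cluster of n spikes at `rate_hz` starting at t0
dense_cluster <- function(n, rate_hz, t0) {
  t0 + seq(0, by = 1 / rate_hz, length.out = n)
}

# metrics table with all ten parameters set per well from a generator
# function value(well, div); used to exercise the ratio stage with exact
# arithmetic
synthetic_metrics <- function(wells, divs, sexes, value,
                              compound = "DMSO control",
                              concentration = 0, experiment = "fx") {
  g <- tidyr::expand_grid(well = wells, div = divs)
  rows <- purrr::pmap_dfr(g, function(well, div) {
    v <- value(well, div)
    m <- stats::setNames(as.list(rep(v, length(metric_names()))),
                         metric_names())
    tibble::tibble(experiment = experiment, plate = 1L, well = well,
                   compound = compound, concentration_uM = concentration,
                   sex = sexes[(well - 1) %% length(sexes) + 1],
                   div = div, !!!m, n_bursting_electrodes = 16L,
                   n_active_electrodes = 16L)
  })
  rows
}
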