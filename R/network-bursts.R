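#' Network-burst detection configuration
#'
#' @param min_spikes Minimum pooled spikes per network burst (default 40).
#' @param min_electrode_fraction Minimum fraction of the well's analysed
#'   electrodes that must contribute at least one spike (default 0.15;
#'   rounded up, so 16 electrodes require 3 participants).
#' @param adaptive_isi_constant Dimensionless constant `C` of the adaptive
#'   maximum-interval rule `C / r_well` (default 0.25).
#' @param isi_bounds Length-2 clamp on the adaptive maximum interval,
#'   seconds (default `c(0.005, 0.3)`).
#' @return An object of class `network_burst_config`.
#' @export
network_burst_config <- function(min_spikes = 40,
                                 min_electrode_fraction = 0.15,
                                 adaptive_isi_constant = 0.25,
                                 isi_bounds = c(0.005, 0.3)) {
  stopifnot(min_spikes >= 1, min_electrode_fraction > 0,
            min_electrode_fraction <= 1, adaptive_isi_constant > 0,
            length(isi_bounds) == 2, isi_bounds[1] > 0,
            isi_bounds[2] >= isi_bounds[1])
  structure(list(min_spikes = as.integer(min_spikes),
                 min_electrode_fraction = min_electrode_fraction,
                 adaptive_isi_constant = adaptive_isi_constant,
                 isi_bounds = as.numeric(isi_bounds)),
            class = "network_burst_config")
}

#' Well-adaptive maximum inter-spike interval
#'
#' The maximum gap joining spikes into one network burst adapts to each
#' well's overall activity: `C / r_well`, clamped to `isi_bounds`, where
#' `r_well` is the pooled spike rate of the analysed electrodes over the
#' analysis window. Busy wells therefore require tighter coincidence than
#' sparse ones.
#'
#' @param n_spikes Pooled spike count of the well over the window.
#' @param duration_s Analysis-window length in seconds (> 0).
#' @param cfg A [network_burst_config()].
#' @return Maximum interval in seconds, or `NA_real_` when the well has no
#'   spikes (no network-burst analysis is possible).
#' @export
#' @examples
#' well_max_isi(1200, 1200)  # r = 1/s -> 0.25 s
well_max_isi <- function(n_spikes, duration_s, cfg = network_burst_config()) {
  stopifnot(inherits(cfg, "network_burst_config"), duration_s > 0)
  if (n_spikes < 1) return(NA_real_)
  r <- n_spikes / duration_s
  min(max(cfg$adaptive_isi_constant / r, cfg$isi_bounds[1]), cfg$isi_bounds[2])
}

#' Well-level network-burst detection
#'
#' Pools the spikes of the analysed electrodes into one sorted sequence and
#' takes maximal runs in which every consecutive gap is at most the
#' well-adaptive maximum interval ([well_max_isi()]). A run becomes a
#' network burst iff it holds at least `min_spikes` pooled spikes and at
#' least `ceiling(min_electrode_fraction * n_electrodes)` distinct
#' electrodes contribute a spike. `n_electrodes` is the number of analysed
#' (activity-filtered) electrodes, not the physical electrode count:
#' inactive electrodes cannot participate.
#'
#' @param spikes Data frame with `electrode` and `time_s` for one well on
#'   one day (analysis window already applied).
#' @param n_electrodes Number of analysed electrodes in the well.
#' @param duration_s Analysis-window length in seconds.
#' @param cfg A [network_burst_config()].
#' @param max_isi Override of the adaptive maximum interval (mainly for
#'   tests); default computed from the data.
#' @return Tibble with one row per network burst: `start_s`, `end_s`,
#'   `n_spikes` (pooled), `n_electrodes` (distinct participants), and
#'   `first`/`last` (1-based index range of member spikes in the
#'   time-sorted pooled train).
#' @export
detect_network_bursts <- function(spikes, n_electrodes, duration_s,
                                  cfg = network_burst_config(),
                                  max_isi = NULL) {
  stopifnot(inherits(cfg, "network_burst_config"))
  empty <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          n_spikes = integer(0), n_electrodes = integer(0),
                          first = integer(0), last = integer(0))
  n <- nrow(spikes)
  if (n == 0) return(empty)
  o <- order(spikes$time_s)
  tt <- spikes$time_s[o]
  el <- as.integer(factor(spikes$electrode[o]))
  nb <- nb_runs(tt, el, n_electrodes, duration_s, cfg, max_isi = max_isi)
  tibble::tibble(start_s = nb$start, end_s = nb$end,
                 n_spikes = nb$n, n_electrodes = nb$n_el,
                 first = nb$first, last = nb$last)
}
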