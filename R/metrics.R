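#' Restrict a recording to its analysis window
#'
#' Analysis uses the last `window_s` seconds (default 20 min) of the
#' recording, the most stable stretch of a 30-min session. Spikes before
#' `duration_s - window_s` are dropped and times are re-anchored so the
#' window starts at 0. Recordings shorter than the window are used in full
#' with a warning.
#'
#' @param spikes Data frame with a `time_s` column (one well-recording).
#' @param duration_s Total recording duration in seconds.
#' @param window_s Analysis-window length in seconds (default 1200).
#' @return A list: `spikes` (filtered, re-anchored tibble) and `duration_s`
#'   (the effective window length).
#' @export
#' @examples
#' sp <- tibble::tibble(electrode = 1L, time_s = c(300, 900))
#' analysis_window(sp, 1800)$spikes$time_s  # 300 (was 900)
analysis_window <- function(spikes, duration_s, window_s = 1200) {
  stopifnot(duration_s > 0, window_s > 0)
  if (duration_s < window_s) {
    warning("recording shorter than the analysis window; using full duration",
            call. = FALSE)
    window_s <- duration_s
  }
  cut <- duration_s - window_s
  out <- dplyr::filter(spikes, .data$time_s >= cut)
  out$time_s <- out$time_s - cut
  list(spikes = tibble::as_tibble(out), duration_s = window_s)
}

#' Cross-correlation synchrony of a well
#'
#' For every unordered pair of eligible electrodes (each with at least
#' `min_spikes` spikes), spike trains are compared through their
#' cross-correlogram over lags up to `max_lag` in bins of `bin_s`: the pair
#' score is the total correlogram area, i.e. the number of spike pairs with
#' lag inside the window, normalized by `sqrt(n_x * n_y)` so two identical
#' trains give a zero-lag peak of exactly 1. The well score is the mean over
#' pairs, clamped to \[0, 1\]. With fewer than two eligible electrodes the
#' score is undefined (`NA`).
#'
#' Under independence the expected pair score has the closed form
#' `sqrt(n_x * n_y) * (2 * halfwidth) / T` with
#' `halfwidth = max_lag + bin_s / 2`, which [synchrony_chance_level()]
#' exposes for testing.
#'
#' @param spikes Data frame with `electrode` and `time_s` (one
#'   well-recording, analysis window applied).
#' @param duration_s Window length in seconds.
#' @param bin_s Correlogram bin width in seconds (default 0.005).
#' @param max_lag_s Maximum lag in seconds (default 0.1).
#' @param min_spikes Minimum spikes per electrode to enter a pair
#'   (default 10).
#' @return Scalar in \[0, 1\], or `NA_real_` when undefined.
#' @export
synchrony_auc <- function(spikes, duration_s, bin_s = 0.005, max_lag_s = 0.1,
                          min_spikes = 10) {
  trains <- split(spikes$time_s, spikes$electrode)
  trains <- trains[vapply(trains, length, integer(1)) >= min_spikes]
  if (length(trains) < 2) return(NA_real_)
  trains <- lapply(trains, sort)
  hw <- max_lag_s + bin_s / 2
  ids <- seq_along(trains)
  scores <- numeric(0)
  for (a in ids[-length(ids)]) {
    for (b in (a + 1):length(ids)) {
      x <- trains[[a]]; y <- trains[[b]]
      scores <- c(scores,
                  count_close_pairs(x, y, hw) / sqrt(length(x) * length(y)))
    }
  }
  min(max(mean(scores), 0), 1)
}

#' @rdname synchrony_auc
#' @param n_x,n_y Spike counts of the two trains.
#' @export
synchrony_chance_level <- function(n_x, n_y, duration_s, bin_s = 0.005,
                                   max_lag_s = 0.1) {
  sqrt(n_x * n_y) * 2 * (max_lag_s + bin_s / 2) / duration_s
}

#' The ten per-well activity parameters
#'
#' Computes, for one well-recording whose detections have already been run
#' on the analysis window, the well-level parameter set: pooled spike count,
#' burst and network-burst counts, mean burst and network-burst durations,
#' mean inter-burst interval (end of one burst to start of the next on the
#' same electrode, pooled across electrodes), mean spikes per burst and per
#' network burst, mean inter-spike interval within network bursts (mean
#' consecutive pooled-spike interval inside each network burst, averaged
#' over network bursts), and the cross-correlation synchrony score. Any mean
#' over an empty set is `NA` (undefined), never 0.
#'
#' @param spikes Analysis-window spike table (`electrode`, `time_s`),
#'   already restricted to included electrodes.
#' @param bursts Output of [well_bursts()].
#' @param network_bursts Output of [detect_network_bursts()] on the same
#'   pooled train.
#' @param duration_s Analysis-window length in seconds.
#' @param synchrony Pre-computed [synchrony_auc()] value; computed here when
#'   `NULL`.
#' @return One-row tibble with the ten parameters plus
#'   `n_bursting_electrodes` (electrodes with at least one burst, used for
#'   well inclusion) and `n_active_electrodes`.
#' @export
compute_well_metrics <- function(spikes, bursts, network_bursts, duration_s,
                                 synchrony = NULL) {
  mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

  ibi <- unlist(lapply(split(bursts, bursts$electrode), function(b) {
    if (nrow(b) < 2) return(numeric(0))
    b <- b[order(b$start_s), ]
    b$start_s[-1] - b$end_s[-nrow(b)]
  }), use.names = FALSE)

  # mean consecutive pooled-spike interval inside a network burst is its
  # span over (count - 1)
  nb_isi <- with(network_bursts,
                 ifelse(n_spikes >= 2, (end_s - start_s) / (n_spikes - 1),
                        NA_real_))

  if (is.null(synchrony)) synchrony <- synchrony_auc(spikes, duration_s)

  tibble::tibble(
    n_spikes = nrow(spikes),
    n_bursts = nrow(bursts),
    n_network_bursts = nrow(network_bursts),
    burst_duration_s = mean_or_na(bursts$end_s - bursts$start_s),
    network_burst_duration_s =
      mean_or_na(network_bursts$end_s - network_bursts$start_s),
    inter_burst_interval_s = mean_or_na(ibi),
    spikes_per_burst = mean_or_na(bursts$n_spikes),
    spikes_per_network_burst = mean_or_na(as.numeric(network_bursts$n_spikes)),
    mean_isi_within_network_bursts_s = mean_or_na(nb_isi[!is.na(nb_isi)]),
    synchrony_auc = synchrony,
    n_bursting_electrodes = length(unique(bursts$electrode)),
    n_active_electrodes = length(unique(spikes$electrode))
  )
}

#' Names of the ten activity parameters
#' @return Character vector of the metric column names.
#' @export
metric_names <- function() {
  c("n_spikes", "n_bursts", "n_network_bursts", "burst_duration_s",
    "network_burst_duration_s", "inter_burst_interval_s", "spikes_per_burst",
    "spikes_per_network_burst", "mean_isi_within_network_bursts_s",
    "synchrony_auc")
}

#' Detection and metrics for a whole spike-list dataset
#'
#' The per-well driver of the pipeline: for every (experiment, plate, well,
#' div) it applies the analysis window, the activity-based electrode filter,
#' Poisson-surprise burst detection, adaptive network-burst detection, and
#' [compute_well_metrics()], then joins the plate-map condition columns.
#'
#' @param spikes Spike-list tibble (`experiment`, `plate`, `well`,
#'   `electrode`, `time_s`, `div`), e.g. from [simulate_experiment()] or
#'   [read_spike_list()].
#' @param plate_map Plate-map tibble (`experiment`, `plate`, `well`,
#'   `compound`, `concentration_uM`, `sex`).
#' @param recording_duration_s Full recording length, seconds (default 1800).
#' @param window_s Analysis-window length, seconds (default 1200).
#' @param burst_cfg,nb_cfg Detection configurations.
#' @param min_rate_per_min Electrode-inclusion threshold (default 6/min).
#' @return A `mea_metrics` tibble: one row per (experiment, plate, well,
#'   div) with condition columns and the ten parameters. Wells present in
#'   the plate map but silent on a day still get a row (zero counts,
#'   undefined means).
#' @export
mea_metrics <- function(spikes, plate_map,
                        recording_duration_s = 1800, window_s = 1200,
                        burst_cfg = burst_config(),
                        nb_cfg = network_burst_config(),
                        min_rate_per_min = 6) {
  known <- as.numeric(plate_map$plate) * 1e5 + as.numeric(plate_map$well)
  seen <- unique(as.numeric(spikes$plate) * 1e5 + as.numeric(spikes$well))
  if (!all(seen %in% known))
    stop("spike list references wells absent from the plate map",
         call. = FALSE)
  if (recording_duration_s < window_s) {
    warning("recording shorter than the analysis window; using full duration",
            call. = FALSE)
    window_s <- recording_duration_s
  }

  grid <- tidyr::expand_grid(
    plate_map[c("experiment", "plate", "well", "compound",
                "concentration_uM", "sex")],
    div = sort(unique(spikes$div))
  )

  # one global sort into (recording, electrode, time) order, then slice;
  # far cheaper than per-recording data-frame splits at plate scale
  el_levels <- sort(unique(spikes$electrode))
  eli <- match(spikes$electrode, el_levels)
  key <- (as.numeric(spikes$plate) * 1e5 + as.numeric(spikes$well)) * 1e3 +
    as.numeric(spikes$div)
  o <- order(key, eli, spikes$time_s)
  kk <- key[o]
  eli <- eli[o]
  tts <- spikes$time_s[o]
  nsp <- length(kk)
  g_start <- which(c(TRUE, kk[-1] != kk[-nsp]))
  g_end <- c(g_start[-1] - 1L, nsp)
  gkey <- kk[g_start]
  gi <- match((as.numeric(grid$plate) * 1e5 + as.numeric(grid$well)) * 1e3 +
                as.numeric(grid$div), gkey)

  cut <- recording_duration_s - window_s
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    i <- gi[r]
    if (is.na(i)) {
      el <- integer(0); tt <- numeric(0)
    } else {
      idx <- g_start[i]:g_end[i]
      el <- eli[idx]; tt <- tts[idx]
    }
    # analysis window
    keep <- tt >= cut
    el <- el[keep]; tt <- tt[keep] - cut
    # activity-based electrode inclusion
    cnt <- tabulate(el, nbins = length(el_levels))
    incl <- which(cnt / (window_s / 60) >= min_rate_per_min)
    mask <- rep(FALSE, length(el_levels)); mask[incl] <- TRUE
    keep <- mask[el]
    el <- el[keep]; tt <- tt[keep]

    m <- well_metrics_core(el, tt, n_included = length(incl),
                           duration_s = window_s, burst_cfg = burst_cfg,
                           nb_cfg = nb_cfg)
    rows[[r]] <- m
  }
  met <- do.call(rbind, rows)
  res <- dplyr::bind_cols(grid, tibble::as_tibble(met))
  class(res) <- c("mea_metrics", class(res))
  res
}

# detection + the ten parameters for one recording, on flat vectors:
# el = integer electrode indices (grouped, times sorted within electrode),
# tt = spike times within the analysis window. Returns a named numeric row.
well_metrics_core <- function(el, tt, n_included, duration_s, burst_cfg,
                              nb_cfg) {
  mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  nsp <- length(tt)

  # per-electrode slices
  if (nsp > 0) {
    s0 <- which(c(TRUE, el[-1] != el[-nsp]))
    s1 <- c(s0[-1] - 1L, nsp)
  } else {
    s0 <- s1 <- integer(0)
  }

  # Poisson-surprise bursts per electrode
  b_el <- integer(0); b_start <- b_end <- b_surp <- numeric(0)
  b_n <- integer(0)
  for (k in seq_along(s0)) {
    trk <- tt[s0[k]:s1[k]]
    if (length(trk) < burst_cfg$min_spikes_per_burst) next
    res <- ls_burst_scan(trk, length(trk) / duration_s, burst_cfg$s_min,
                         burst_cfg$min_spikes_per_burst,
                         burst_cfg$seed_isi_factor, burst_cfg$lookahead)
    if (nrow(res) == 0) next
    b_el <- c(b_el, rep.int(el[s0[k]], nrow(res)))
    b_start <- c(b_start, trk[res$first])
    b_end <- c(b_end, trk[res$last])
    b_n <- c(b_n, res$last - res$first + 1L)
    b_surp <- c(b_surp, res$surprise)
  }

  # inter-burst intervals within electrode (bursts are in time order)
  ibi <- numeric(0)
  if (length(b_el) >= 2) {
    same <- b_el[-1] == b_el[-length(b_el)]
    ibi <- (b_start[-1] - b_end[-length(b_el)])[same]
  }

  # network bursts on the pooled, time-sorted train
  ot <- order(tt)
  ts <- tt[ot]; es <- el[ot]
  nb <- nb_runs(ts, es, n_included, duration_s, nb_cfg)

  # synchrony over electrode pairs with >= 10 spikes
  elig <- which((s1 - s0 + 1L) >= 10)
  syn <- NA_real_
  if (length(elig) >= 2) {
    hw <- 0.1 + 0.005 / 2
    scores <- numeric(0)
    for (a in seq_len(length(elig) - 1)) {
      for (b in (a + 1):length(elig)) {
        ia <- elig[a]; ib <- elig[b]
        na <- s1[ia] - s0[ia] + 1L; nb_ <- s1[ib] - s0[ib] + 1L
        scores <- c(scores,
                    count_close_pairs(tt[s0[ia]:s1[ia]], tt[s0[ib]:s1[ib]],
                                      hw) / sqrt(na * nb_))
      }
    }
    syn <- min(max(mean(scores), 0), 1)
  }

  c(n_spikes = nsp,
    n_bursts = length(b_el),
    n_network_bursts = length(nb$start),
    burst_duration_s = mean_or_na(b_end - b_start),
    network_burst_duration_s = mean_or_na(nb$end - nb$start),
    inter_burst_interval_s = mean_or_na(ibi),
    spikes_per_burst = mean_or_na(as.numeric(b_n)),
    spikes_per_network_burst = mean_or_na(as.numeric(nb$n)),
    mean_isi_within_network_bursts_s =
      mean_or_na(((nb$end - nb$start) / (nb$n - 1))[nb$n >= 2]),
    synchrony_auc = syn,
    n_bursting_electrodes = length(unique(b_el)),
    n_active_electrodes = n_included)
}

# network-burst runs on a pooled time-sorted train; returns flat vectors
# (plus the member index range per run)
nb_runs <- function(ts, es, n_electrodes, duration_s, cfg, max_isi = NULL) {
  n <- length(ts)
  out0 <- list(start = numeric(0), end = numeric(0), n = integer(0),
               n_el = integer(0), first = integer(0), last = integer(0))
  if (n == 0) return(out0)
  if (is.null(max_isi)) max_isi <- well_max_isi(n, duration_s, cfg)
  if (is.na(max_isi)) return(out0)
  brk <- which(diff(ts) > max_isi)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  keep <- which((ends - starts + 1L) >= cfg$min_spikes)
  if (length(keep) == 0) return(out0)
  starts <- starts[keep]; ends <- ends[keep]
  need_el <- ceiling(cfg$min_electrode_fraction * n_electrodes)
  run_of <- rep(0L, n)
  for (k in seq_along(starts)) run_of[starts[k]:ends[k]] <- k
  m <- max(es)
  u <- unique((run_of * (m + 1L) + es)[run_of > 0L])
  n_part <- tabulate(u %/% (m + 1L), nbins = length(starts))
  ok <- n_part >= need_el
  list(start = ts[starts[ok]], end = ts[ends[ok]],
       n = as.integer(ends[ok] - starts[ok] + 1L),
       n_el = as.integer(n_part[ok]),
       first = starts[ok], last = ends[ok])
}
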