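#' Burst-detection configuration (Poisson surprise)
#'
#' @param s_min Minimum surprise, in nats, for an accepted burst
#'   (default 10).
#' @param min_spikes_per_burst Minimum spikes per burst (default 3,
#'   must be >= 2).
#' @param seed_isi_factor Fraction of the train's mean inter-spike interval
#'   below which consecutive ISIs seed a candidate burst (default 0.5).
#' @param lookahead Spikes of forward lookahead during burst extension
#'   (default 10).
#' @return An object of class `burst_config`.
#' @export
burst_config <- function(s_min = 10, min_spikes_per_burst = 3,
                         seed_isi_factor = 0.5, lookahead = 10) {
  stopifnot(s_min > 0, min_spikes_per_burst >= 2, seed_isi_factor > 0,
            lookahead >= 1)
  structure(list(s_min = s_min,
                 min_spikes_per_burst = as.integer(min_spikes_per_burst),
                 seed_isi_factor = seed_isi_factor,
                 lookahead = as.integer(lookahead)),
            class = "burst_config")
}

#' Poisson surprise of a spike cluster
#'
#' The surprise of observing `n` spikes in `interval_s` seconds on a train
#' with mean rate `rate_hz` is `S = -ln P(X >= n)` with
#' `X ~ Poisson(rate_hz * interval_s)`. Evaluated in the log domain, so S is
#' accurate far beyond 700 nats. `n = 0` gives S = 0 (the tail probability
#' is 1); a zero-length interval holding spikes has surprise capped at 1e9.
#'
#' @param n_spikes Spike count(s) (>= 0).
#' @param interval_s Cluster duration(s), seconds (>= 0).
#' @param rate_hz Train mean rate, spikes/s (> 0).
#' @return Numeric surprise value(s) in nats, >= 0.
#' @export
#' @examples
#' poisson_surprise(10, 1, 1)   # -log P(Poisson(1) >= 10)
poisson_surprise <- function(n_spikes, interval_s, rate_hz) {
  if (any(rate_hz <= 0)) stop("rate_hz must be > 0", call. = FALSE)
  if (any(n_spikes < 0) || any(interval_s < 0))
    stop("n_spikes and interval_s must be >= 0", call. = FALSE)
  lambda <- rate_hz * interval_s
  s <- -ppois(n_spikes - 1, lambda, lower.tail = FALSE, log.p = TRUE)
  s[n_spikes == 0] <- 0
  pmin(pmax(s, 0), 1e9)
}

#' Single-electrode burst detection by the Poisson surprise method
#'
#' Implements the classic surprise-maximization scan: candidate bursts are
#' seeded on runs of at least two consecutive inter-spike intervals shorter
#' than `seed_isi_factor` times the train's mean ISI, extended spike-by-spike
#' at the right edge (with a lookahead horizon) while the surprise strictly
#' increases, and trimmed at the left edge while the surprise strictly
#' increases, iterating to a fixed point. A candidate is accepted when its
#' surprise reaches `s_min` and it holds at least `min_spikes_per_burst`
#' spikes; the scan resumes after the accepted burst, so bursts are disjoint
#' and time-ordered. Ties prefer the shorter burst (strict improvement is
#' required to grow).
#'
#' The train's mean rate is `length(times) / (window[2] - window[1])`: the
#' observation window, not the span of the spikes, defines the null rate.
#'
#' @param times Strictly increasing spike times in seconds.
#' @param window Length-2 analysis window `(start_s, end_s)` containing the
#'   spikes.
#' @param cfg A [burst_config()].
#' @return A tibble with one row per burst: `first`, `last` (1-based spike
#'   indices, inclusive), `start_s`, `end_s`, `n_spikes`, `surprise`.
#'   Empty or near-empty trains yield zero rows.
#' @export
detect_bursts <- function(times, window = range(times), cfg = burst_config()) {
  stopifnot(inherits(cfg, "burst_config"))
  n <- length(times)
  empty <- tibble::tibble(first = integer(0), last = integer(0),
                          start_s = numeric(0), end_s = numeric(0),
                          n_spikes = integer(0), surprise = numeric(0))
  if (n < cfg$min_spikes_per_burst) return(empty)
  span <- diff(window)
  if (!is.finite(span) || span <= 0) return(empty)
  rate <- n / span
  res <- ls_burst_scan(times, rate, cfg$s_min, cfg$min_spikes_per_burst,
                       cfg$seed_isi_factor, cfg$lookahead)
  if (nrow(res) == 0) return(empty)
  tibble::tibble(first = as.integer(res$first), last = as.integer(res$last),
                 start_s = times[res$first], end_s = times[res$last],
                 n_spikes = as.integer(res$last - res$first + 1L),
                 surprise = res$surprise)
}

#' Exhaustive burst-detection oracle
#'
#' Test oracle: scores every contiguous spike subsequence with
#' [poisson_surprise()] and greedily accepts non-overlapping subsequences in
#' order of decreasing surprise until none with `S >= s_min` remain.
#' Quadratic in the number of spikes, so restricted to short trains.
#'
#' @inheritParams detect_bursts
#' @param max_spikes Guard on the train length (default 200).
#' @return Same shape as [detect_bursts()], rows in time order.
#' @export
brute_force_bursts <- function(times, window = range(times),
                               cfg = burst_config(), max_spikes = 200) {
  stopifnot(inherits(cfg, "burst_config"))
  n <- length(times)
  if (n > max_spikes) stop("train too long for the exhaustive oracle",
                           call. = FALSE)
  empty <- tibble::tibble(first = integer(0), last = integer(0),
                          start_s = numeric(0), end_s = numeric(0),
                          n_spikes = integer(0), surprise = numeric(0))
  if (n < cfg$min_spikes_per_burst) return(empty)
  span <- diff(window)
  if (!is.finite(span) || span <= 0) return(empty)
  rate <- n / span

  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) j - i + 1 >= cfg$min_spikes_per_burst),
               arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  s <- poisson_surprise(j - i + 1, times[j] - times[i], rate)
  keep <- s >= cfg$s_min
  i <- i[keep]; j <- j[keep]; s <- s[keep]
  # greedy: descending S, shorter first on ties, then earlier
  o <- order(-s, j - i, i)
  i <- i[o]; j <- j[o]; s <- s[o]
  taken <- rep(FALSE, n)
  first <- integer(0); last <- integer(0); surp <- numeric(0)
  for (k in seq_along(i)) {
    if (any(taken[i[k]:j[k]])) next
    taken[i[k]:j[k]] <- TRUE
    first <- c(first, i[k]); last <- c(last, j[k]); surp <- c(surp, s[k])
  }
  o <- order(first)
  tibble::tibble(first = first[o], last = last[o],
                 start_s = times[first[o]], end_s = times[last[o]],
                 n_spikes = last[o] - first[o] + 1L,
                 surprise = surp[o])
}

#' Burst table for all electrodes of one well-recording
#'
#' Runs [detect_bursts()] on each included electrode of a single
#' well-recording and stacks the results.
#'
#' @param spikes Data frame with `electrode` and `time_s` for one well on
#'   one day.
#' @param window Length-2 analysis window in seconds.
#' @param electrodes Electrode ids to analyse (default: all present).
#' @param cfg A [burst_config()].
#' @return Tibble: `electrode`, `first`, `last`, `start_s`, `end_s`,
#'   `n_spikes`, `surprise`.
#' @export
well_bursts <- function(spikes, window, electrodes = NULL,
                        cfg = burst_config()) {
  if (is.null(electrodes)) electrodes <- sort(unique(spikes$electrode))
  by_el <- split(spikes$time_s, factor(spikes$electrode, levels = electrodes))
  span <- diff(window)
  parts <- lapply(seq_along(electrodes), function(k) {
    tt <- sort(by_el[[k]])
    n <- length(tt)
    if (n < cfg$min_spikes_per_burst || !is.finite(span) || span <= 0)
      return(NULL)
    res <- ls_burst_scan(tt, n / span, cfg$s_min, cfg$min_spikes_per_burst,
                         cfg$seed_isi_factor, cfg$lookahead)
    if (nrow(res) == 0) return(NULL)
    list(electrode = rep(electrodes[k], nrow(res)),
         first = as.integer(res$first), last = as.integer(res$last),
         start_s = tt[res$first], end_s = tt[res$last],
         surprise = res$surprise)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  pull <- function(f) unlist(lapply(parts, `[[`, f), use.names = FALSE)
  first <- as.integer(pull("first")); last <- as.integer(pull("last"))
  tibble::tibble(
    electrode = pull("electrode") %||% integer(0),
    first = first %||% integer(0), last = last %||% integer(0),
    start_s = pull("start_s") %||% numeric(0),
    end_s = pull("end_s") %||% numeric(0),
    n_spikes = if (length(first)) last - first + 1L else integer(0),
    surprise = pull("surprise") %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
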