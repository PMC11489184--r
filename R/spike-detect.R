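#' Spike-detection configuration
#'
#' Parameters of the raw-trace front end: band-pass edges, the threshold
#' multiplier on the robust noise estimate, the pre/post spike window and the
#' rolling noise-estimation window.
#'
#' @param threshold_k Threshold as a multiple of the per-electrode noise SD
#'   (default 7).
#' @param band Length-2 band-pass edges in Hz (default `c(200, 5000)`).
#' @param pre_spike_s,post_spike_s Pre/post spike durations in seconds
#'   (defaults 0.0024 and 0.0036). `post_spike_s` doubles as the dead time
#'   after an accepted spike.
#' @param noise_window_s Window length of the rolling noise estimate,
#'   seconds (default 10).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(threshold_k = 7, band = c(200, 5000),
                             pre_spike_s = 0.0024, post_spike_s = 0.0036,
                             noise_window_s = 10) {
  stopifnot(threshold_k > 0, length(band) == 2, band[1] > 0,
            band[2] > band[1], pre_spike_s >= 0, post_spike_s >= 0,
            noise_window_s > 0)
  structure(list(threshold_k = threshold_k, band = as.numeric(band),
                 pre_spike_s = pre_spike_s, post_spike_s = post_spike_s,
                 noise_window_s = noise_window_s),
            class = "detection_config")
}

#' Zero-phase band-pass filter of a raw trace
#'
#' 2nd-order Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), so the output is zero-phase and the same length
#' as the input. DC and slow drift are removed entirely.
#'
#' @param x Numeric voltage trace (finite values).
#' @param fs Sampling rate in Hz (default 12500).
#' @param band Length-2 band edges in Hz; must lie inside the Nyquist range.
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, fs = 12500, band = c(200, 5000)) {
  if (any(!is.finite(x))) stop("trace must be finite", call. = FALSE)
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band must lie strictly inside (0, fs/2)", call. = FALSE)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  # remove the mean first: the passband excludes DC anyway, and centring
  # avoids the forward-backward filter's edge transients on offset traces
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Robust per-electrode noise estimate
#'
#' Rolling estimate of the noise SD (rms of the noise floor): the trace is
#' cut into windows of `window_s` seconds, each window's SD is estimated by
#' the median absolute deviation scaled to Gaussian rms (MAD / 0.6745), and
#' the median across windows is returned. MAD makes the estimate insensitive
#' to a sparse minority of large spikes.
#'
#' @param x Numeric trace (non-empty).
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 10).
#' @return Estimated noise SD (>= 0).
#' @export
estimate_noise <- function(x, fs = 12500, window_s = 10) {
  if (length(x) == 0) stop("trace is empty", call. = FALSE)
  n_win <- max(1L, floor(length(x) / (fs * window_s)))
  size <- ceiling(length(x) / n_win)
  idx <- ceiling(seq_along(x) / size)
  est <- vapply(split(x, idx), function(w) {
    stats::mad(w, center = median(w), constant = 1 / 0.6745)
  }, numeric(1))
  median(est)
}

#' Threshold-crossing spike detection on a filtered trace
#'
#' Detects spikes as crossings of `threshold_k` times the robust noise SD,
#' in either polarity. The spike timestamp is the time of the absolute
#' extremum within the pre/post window around the crossing. After each
#' accepted spike, further crossings within `post_spike_s` are suppressed
#' (dead time), so spike times are separated by at least `post_spike_s`.
#'
#' @param x Filtered numeric trace.
#' @param fs Sampling rate in Hz.
#' @param cfg A [detection_config()].
#' @param sigma Optional noise SD; estimated with [estimate_noise()] when
#'   missing.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
detect_spikes <- function(x, fs = 12500, cfg = detection_config(),
                          sigma = NULL) {
  stopifnot(inherits(cfg, "detection_config"))
  if (length(x) == 0) return(numeric(0))
  if (is.null(sigma)) sigma <- estimate_noise(x, fs, cfg$noise_window_s)
  thr <- cfg$threshold_k * sigma
  if (thr <= 0) return(numeric(0))
  over <- abs(x) >= thr
  if (!any(over)) return(numeric(0))
  # onsets of above-threshold excursions
  onsets <- which(over & !c(FALSE, over[-length(over)]))
  pre_n <- round(cfg$pre_spike_s * fs)
  post_n <- round(cfg$post_spike_s * fs)
  times <- numeric(0)
  last_t <- -Inf
  for (i in onsets) {
    t_cross <- (i - 1) / fs
    if (t_cross - last_t < cfg$post_spike_s) next
    lo <- max(1L, i - pre_n)
    hi <- min(length(x), i + post_n)
    ext <- lo + which.max(abs(x[lo:hi])) - 1L
    t_sp <- (ext - 1) / fs
    if (t_sp - last_t < cfg$post_spike_s) next
    times <- c(times, t_sp)
    last_t <- t_sp
  }
  sort(times)
}

#' Activity-based electrode inclusion
#'
#' An electrode enters the analysis only if it fired at least
#' `min_rate_per_min` spikes per minute over the recording (default 6/min,
#' threshold inclusive).
#'
#' @param spikes A data frame with at least `electrode` and `time_s`
#'   columns (one well), or a named list of numeric spike-time vectors.
#' @param duration_s Recording duration in seconds (> 0).
#' @param min_rate_per_min Inclusion threshold in spikes/minute (default 6).
#' @return Sorted vector of included electrode ids (integer when the input
#'   uses integer ids).
#' @export
#' @examples
#' sp <- tibble::tibble(electrode = rep(1:2, c(180, 10)),
#'                      time_s = runif(190, 0, 1800))
#' active_electrodes(sp, 1800)  # only electrode 1 (6.0/min)
active_electrodes <- function(spikes, duration_s, min_rate_per_min = 6) {
  stopifnot(duration_s > 0)
  if (is.data.frame(spikes)) {
    counts <- table(spikes$electrode)
  } else {
    counts <- vapply(spikes, length, numeric(1))
  }
  rate <- as.numeric(counts) / (duration_s / 60)
  ids <- names(counts)[rate >= min_rate_per_min]
  ids <- type.convert(ids, as.is = TRUE)
  sort(ids)
}
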