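# Deterministic substream seed for (seed, plate, well, div). Mixing by
# multiply-xor keeps the result a valid 32-bit R seed and decorrelates
# neighbouring wells; adding wells or DIVs never perturbs existing ones.
substream_seed <- function(seed, plate, well, div = 0L) {
  h <- (as.double(seed) * 2654435761 + as.double(plate) * 40503 +
        as.double(well) * 2246822519 + as.double(div) * 3266489917) %%
    2147483647
  as.integer(h)
}

# Per-well log-normal rate multiplier, shared across DIVs (drawn from the
# (seed, plate, well) substream only). Mean 1, coefficient of variation cv.
well_multiplier <- function(config, plate, well) {
  cv <- config$well_heterogeneity_cv
  if (cv <= 0) return(1)
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(substream_seed(config$seed, plate, well),
                   rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog))
}

#' Simulate one well-recording
#'
#' Draws the spike trains of all electrodes of one well on one recording day.
#' Network-burst events arrive as a homogeneous Poisson process whose rate is
#' the plateau rate scaled by the developmental ramp, the per-well
#' multiplier, the male network-burst boost (when applicable) and any
#' compound multipliers (applied only when `div >= onset_div` and the sex is
#' in scope). Each event recruits every electrode independently with
#' probability `recruitment_fraction`; a recruited electrode fires a Poisson
#' number of spikes (within-burst rate x a log-normal volley duration)
#' uniformly over its jittered volley. Background spikes are independent
#' homogeneous Poisson processes per electrode. All randomness comes from a
#' substream derived from `(seed, plate, well, div)`, so the same
#' config/seed reproduces the well exactly and adding wells does not disturb
#' existing ones.
#'
#' @param config A [sim_config()].
#' @param div Day in vitro; must be one of `config$recording_days` (or any
#'   non-negative day when `check_div = FALSE`).
#' @param sex `"male"` or `"female"`.
#' @param effect A [compound_effect()]; defaults to the solvent control.
#' @param plate,well Integer ids used for the RNG substream and the output.
#' @param check_div Enforce `div %in% recording_days` (default TRUE).
#' @return A tibble with columns `plate`, `well`, `electrode`, `time_s`
#'   (sorted within electrode), one row per spike. Zero-rate configurations
#'   return zero rows.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7)
#' sp <- simulate_well(cfg, div = 14, sex = "female")
#' nrow(sp)
simulate_well <- function(config, div, sex = c("female", "male"),
                          effect = control_condition(),
                          plate = 1L, well = 1L, check_div = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(effect, "compound_effect"))
  sex <- match.arg(sex)
  if (check_div && !div %in% config$recording_days)
    stop("div must be one of config$recording_days", call. = FALSE)

  d <- development_curve(config, div)
  w <- well_multiplier(config, plate, well)

  m <- list(network_burst_rate = 1, within_burst_rate = 1, burst_duration = 1,
            recruitment = 1, background_rate = 1, onset_jitter = 1)
  applies <- div >= effect$onset_div &&
    (effect$sex_scope == "both" || effect$sex_scope == sex)
  if (applies) m[names(effect$multipliers)] <- effect$multipliers

  nb_rate <- config$baseline_network_burst_rate / 60 * m$network_burst_rate
  if (sex == "male" && div >= config$sex_nb_div_range[1] &&
      div <= config$sex_nb_div_range[2]) {
    nb_rate <- nb_rate * (1 + config$sex_nb_boost)
  }
  bg_rate <- config$background_rate * m$background_rate
  wb_rate <- config$within_burst_rate * m$within_burst_rate
  dur_med <- config$burst_duration_s * m$burst_duration
  recruit <- min(1, config$recruitment_fraction * m$recruitment)
  jit_sd <- config$onset_jitter_sd_s * m$onset_jitter

  dur_s <- config$recording_duration_s
  n_el <- config$electrodes_per_well

  withr::with_seed(substream_seed(config$seed, plate, well, div), {
    el <- integer(0); tt <- numeric(0)

    # network-burst events, fully vectorized over (event, electrode) pairs
    n_ev <- rpois(1, nb_rate * d * w * dur_s)
    if (n_ev > 0) {
      ev_t <- sort(runif(n_ev, 0, dur_s))
      rec <- which(runif(n_ev * n_el) < recruit)  # pair index, event-major
      if (length(rec) > 0) {
        p_ev <- (rec - 1L) %/% n_el + 1L
        p_el <- (rec - 1L) %% n_el + 1L
        vol_dur <- rlnorm(length(rec), log(dur_med),
                          config$burst_duration_sdlog)
        n_sp <- rpois(length(rec), wb_rate * vol_dur)
        t0 <- ev_t[p_ev] + rnorm(length(rec), 0, jit_sd)
        tot <- sum(n_sp)
        if (tot > 0) {
          tt <- rep.int(t0, n_sp) + runif(tot) * rep.int(vol_dur, n_sp)
          el <- rep.int(p_el, n_sp)
        }
      }
    }

    # tonic background, per electrode
    lam_bg <- bg_rate * d * w * dur_s
    if (lam_bg > 0) {
      n_bg <- rpois(n_el, lam_bg)
      tt <- c(tt, runif(sum(n_bg), 0, dur_s))
      el <- c(el, rep.int(seq_len(n_el), n_bg))
    }

    keep <- tt >= 0 & tt <= dur_s
    tt <- tt[keep]; el <- el[keep]
    o <- order(el, tt)
    tibble::tibble(plate = as.integer(plate), well = as.integer(well),
                   electrode = as.integer(el[o]), time_s = tt[o])
  })
}

#' Build a plate design
#'
#' Assigns one condition per well, the study's design constraint (a well is
#' exposed to exactly one concentration of one compound). Conditions are
#' recycled in blocks over the wells of each plate, and sexes split plates in
#' half by default so both sexes and per-sex solvent controls are present.
#'
#' @param config A [sim_config()].
#' @param effects List of [compound_effect()] objects (include
#'   [control_condition()] for solvent wells).
#' @param experiment Experiment id string.
#' @return A tibble (plate map) with columns `experiment`, `plate`, `well`,
#'   `compound`, `concentration_uM`, `sex`, and a list-column `effect`.
#' @export
plate_design <- function(config, effects = list(control_condition()),
                         experiment = "sim") {
  stopifnot(inherits(config, "sim_config"))
  ok <- vapply(effects, inherits, logical(1), "compound_effect")
  if (!all(ok)) stop("effects must be compound_effect objects", call. = FALSE)
  n_w <- config$wells_per_plate
  n_cond <- length(effects)
  purrr::map_dfr(seq_len(config$n_plates), function(p) {
    well <- seq_len(n_w)
    sex <- ifelse(well <= n_w / 2, "male", "female")
    # within each sex block, recycle conditions
    idx <- unlist(lapply(split(well, sex), function(wv) {
      rep_len(seq_len(n_cond), length(wv))
    })[unique(sex)], use.names = FALSE)
    eff <- effects[idx]
    tibble::tibble(
      experiment = experiment, plate = as.integer(p), well = as.integer(well),
      compound = vapply(eff, function(e) e$compound, character(1)),
      concentration_uM = vapply(eff, function(e) e$concentration, numeric(1)),
      sex = sex, effect = eff
    )
  })
}

#' Simulate a full MEA experiment
#'
#' Runs [simulate_well()] for every well of a plate map on every recording
#' day and returns the spike list plus the plate map in the pipeline's
#' canonical tabular formats.
#'
#' @param config A [sim_config()].
#' @param design A plate map from [plate_design()], or a list of
#'   [compound_effect()]s (then a design is built with defaults).
#' @param out_dir Optional directory; when given, `spike_list.csv` and
#'   `plate_map.csv` are written there (see [write_spike_list()]).
#' @return A list with `spikes` (tibble: experiment, plate, well, electrode,
#'   time_s, div) and `plate_map` (tibble: experiment, plate, well, compound,
#'   concentration_uM, sex).
#' @export
#' @examples
#' cfg <- sim_config(wells_per_plate = 4, recording_days = c(7L, 10L), seed = 2)
#' ex <- simulate_experiment(cfg)
#' dplyr::count(ex$spikes, div)
simulate_experiment <- function(config, design = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(design)) design <- plate_design(config)
  if (is.list(design) && !is.data.frame(design))
    design <- plate_design(config, effects = design)
  if (any(design$well > config$wells_per_plate) ||
      any(design$plate > config$n_plates))
    stop("design references a well/plate outside the configured plate",
         call. = FALSE)
  if (anyDuplicated(design[c("plate", "well")]))
    stop("each well must carry exactly one condition", call. = FALSE)

  spikes <- purrr::map_dfr(config$recording_days, function(dv) {
    purrr::map_dfr(seq_len(nrow(design)), function(i) {
      sp <- simulate_well(config, div = dv, sex = design$sex[i],
                          effect = design$effect[[i]],
                          plate = design$plate[i], well = design$well[i])
      sp$div <- as.integer(dv)
      sp
    })
  })
  spikes <- dplyr::mutate(spikes, experiment = design$experiment[1],
                          .before = 1)
  plate_map <- dplyr::select(design, -"effect")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_spike_list(spikes, file.path(out_dir, "spike_list.csv"))
    readr::write_csv(plate_map, file.path(out_dir, "plate_map.csv"))
  }
  list(spikes = spikes, plate_map = plate_map)
}
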