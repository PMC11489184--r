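test_that("analysis window keeps the last 20 minutes and re-anchors times", {
  sp <- tibble::tibble(electrode = 1L, time_s = c(300, 900))
  win <- analysis_window(sp, 1800)
  expect_equal(win$spikes$time_s, 300)  # the 900 s spike, re-anchored
  expect_equal(win$duration_s, 1200)
  expect_equal(nrow(analysis_window(sp[0, ], 1800)$spikes), 0)
  late <- tibble::tibble(electrode = 1L, time_s = seq(700, 1700, by = 100))
  expect_equal(nrow(analysis_window(late, 1800)$spikes), nrow(late))
  expect_warning(win2 <- analysis_window(sp, 900), "shorter")
  expect_equal(win2$duration_s, 900)
})

test_that("the ten parameters reproduce hand-computed fixture arithmetic", {
  # two bursts of 5 spikes (durations 0.1 and 0.3 s) on one electrode
  sp <- tibble::tibble(
    electrode = rep(1L, 10),
    time_s = c(seq(10, 10.1, length.out = 5), seq(50, 50.3, length.out = 5)))
  bursts <- tibble::tibble(electrode = 1L, first = c(1L, 6L), last = c(5L, 10L),
                           start_s = c(10, 50), end_s = c(10.1, 50.3),
                           n_spikes = c(5L, 5L), surprise = c(20, 20))
  nb0 <- detect_network_bursts(sp[0, ], 16, 1200)
  m <- compute_well_metrics(sp, bursts, nb0, 1200)
  expect_equal(m$n_bursts, 2)
  expect_equal(m$spikes_per_burst, 5)
  expect_equal(m$burst_duration_s, 0.2)
  expect_equal(m$inter_burst_interval_s, 50 - 10.1)
  expect_equal(m$n_network_bursts, 0)
  expect_true(is.na(m$network_burst_duration_s))
  expect_true(is.na(m$spikes_per_network_burst))
  expect_equal(m$n_bursting_electrodes, 1)
  # one network burst of 40 spikes spanning 0.5 s
  sp2 <- tibble::tibble(electrode = rep_len(1:4, 40),
                        time_s = seq(100, 100.5, length.out = 40))
  nb <- detect_network_bursts(sp2, 16, 1200, max_isi = 0.1)
  m2 <- compute_well_metrics(sp2, bursts[0, ], nb, 1200)
  expect_equal(m2$n_network_bursts, 1)
  expect_equal(m2$spikes_per_network_burst, 40)
  expect_equal(m2$network_burst_duration_s, 0.5)
  expect_equal(m2$mean_isi_within_network_bursts_s, 0.5 / 39)
})

test_that("synchrony is 1 for identical trains, undefined for one electrode, chance-level for independent ones", {
  tr <- sort(runif(50, 0, 600))
  sp <- tibble::tibble(electrode = rep(1:4, each = 50), time_s = rep(tr, 4))
  expect_equal(synchrony_auc(sp, 600), 1)
  one <- tibble::tibble(electrode = 1L, time_s = tr)
  expect_true(is.na(synchrony_auc(one, 600)))
  # independent Poisson trains: mean score near the closed-form chance level
  set.seed(77)
  n_sim <- 100
  scores <- replicate(n_sim, {
    a <- poisson_train(2, 300); b <- poisson_train(2, 300)
    synchrony_auc(tibble::tibble(electrode = rep(1:2, c(length(a), length(b))),
                                 time_s = c(a, b)), 300)
  })
  chance <- synchrony_chance_level(600, 600, 300)
  expect_lt(abs(mean(scores) - chance),
            3 * sd(scores) / sqrt(n_sim) + 0.2 * chance)
})

test_that("metrics are invariant under electrode relabeling and conserve spikes", {
  cfg <- tiny_config(seed = 13)
  sp <- simulate_well(cfg, 10, "female")
  aw <- analysis_window(sp, cfg$recording_duration_s)
  run <- function(spk) {
    keep <- active_electrodes(spk, aw$duration_s)
    spk <- dplyr::filter(spk, electrode %in% keep)
    b <- well_bursts(spk, c(0, aw$duration_s), electrodes = keep)
    nb <- detect_network_bursts(spk, length(keep), aw$duration_s)
    compute_well_metrics(spk, b, nb, aw$duration_s)
  }
  m1 <- run(aw$spikes)
  relabeled <- dplyr::mutate(aw$spikes, electrode = 17L - electrode)
  m2 <- run(relabeled)
  expect_equal(m1[metric_names()], m2[metric_names()], tolerance = 1e-12)
  # conservation whenever both defined
  b <- well_bursts(aw$spikes, c(0, aw$duration_s))
  expect_lte(sum(b$n_spikes), nrow(aw$spikes))
})

test_that("raising simulator recruitment raises mean synchrony", {
  base <- list(seed = 17, well_heterogeneity_cv = 0)
  syn_at <- function(p) {
    cfg <- do.call(sim_config, c(base, list(recruitment_fraction = p)))
    mean(vapply(1:5, function(w) {
      sp <- simulate_well(cfg, 21, "female", well = w)
      aw <- analysis_window(sp, cfg$recording_duration_s)
      synchrony_auc(aw$spikes, aw$duration_s)
    }, numeric(1)))
  }
  vals <- vapply(c(0.05, 0.15, 0.3), syn_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the metrics driver produces one row per well-recording and validates wells", {
  cfg <- tiny_config(seed = 19)
  ex <- simulate_experiment(cfg)
  m <- mea_metrics(ex$spikes, ex$plate_map)
  expect_s3_class(m, "mea_metrics")
  expect_equal(nrow(m), cfg$wells_per_plate * length(cfg$recording_days))
  expect_true(all(metric_names() %in% names(m)))
  expect_true(all(m$n_spikes >= 0))
  bad <- dplyr::mutate(ex$spikes, well = well + 100L)
  expect_error(mea_metrics(bad, ex$plate_map), "absent")
})
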