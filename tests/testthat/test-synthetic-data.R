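test_that("development curve is 0 before onset, 1 from the plateau, smooth between", {
  cfg <- sim_config(seed = 1)
  expect_equal(development_curve(cfg, 0), 0)
  expect_equal(development_curve(cfg, cfg$growth_onset_div), 0)
  expect_equal(development_curve(cfg, 28), 1)
  expect_equal(development_curve(cfg, cfg$growth_plateau_div), 1)
  # midway through the 4->10 ramp the raised cosine is exactly 1/2
  expect_equal(development_curve(cfg, 7), 0.5)
  ramp <- development_curve(cfg, seq(4, 10, by = 0.25))
  expect_true(all(diff(ramp) > 0))
  expect_true(all(ramp >= 0 & ramp <= 1))
  expect_error(development_curve(cfg, -1), "div")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(background_rate = -1), "rates")
  expect_error(sim_config(recruitment_fraction = 1.5), "recruitment")
  expect_error(sim_config(recording_days = c(10, 7)), "increasing")
  expect_error(sim_config(growth_onset_div = 10, growth_plateau_div = 10),
               "plateau")
  expect_error(compound_effect("x", 1, network_burst_rate = 0), "multipliers")
  expect_error(compound_effect("x", 1, onset_div = 7, sex_scope = "neither"))
})

test_that("simulation is deterministic and substreams are independent of the design", {
  cfg <- tiny_config(seed = 9)
  a <- simulate_well(cfg, 10, "male", well = 3)
  b <- simulate_well(cfg, 10, "male", well = 3)
  expect_identical(a, b)
  ex1 <- simulate_experiment(cfg)
  ex2 <- simulate_experiment(cfg)
  expect_identical(ex1$spikes, ex2$spikes)
  # well 3 inside the experiment equals well 3 simulated alone
  w3 <- dplyr::filter(ex1$spikes, well == 3, div == 10)
  cond <- dplyr::filter(ex1$plate_map, well == 3)
  alone <- simulate_well(cfg, 10, cond$sex, well = 3)
  expect_equal(w3$time_s, alone$time_s)
})

test_that("zero rates give empty wells and pre-onset days are silent", {
  cfg <- sim_config(background_rate = 0, baseline_network_burst_rate = 0,
                    seed = 2)
  expect_equal(nrow(simulate_well(cfg, 14, "female")), 0)
  cfg2 <- sim_config(seed = 3)
  expect_equal(nrow(simulate_well(cfg2, 0, "female", check_div = FALSE)), 0)
})

test_that("realized spike counts match the closed-form expectation of the point process", {
  cfg <- sim_config(seed = 21, well_heterogeneity_cv = 0)
  n_rep <- 12
  counts <- vapply(seq_len(n_rep), function(w)
    nrow(simulate_well(cfg, 21, "female", well = w)), numeric(1))
  expected <- expected_well_spike_count(cfg, 21)
  sem <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * sem + 1e-9)
  # male network-burst boost is confined to its DIV range
  expect_gt(expected_well_spike_count(cfg, 14, "male"),
            expected_well_spike_count(cfg, 14, "female"))
  expect_equal(expected_well_spike_count(cfg, 21, "male"),
               expected_well_spike_count(cfg, 21, "female"))
})

test_that("all wells are active at DIV 7 under the default configuration", {
  cfg <- sim_config(seed = 4)
  n_sp <- vapply(1:24, function(w)
    nrow(simulate_well(cfg, 7, if (w %% 2) "male" else "female", well = w)),
    numeric(1))
  expect_true(all(n_sp >= 1))
})

test_that("compound multipliers apply only from onset and in the scoped sex", {
  cfg <- sim_config(seed = 7, well_heterogeneity_cv = 0)
  eff <- compound_effect("x", 10, sex_scope = "female", onset_div = 14,
                         network_burst_rate = 1.5)
  # male wells identical to control under a female-scoped effect
  expect_identical(simulate_well(cfg, 21, "male", eff, well = 2),
                   simulate_well(cfg, 21, "male", control_condition(),
                                 well = 2))
  # pre-onset days unaffected in the scoped sex
  expect_identical(simulate_well(cfg, 10, "female", eff, well = 2),
                   simulate_well(cfg, 10, "female", control_condition(),
                                 well = 2))
  # post-onset: elevated expected activity (averaged over wells)
  n_eff <- sapply(1:8, function(w)
    nrow(simulate_well(cfg, 21, "female", eff, well = w)))
  n_ctl <- sapply(1:8, function(w)
    nrow(simulate_well(cfg, 21, "female", control_condition(), well = w)))
  expect_gt(mean(n_eff), mean(n_ctl))
})

test_that("raising the network-burst multiplier never lowers detected network bursts", {
  cfg <- sim_config(seed = 31, well_heterogeneity_cv = 0)
  counts <- vapply(c(1, 1.3, 1.6), function(mult) {
    eff <- compound_effect("x", 10, onset_div = 0,
                           network_burst_rate = mult)
    mean(vapply(1:6, function(w) {
      sp <- simulate_well(cfg, 21, "female", eff, well = w)
      aw <- analysis_window(sp, cfg$recording_duration_s)
      nrow(detect_network_bursts(aw$spikes, 16, aw$duration_s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("simulate_experiment emits the canonical tables and validates its design", {
  cfg <- tiny_config(seed = 5)
  # minimal two-well control design
  des <- plate_design(cfg)[1:2, ]
  ex <- simulate_experiment(cfg, des)
  expect_setequal(unique(ex$spikes$well), 1:2)
  expect_true(all(ex$plate_map$compound == "DMSO control"))
  expect_named(ex$plate_map, c("experiment", "plate", "well", "compound",
                               "concentration_uM", "sex"))
  # one recording per well per day
  full <- simulate_experiment(cfg)
  expect_equal(nrow(dplyr::distinct(full$spikes, well, div)),
               cfg$wells_per_plate * length(cfg$recording_days))
  # invalid designs rejected
  bad <- plate_design(cfg); bad$well[1] <- 99L
  expect_error(simulate_experiment(cfg, bad), "outside")
  dup <- plate_design(cfg); dup$well[2] <- dup$well[1]
  expect_error(simulate_experiment(cfg, dup), "one condition")
})
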