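test_that("config validation catches inconsistent designs", {
  expect_error(sim_config(rheobase_sdtc_correlation = 1), "correlation")
  expect_error(sim_config(nominal_levels = c(100, 90)), "ascending")
  expect_error(sim_config(conditions = c("placebo", "newdrug")), "newdrug")
  expect_error(
    sim_config(drug_effects = list(
      placebo = list(rheobase_additive = 1, sdtc_additive = 0,
                     threshold_scale = 1),
      carbamazepine = list(rheobase_additive = 0, sdtc_additive = 0,
                           threshold_scale = 1.15),
      lacosamide = list(rheobase_additive = 0, sdtc_additive = 0,
                        threshold_scale = 1.57, sdtc_scale = 0.65))),
    "identity")
})

test_that("population draws honour the configured moments and correlation", {
  cfg <- sim_config(n_subjects = 13, sd_rheobase = 0, sd_sdtc = 0)
  pop <- draw_population(cfg)
  expect_equal(nrow(pop), 13)
  expect_true(all(pop$rheobase_pct_mso == cfg$mean_rheobase_pct_mso))
  expect_true(all(pop$sdtc_us == cfg$mean_sdtc_us))

  cfg2 <- sim_config(n_subjects = 10000, rheobase_sdtc_correlation = -0.8,
                     sd_rheobase = 0.25, sd_sdtc = 50, seed = 99L)
  pop2 <- draw_population(cfg2)
  expect_lt(abs(cor(pop2$rheobase_pct_mso, pop2$sdtc_us) - (-0.8)), 0.02)
})

test_that("infeasible designs are rejected rather than silently truncated", {
  cfg <- sim_config(mean_rheobase_pct_mso = 18, sd_rheobase = 3)
  expect_error(draw_population(cfg), "infeasible")
})

test_that("condition latents follow the additive-then-scale rule", {
  cfg <- sim_config()
  lat <- tibble::tibble(subject_id = "S01", rheobase_pct_mso = 4,
                        sdtc_us = 500, io_spread_s = 5, plateau_mv = 2)
  pla <- condition_latents(lat, "placebo", cfg)
  expect_equal(pla$rheobase_pct_mso, 4)
  expect_equal(pla$sdtc_us, 500)
  lcs <- condition_latents(lat, "lacosamide", cfg)
  expect_equal(lcs$rheobase_pct_mso, 4 * 1.57)
  expect_equal(lcs$sdtc_us, 500 * 0.65)
  cbz <- condition_latents(lat, "carbamazepine", cfg)
  expect_equal(cbz$rheobase_pct_mso, 4 * 1.15)
  expect_equal(cbz$sdtc_us, 500)
  # additive effects are applied before the scale
  add_cfg <- sim_config(drug_effects = list(
    placebo = list(rheobase_additive = 0, sdtc_additive = 0,
                   threshold_scale = 1),
    carbamazepine = list(rheobase_additive = 0.5, sdtc_additive = -50,
                         threshold_scale = 1.1),
    lacosamide = list(rheobase_additive = 0, sdtc_additive = 0,
                      threshold_scale = 1.57, sdtc_scale = 0.65)))
  cbz2 <- condition_latents(lat, "carbamazepine", add_cfg)
  expect_equal(cbz2$rheobase_pct_mso, (4 + 0.5) * 1.1)
  expect_equal(cbz2$sdtc_us, 450)
  bad_cfg <- sim_config(drug_effects = list(
    placebo = list(rheobase_additive = 0, sdtc_additive = 0,
                   threshold_scale = 1),
    carbamazepine = list(rheobase_additive = 0, sdtc_additive = -600,
                         threshold_scale = 1),
    lacosamide = list(rheobase_additive = 0, sdtc_additive = 0,
                      threshold_scale = 1.57, sdtc_scale = 0.65)))
  expect_error(condition_latents(lat, "carbamazepine", bad_cfg),
               "non-positive")
})

test_that("a multiplicative effect scales every width's threshold equally", {
  wfs <- ctms_family()
  cfg <- sim_config()
  lat <- tibble::tibble(subject_id = "S01", rheobase_pct_mso = 3.5,
                        sdtc_us = 520, io_spread_s = 5, plateau_mv = 2)
  cbz <- condition_latents(lat, "carbamazepine", cfg)
  for (w in c("30", "60", "120")) {
    expect_equal(model_threshold(cbz$rheobase_pct_mso, cbz$sdtc_us, wfs[[w]]) /
                   model_threshold(lat$rheobase_pct_mso, lat$sdtc_us, wfs[[w]]),
                 1.15, tolerance = 1e-10)
  }
})

test_that("sessions have the designed trial structure", {
  cfg <- sim_config(seed = 17L)
  wfs <- ctms_family()
  pop <- draw_population(cfg)
  ses <- simulate_session(pop[1, ], "placebo", cfg, wfs, seed = 123L)
  expect_equal(nrow(ses), 3 * 11 * 10)
  counts <- table(ses$pulse_width_us)
  expect_true(all(counts == 110))
  expect_true(all(ses$mep_pp_mv > 0))
  expect_true(all(ses$noise_pp_mv > 0))
  for (w in c(30, 60, 120)) {
    expect_lte(max(ses$intensity_pct_mso[ses$pulse_width_us == w]),
               mso_ceiling(w))
  }
  truth <- attr(ses, "truth")
  expect_equal(nrow(truth), 3)
  expect_true(all(diff(truth$true_threshold_pct_mso) < 0))
})

test_that("a full study has the design size and decreasing true thresholds", {
  cfg <- sim_config(seed = 5L)
  st <- simulate_study(cfg)
  expect_equal(nrow(st$trials), 13 * 3 * 330)
  expect_equal(nrow(st$truth), 13 * 3 * 3)
  dec <- st$truth |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(dec = all(diff(.data$true_threshold_pct_mso) < 0),
                     .groups = "drop")
  expect_true(all(dec$dec))
})

test_that("simulation is byte-identical under the same seed", {
  cfg <- sim_config(n_subjects = 3, seed = 33L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_study(cfg), d1)
  write_simulation(simulate_study(cfg), d2)
  for (f in c("trials.csv", "ground_truth.csv", "sim_config.yaml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # and a different seed changes the data
  st3 <- simulate_study(sim_config(n_subjects = 3, seed = 34L))
  expect_false(identical(read.csv(file.path(d1, "trials.csv"))$mep_pp_mv,
                         st3$trials$mep_pp_mv))
})

test_that("sessions are reproducible in isolation from the master seed", {
  cfg <- sim_config(n_subjects = 3, seed = 8L)
  st <- simulate_study(cfg)
  pop <- draw_population(cfg)
  lat <- condition_latents(pop[2, ], "lacosamide", cfg)
  ses <- simulate_session(lat, "lacosamide", cfg, ctms_family(),
                          seed = sdtms:::stream_seed(8L, 2L, 3L))
  sub <- st$trials[st$trials$subject_id == "S02" &
                     st$trials$condition == "lacosamide", ]
  expect_equal(ses$mep_pp_mv, sub$mep_pp_mv)
})

test_that("noiseless sessions invert back to the generating threshold", {
  cfg <- sim_config(trial_noise_sd_log10 = 0,
                    noise_floor_median_mv = 1e-3, noise_floor_gsd = 1,
                    prelim_jitter_pct_mso = 0, io_spread_sd = 0,
                    upper_plateau_gsd = 1, seed = 2L)
  wfs <- ctms_family()
  pop <- draw_population(cfg)
  ses <- simulate_session(pop[1, ], "placebo", cfg, wfs, seed = 7L)
  truth <- attr(ses, "truth")
  # with the generating asymptotes, the medians lie exactly on the sigmoid
  # and fit + inversion reproduce the true threshold
  asym <- list(y_low = log10(cfg$noise_floor_median_mv),
               y_high = log10(pop$plateau_mv[1]))
  rmts <- vapply(c(30, 60, 120), function(w) {
    pts <- median_log_response(ses[ses$pulse_width_us == w, ])
    invert_rmt(fit_io_curve(pts, asym))
  }, numeric(1))
  expect_lt(max(abs(rmts - truth$true_threshold_pct_mso)), 1e-6)
  # and the strength-duration fit recovers the latent parameters
  sd_fit <- fit_sd_individual(setNames(rmts, c(30, 60, 120)), wfs)
  expect_equal(sd_fit$rheobase_pct_mso, pop$rheobase_pct_mso[1],
               tolerance = 1e-5)
  expect_equal(sd_fit$sdtc_us, pop$sdtc_us[1], tolerance = 1e-5)
  # the data-driven session pipeline lands close despite estimating the
  # asymptotes from the recorded amplitudes
  fits <- fit_io_session(ses)
  expect_lt(max(abs(fits$rmt_io - truth$true_threshold_pct_mso)), 0.6)
})

test_that("noise floor median is recoverable from simulated noise traces", {
  cfg <- sim_config(seed = 21L)
  st <- simulate_study(sim_config(n_subjects = 3, seed = 21L))
  noise <- st$trials$noise_pp_mv
  expect_gt(length(noise), 2000)
  expect_lt(abs(median(noise) / cfg$noise_floor_median_mv - 1), 0.05)
})

test_that("generating time constants separate in the fitted estimates", {
  fit_cohort <- function(tau) {
    cfg <- sim_config(n_subjects = 4, conditions = "placebo",
                      drug_effects = list(placebo = list(
                        rheobase_additive = 0, sdtc_additive = 0,
                        threshold_scale = 1)),
                      mean_sdtc_us = tau, sd_sdtc = 0, sd_rheobase = 0,
                      mean_rheobase_pct_mso = if (tau < 400) 6 else 3.3,
                      seed = 400L + tau)
    st <- simulate_study(cfg)
    io <- fit_io_study(st$trials)
    fit_sd_study(io, ctms_family())$sdtc_us
  }
  low <- fit_cohort(200)
  high <- fit_cohort(800)
  expect_lt(median(low), median(high))
  expect_lt(max(low), min(high))
})
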