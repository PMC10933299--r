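test_that("noiseless FRAP traces reproduce the recovery model exactly", {
  tau <- log(2) / 30
  tr <- simulate_frap_trace(frap_sim_params(mobile_fraction = 0.7, rate = tau,
                                            noise_sd = 0, seed = 1))
  post <- tr[tr$phase == "post", ]
  expect_equal(post$bleached_intensity, 0.7 * (1 - exp(-tau * post$time_s)),
               tolerance = 1e-15)
  expect_true(all(tr$bleached_intensity[tr$phase == "pre"] == 1))

  frozen <- simulate_frap_trace(frap_sim_params(mobile_fraction = 0, rate = tau,
                                                noise_sd = 0, seed = 1))
  expect_true(all(frozen$bleached_intensity[frozen$phase == "post"] == 0))
})

test_that("FRAP simulator rejects invalid parameters", {
  expect_error(frap_sim_params(schedule = c(0, 10, 5)), "increasing")
  expect_error(frap_sim_params(noise_sd = -0.1), "non-negative")
})

test_that("noisy FRAP traces are unbiased around the model mean", {
  tau <- log(2) / 30
  sched <- frap_default_schedule()
  traces <- vapply(1:1000, function(i) {
    tr <- simulate_frap_trace(frap_sim_params(0.7, tau, noise_sd = 0.02,
                                              seed = 4000 + i))
    tr$bleached_intensity[tr$phase == "post"]
  }, numeric(length(sched)))
  model <- 0.7 * (1 - exp(-tau * sched))
  se <- 0.02 / sqrt(1000)
  expect_true(all(abs(rowMeans(traces) - model) <= 3 * se))
})

test_that("simulated images have the designed in-mask CV structure", {
  quiet <- simulate_cell_image(image_sim_params(read_noise_sd = 0, seed = 1))
  expect_identical(quiet$truth$realized_cv, 0)

  punctate <- simulate_cell_image(image_sim_params(puncta_count = 5,
                                                   puncta_amplitude = 8000,
                                                   read_noise_sd = 0, seed = 2))
  expect_gt(punctate$truth$realized_cv, 0.62)

  # CV is invariant under intensity rescaling of the whole image
  img <- simulate_cell_image(image_sim_params(puncta_count = 3, target_cv = 0.9,
                                              read_noise_sd = 5, seed = 3))
  cv1 <- cell_cv(img$reporter[img$mask])
  cv10 <- cell_cv(10 * img$reporter[img$mask])
  expect_equal(cv10, cv1, tolerance = 1e-12)

  expect_error(image_sim_params(cell_radius = 40, image_shape = c(64, 64)),
               "too large")
})

test_that("designed target CV is hit exactly for noiseless punctate images", {
  img <- simulate_cell_image(image_sim_params(puncta_count = 4, target_cv = 1.0,
                                              read_noise_sd = 0, seed = 9))
  expect_equal(img$truth$realized_cv, 1.0, tolerance = 1e-8)
})

test_that("cohort simulator validates preconditions and covers day 1", {
  expect_error(cohort_sim_params(groups = character(0)), "non-empty")
  expect_error(cohort_sim_params(censor_day = 0.5, imaging_days = 1:10),
               "precede")
  expect_error(cohort_sim_params(baseline_death_rate = 0), "positive")

  sim <- simulate_cohort(cohort_sim_params(n_cells = 300, seed = 5))
  day1 <- sim$tracks[sim$tracks$day == 1, ]
  expect_setequal(day1$cell_id, sim$truth$cell_id)
  expect_true(all(day1$alive))
  # truth is sufficient to score the estimators
  expect_true(all(c("latent_death_day", "latent_puncta_day", "lp_death",
                    "lp_puncta", "expression_day1") %in% names(sim$truth)))
})

test_that("cohort generation is deterministic given the seed", {
  p <- cohort_sim_params(n_cells = 150, seed = 99)
  expect_identical(simulate_cohort(p), simulate_cohort(p))
  p2 <- cohort_sim_params(n_cells = 150, seed = 100)
  expect_false(identical(simulate_cohort(p), simulate_cohort(p2)))
})

test_that("null cohorts give exchangeable groups with HR near 1", {
  sim <- simulate_cohort(cohort_sim_params(n_cells = 2000,
                                           groups = c("iRFP", "WT"), seed = 21))
  rec <- event_records(extract_events(sim$tracks), "death")
  res <- fit_cox(rec, reference = "iRFP")
  expect_true(res$table$ci_low < 1 && res$table$ci_high > 1)
  expect_lt(abs(res$table$beta), 3 * res$table$se)
})

test_that("cohort Cox fits recover the generating hazard ratio", {
  sim <- simulate_cohort(cohort_sim_params(
    n_cells = 2000, groups = c("iRFP", "WT"),
    log_hazard_death = c(iRFP = 0, WT = log(1.6)), seed = 31))
  rec <- event_records(extract_events(sim$tracks), "death")
  res <- fit_cox(rec, reference = "iRFP")
  expect_lt(abs(res$table$beta - log(1.6)), 3 * res$table$se)
})

test_that("noiseless decay traces satisfy the mono-exponential model", {
  p <- decay_sim_params(half_life = 10, T0_level = 100, T1_level = 1100,
                        noise_cv = 0, hours = 1:14, n_wells = 1,
                        n_experiments = 1, seed = 1)
  d <- simulate_decay_trace(p)
  T0 <- d$tritc_intensity[d$time_h == -1]
  T1 <- d$tritc_intensity[d$time_h == 0]
  # half-life definition: halfway between peak and background at t = 10 h
  expect_equal(d$tritc_intensity[d$time_h == 10], (T1 - T0) / 2 + T0,
               tolerance = 1e-12)
  k <- log(2) / 10
  norm <- (d$tritc_intensity[d$time_h > 0] - T0) / (T1 - T0)
  expect_equal(norm, exp(-k * d$time_h[d$time_h > 0]), tolerance = 1e-12)
  expect_error(decay_sim_params(half_life = -1), "positive")
})

test_that("fitted half-lives recover the decay truth per experiment", {
  d <- simulate_decay_trace(decay_sim_params(half_life = 10, noise_cv = 0.02,
                                             n_wells = 6, n_experiments = 3,
                                             seed = 7))
  fits <- fit_flux_wells(d, mode = "background-subtracted")
  agg <- aggregate_flux(fits)
  expect_true(all(abs(agg$experiment_means$half_life - 10) / 10 <= 0.05))
})
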