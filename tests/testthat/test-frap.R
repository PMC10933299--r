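make_trace <- function(pre_vals, post_vals, post_times = NULL) {
  n_pre <- length(pre_vals)
  if (is.null(post_times)) post_times <- seq(0, by = 10, length.out = length(post_vals))
  data.frame(
    time_s = c(-(n_pre:1), post_times),
    phase = rep(c("pre", "post"), c(n_pre, length(post_vals))),
    bleached_intensity = c(pre_vals, post_vals)
  )
}

test_that("two-point normalization maps pre-bleach mean to 1 and first post to 0", {
  tr <- make_trace(c(0.40, 0.41, 0.39), c(0.10, 0.25, 0.30, 0.32))
  nm <- normalize_frap_trace(tr)
  expect_equal(mean(nm$value[nm$phase == "pre"]), 1)
  expect_equal(nm$value[nm$phase == "post"][1], 0)
  # hand affine arithmetic: (0.25 - 0.10) / (0.40 - 0.10)
  expect_equal(nm$value[nm$phase == "post"][2], 0.5)
})

test_that("normalization uses the whole-granule ratio when present", {
  tr <- make_trace(c(0.8, 0.8), c(0.2, 0.5, 0.6))
  tr$whole_intensity <- 2
  nm <- normalize_frap_trace(tr)
  # ratios are pre 0.4, post 0.1/0.25/0.3 -> same affine result
  expect_equal(nm$value[nm$phase == "post"], c(0, 0.5, 2 / 3), tolerance = 1e-12)
})

test_that("normalization is idempotent and rejects zero bleach depth", {
  tr <- make_trace(c(0.40, 0.41, 0.39), c(0.10, 0.25, 0.30))
  nm <- normalize_frap_trace(tr)
  again <- nm
  names(again)[names(again) == "value"] <- "bleached_intensity"
  nm2 <- normalize_frap_trace(again)
  expect_equal(nm2$value, nm$value, tolerance = 1e-12)

  flat <- make_trace(c(0.4, 0.4), c(0.4, 0.41, 0.42))
  expect_error(normalize_frap_trace(flat), "zero bleach depth")
})

test_that("recovery fits are exact on noiseless model data", {
  for (truth in list(c(A = 0.7, tau = log(2) / 30), c(A = 0.4, tau = 0.1),
                     c(A = 1.2, tau = 0.01))) {
    tr <- simulate_frap_trace(frap_sim_params(truth[["A"]], truth[["tau"]],
                                              noise_sd = 0, seed = 1))
    f <- fit_recovery(normalize_frap_trace(tr))
    expect_equal(f$mobile_fraction, truth[["A"]], tolerance = 1e-6)
    expect_equal(f$rate, truth[["tau"]], tolerance = 1e-6)
    expect_equal(f$t_half * f$rate, log(2), tolerance = 4 * .Machine$double.eps)
  }
})

test_that("degenerate series are rejected as unidentifiable", {
  flat <- data.frame(time_s = c(0, 10, 20, 30), phase = "post", value = 0)
  expect_error(fit_recovery(flat), "unidentifiable tau")
})

test_that("fit recovery under noise is accurate at the study noise level", {
  errs <- vapply(1:50, function(i) {
    tr <- simulate_frap_trace(frap_sim_params(0.7, log(2) / 30, noise_sd = 0.02,
                                              seed = 100 + i))
    f <- fit_recovery(normalize_frap_trace(tr))
    abs(f$mobile_fraction - 0.7)
  }, numeric(1))
  expect_lte(median(errs), 0.02)
})

test_that("larger true rates give smaller estimated half-times", {
  taus <- c(0.01, 0.02, 0.05, 0.2)
  th <- vapply(taus, function(tau) {
    tr <- simulate_frap_trace(frap_sim_params(0.7, tau, noise_sd = 0, seed = 1))
    fit_recovery(normalize_frap_trace(tr))$t_half
  }, numeric(1))
  expect_true(all(diff(th) < 0))
})

test_that("half_time implements ln2 / tau", {
  expect_equal(half_time(log(2)), 1.0)
  expect_equal(half_time(0.023105), log(2) / 0.023105)
  expect_error(half_time(0), "positive")
})

test_that("diffusion coefficient follows the bleach-spot formula", {
  expect_equal(diffusion_coefficient(1, 0.22), 1.0)
  expect_equal(diffusion_coefficient(3.7, 30), 0.88 * 3.7^2 / 120)
  expect_equal(diffusion_coefficient(3.7, 60),
               diffusion_coefficient(3.7, 30) / 2)
  expect_error(diffusion_coefficient(-1, 30), "positive")
})

test_that("Stokes radius follows the cube-root mass relation in nm", {
  expect_equal(stokes_radius(1 / 0.66), 0.1)
  expect_equal(stokes_radius(140000), (0.66 * 140000)^(1 / 3) / 10)
  expect_equal(stokes_radius(140000), 4.52, tolerance = 1e-3)
  expect_equal(stokes_radius(8 * 140000), 2 * stokes_radius(140000))
  expect_error(stokes_radius(0), "positive")
})

test_that("Einstein-Stokes viscosity behaves as the closed form", {
  k_b <- 1.380649e-23
  # choose D * r_s numerically equal to k_B T / (6 pi) in SI
  T_K <- 310
  D <- 0.5
  r_nm <- k_b * T_K / (6 * pi * (D * 1e-12)) * 1e9
  expect_equal(viscosity(D, r_nm, T_K), 1.0, tolerance = 1e-12)
  expect_equal(viscosity(0.1004, 4.5, 620), 2 * viscosity(0.1004, 4.5, 310))
  expect_error(viscosity(0, 4.5, 310), "positive")
})

test_that("the fitted physics pipeline matches the closed-form composition", {
  A <- 0.8; tau <- 0.03
  tr <- simulate_frap_trace(frap_sim_params(A, tau, noise_sd = 0, seed = 1))
  f <- frap_physics(fit_recovery(normalize_frap_trace(tr)),
                    roi_radius_um = 3.7, stokes_radius_nm = 4.5,
                    temperature_K = 310)
  th <- log(2) / tau
  D <- 0.88 * 3.7^2 / (4 * th)
  eta <- 1.380649e-23 * 310 / (6 * pi * D * 1e-12 * 4.5e-9)
  expect_equal(f$diffusion_um2_s, D, tolerance = 1e-6)
  expect_equal(f$viscosity_pa_s, eta, tolerance = 1e-6)
})

test_that("recovery summaries compute per-time means and SEMs", {
  tr <- simulate_frap_trace(frap_sim_params(0.7, 0.05, noise_sd = 0, seed = 1))
  nm <- normalize_frap_trace(tr)
  one <- summarize_recovery(list(g1 = nm), genotypes = "WT")
  expect_equal(one$mean, nm$value[nm$phase == "post"])
  expect_true(all(one$sem == 0))

  two <- summarize_recovery(list(g1 = nm, g2 = nm), genotypes = c("WT", "WT"))
  expect_true(all(two$sem == 0))
  expect_true(all(two$n == 2))

  f <- fit_recovery(nm)
  pn <- summarize_recovery(list(g1 = nm), genotypes = "WT",
                           fits = list(g1 = f), plateau_normalize = TRUE)
  expect_equal(pn$mean[which.max(pn$time_s)], 1.0, tolerance = 1e-4)
  expect_error(summarize_recovery(list(), genotypes = character(0)), "non-empty")
})

test_that("frap_fit methods are coherent", {
  tr <- simulate_frap_trace(frap_sim_params(0.7, 0.05, noise_sd = 0.02, seed = 3))
  f <- fit_recovery(normalize_frap_trace(tr), granule_id = "g1", genotype = "WT")
  expect_named(coef(f), c("A", "tau"))
  expect_equal(length(residuals(f)), f$n_points)
  expect_equal(predict(f, 0), 0)
  expect_output(print(f), "mobile fraction")
  s <- summary(f)
  expect_equal(s$mobile_fraction, f$mobile_fraction)
  sim <- simulate(f, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_s3_class(sim[[1]], "frap_trace")
})
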