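test_that("exchangeable groups give a hazard ratio of exactly 1", {
  d <- data.frame(time = c(1, 1, 2, 2, 3, 3, 4, 4),
                  event = c(1, 1, 1, 1, 1, 1, 0, 0),
                  group = rep(c("A", "B"), 4))
  res <- fit_cox(d, reference = "A", strata = NULL)
  expect_equal(res$table$hazard_ratio, 1, tolerance = 1e-8)
})

test_that("fitted coefficients match the Efron partial-likelihood grid oracle", {
  for (fx in cox_toy_fixtures()) {
    res <- fit_cox(fx, reference = "A", strata = NULL)
    oracle <- grid_max_beta(fx$time, fx$event, as.integer(fx$group == "B"))
    expect_equal(res$table$beta, oracle, tolerance = 1e-3)
  }
})

test_that("fit_cox enforces its preconditions and flags separation", {
  no_events <- data.frame(time = 1:4, event = 0, group = c("A", "A", "B", "B"))
  expect_error(fit_cox(no_events), "event")
  one_group <- data.frame(time = 1:4, event = 1, group = "A")
  expect_error(fit_cox(one_group), "two groups")
  # monotone likelihood: every A event precedes every B event, so the
  # B-vs-A coefficient runs away and must be flagged, not silently returned
  sep <- data.frame(time = 1:6, event = c(1, 1, 1, 1, 1, 0),
                    group = c("A", "A", "A", "B", "B", "B"))
  res <- fit_cox(sep, reference = "A", strata = NULL)
  expect_true(res$table$flagged)
})

test_that("beta is invariant to strata relabeling and time rescaling", {
  set.seed(5)
  d <- data.frame(time = sample(1:8, 120, TRUE),
                  event = rbinom(120, 1, 0.7),
                  group = sample(c("A", "B"), 120, TRUE),
                  stratum = sample(1:3, 120, TRUE))
  b1 <- fit_cox(d, reference = "A")$table$beta
  d2 <- d; d2$stratum <- c(30, 10, 20)[d2$stratum]
  expect_equal(fit_cox(d2, reference = "A")$table$beta, b1, tolerance = 1e-10)
  d3 <- d; d3$time <- d3$time * 7.3
  expect_equal(fit_cox(d3, reference = "A")$table$beta, b1, tolerance = 1e-10)
})

test_that("quintile binning is rank based with stable ties", {
  q <- quintile_bin(1:10)
  expect_equal(as.vector(table(q$quintile)), rep(2, 5))
  expect_equal(q$quintile[1], 1L)
  q5 <- quintile_bin(c(3, 1, 5, 2, 4))
  expect_equal(sort(q5$quintile), 1:5)
  expect_equal(q5$quintile[q5$value == 1], 1L)
  qt <- quintile_bin(c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3))
  expect_equal(as.vector(table(qt$quintile)), rep(2, 5))
  # stable: earlier occurrences of a tied value get the lower quintile
  expect_equal(qt$quintile[1:4], c(1L, 1L, 2L, 2L))
  expect_error(quintile_bin(1:4), "at least 5")
})

test_that("a log-linear expression effect yields monotone quintile hazards", {
  sim <- simulate_cohort(cohort_sim_params(
    n_cells = 4000, groups = "WT", expression_effect_death = 0.5, seed = 41))
  rec <- event_records(extract_events(sim$tracks), "death")
  q <- hazard_by_quintile(rec, basis = "expression")
  expect_true(all(diff(q$hazard_ratio) > 0))
  expect_equal(q$hazard_ratio[q$quintile == 1], 1)
})

test_that("quintile hazards are null when expression has no effect", {
  sim <- simulate_cohort(cohort_sim_params(n_cells = 2500, groups = "WT",
                                           seed = 43))
  rec <- event_records(extract_events(sim$tracks), "death")
  q <- hazard_by_quintile(rec, basis = "expression")
  q25 <- q[q$quintile > 1, ]
  expect_true(all(q25$ci_low < 1 & q25$ci_high > 1))
})

test_that("diffuse/punctate subgroup contrasts recover simulated effects", {
  sim <- simulate_cohort(cohort_sim_params(
    n_cells = 4000, groups = c("iRFP", "WT"),
    log_hazard_puncta = c(iRFP = -20, WT = 1),
    baseline_puncta_rate = 0.7,
    day1_puncta_effect_death = log(1.3), seed = 47))
  rec <- event_records(extract_events(sim$tracks), "death")
  dp <- suppressWarnings(diffuse_vs_punctate_analysis(rec, control = "iRFP"))
  wt <- dp$within_genotype[dp$within_genotype$group == "WT", ]
  expect_true(wt$ci_low <= 1.3 && wt$ci_high >= 1.3)
  expect_lt(abs(log(wt$hazard_ratio) - log(1.3)), 0.2)
  expect_error(diffuse_vs_punctate_analysis(rec, control = "nope"), "present")
})

test_that("diffuse/punctate contrasts are null under equal hazards", {
  sim <- simulate_cohort(cohort_sim_params(
    n_cells = 3000, groups = c("iRFP", "WT"),
    baseline_puncta_rate = 0.7, seed = 53))
  rec <- event_records(extract_events(sim$tracks), "death")
  dp <- diffuse_vs_punctate_analysis(rec, control = "iRFP")
  expect_true(all(dp$vs_control$ci_low < 1 & dp$vs_control$ci_high > 1))
  expect_true(all(dp$within_genotype$ci_low < 1 & dp$within_genotype$ci_high > 1))
})

test_that("risk tables format and round-trip through CSV", {
  one <- data.frame(term = "WT", n = 10L, hazard_ratio = 1, ci_low = 0.8,
                    ci_high = 1.25, p = 0.9)
  tab <- risk_table_report(one)
  expect_equal(tab$hazard_ratio, "1.0000")
  expect_equal(risk_table_report(data.frame(term = "x", hazard_ratio = 2,
                                            ci_low = 1.5, ci_high = 2.5,
                                            p = 2e-5))$p, "2.00e-05")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  risk_table_report(one, path = path)
  back <- utils::read.csv(path, colClasses = "character")
  expect_identical(back$hazard_ratio, tab$hazard_ratio)
  expect_identical(back$p, tab$p)

  sim <- simulate_cohort(cohort_sim_params(n_cells = 1500, seed = 61))
  res <- fit_cox(event_records(extract_events(sim$tracks), "death"),
                 reference = "iRFP")
  full <- risk_table_report(res)
  expect_equal(nrow(full), 7)
  expect_equal(full$hazard_ratio[full$term == "iRFP"], "1.0000")
})
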