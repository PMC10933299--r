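#' Normalize a photoconverted-reporter decay trace
#'
#' Normalizes hourly TRITC intensities to the photoconversion depth.
#' `"as-printed"` divides each value by `T1 - T0` (so the t = 0 value is
#' `T1/(T1 - T0)`, which exceeds 1 whenever the background `T0` is nonzero);
#' `"background-subtracted"` first subtracts `T0`, so the normalized series
#' starts at 1 and decays to 0 — the form matched by the fixed-scale
#' exponential fit.
#'
#' @param trace One well's rows of a decay table: columns `time_h` (-1 codes
#'   the pre-conversion background T0, 0 the post-conversion peak T1,
#'   positive values the hourly reads) and `tritc_intensity`.
#' @param mode `"as-printed"` or `"background-subtracted"`.
#' @return Data frame of class `decay_norm` with columns `time_h`, `value`
#'   for the post-conversion timepoints (t > 0), and attributes `T0`, `T1`,
#'   `mode`.
#' @export
normalize_decay <- function(trace, mode = c("as-printed", "background-subtracted")) {
  mode <- match.arg(mode)
  check_that(
    "trace must contain time_h and tritc_intensity" =
      all(c("time_h", "tritc_intensity") %in% names(trace)),
    "trace must contain the T0 (time_h = -1) and T1 (time_h = 0) rows" =
      any(trace$time_h == -1) && any(trace$time_h == 0)
  )
  T0 <- trace$tritc_intensity[trace$time_h == -1][1]
  T1 <- trace$tritc_intensity[trace$time_h == 0][1]
  if (T1 <= T0) stop("zero conversion depth", call. = FALSE)
  hourly <- trace[trace$time_h > 0, , drop = FALSE]
  hourly <- hourly[order(hourly$time_h), , drop = FALSE]
  value <- if (mode == "as-printed") {
    hourly$tritc_intensity / (T1 - T0)
  } else {
    (hourly$tritc_intensity - T0) / (T1 - T0)
  }
  out <- data.frame(time_h = hourly$time_h, value = value)
  attr(out, "T0") <- T0
  attr(out, "T1") <- T1
  attr(out, "mode") <- mode
  class(out) <- c("decay_norm", "data.frame")
  out
}

#' Fit a mono-exponential half-life to a normalized decay series
#'
#' Least-squares fit of `y = exp(-k t)` (scale fixed at 1 at t = 0, the
#' post-conversion frame; a free scale is optional) to the post-conversion
#' timepoints. The half-life is `ln 2 / k`. A non-decaying series
#' (estimated k <= 0) is flagged rather than silently returned.
#'
#' @param norm A [normalize_decay()] result, or a data frame with columns
#'   `time_h` (> 0) and `value`.
#' @param free_scale Also estimate the amplitude at t = 0 instead of fixing
#'   it at 1.
#' @param log_linear Fit by linear regression of `log(value)` on time instead
#'   of nonlinear least squares.
#' @param well_id,experiment_id,condition Labels stored in the result.
#' @return An object of class `flux_fit` with `half_life` (hours), `k`
#'   (per hour), `scale`, `rss`, `n_timepoints`, `flagged`, `mode`.
#' @export
fit_halflife <- function(norm, free_scale = FALSE, log_linear = FALSE,
                         well_id = NA_character_, experiment_id = NA,
                         condition = NA_character_) {
  check_that(
    "`norm` must have columns time_h and value" =
      all(c("time_h", "value") %in% names(norm)),
    "at least 4 timepoints are required" = nrow(norm) >= 4,
    "times must be positive (post-conversion)" = all(norm$time_h > 0)
  )
  t <- norm$time_h
  y <- norm$value
  mode <- attr(norm, "mode") %||% "unknown"
  flagged <- FALSE

  # a series that does not decay has no positive-rate fit; flag it up front
  slope <- unname(stats::coef(stats::lm(y ~ t))[2])
  if (!is.finite(slope) || slope >= -1e-9 * max(abs(y)) || stats::sd(y) == 0) {
    return(structure(list(half_life = NA_real_, k = NA_real_, scale = 1,
                          rss = NA_real_, n_timepoints = length(t),
                          flagged = TRUE, mode = mode, well_id = well_id,
                          experiment_id = experiment_id, condition = condition,
                          data = data.frame(time_h = t, value = y)),
                     class = "flux_fit"))
  }

  if (log_linear) {
    ok <- y > 0
    check_that("log-linear fit needs positive values" = sum(ok) >= 4)
    lf <- stats::lm(log(y[ok]) ~ t[ok])
    k <- -unname(stats::coef(lf)[2])
    s <- exp(unname(stats::coef(lf)[1]))
    if (!free_scale) {
      lf0 <- stats::lm(log(y[ok]) ~ 0 + t[ok])
      k <- -unname(stats::coef(lf0)[1])
      s <- 1
    }
    rss <- sum((y - s * exp(-k * t))^2)
  } else {
    k0 <- {
      ok <- y > 0
      if (sum(ok) >= 2) max(1e-4, -unname(stats::coef(stats::lm(log(y[ok]) ~ t[ok]))[2]))
      else 0.1
    }
    fit <- if (free_scale) {
      minpack.lm::nlsLM(y ~ s * exp(-k * t), start = list(s = max(y[1], 0.5), k = k0),
                        lower = c(s = 1e-8, k = -5), upper = c(s = 10, k = 10))
    } else {
      minpack.lm::nlsLM(y ~ exp(-k * t), start = list(k = k0),
                        lower = c(k = -5), upper = c(k = 10))
    }
    cf <- stats::coef(fit)
    k <- unname(cf[["k"]])
    s <- if (free_scale) unname(cf[["s"]]) else 1
    rss <- sum(stats::resid(fit)^2)
  }
  if (!is.finite(k) || k <= 0) {
    flagged <- TRUE
    half_life <- NA_real_
  } else {
    half_life <- log(2) / k
  }
  structure(list(half_life = half_life, k = k, scale = s, rss = rss,
                 n_timepoints = length(t), flagged = flagged, mode = mode,
                 well_id = well_id, experiment_id = experiment_id,
                 condition = condition,
                 data = data.frame(time_h = t, value = y)),
            class = "flux_fit")
}

#' Fit half-lives for every well of a decay table
#'
#' Splits a long-format decay table by well, normalizes each well's trace,
#' and fits its mono-exponential half-life.
#'
#' @param decay Long-format decay table: `well_id`, `experiment_id`,
#'   `condition`, `time_h`, `tritc_intensity` (see [simulate_decay_trace()]
#'   and [read_decay()]).
#' @param mode Normalization mode, see [normalize_decay()].
#' @param ... Passed to [fit_halflife()].
#' @return Data frame with one row per well: `well_id`, `experiment_id`,
#'   `condition`, `half_life`, `k`, `rss`, `n_timepoints`, `flagged`.
#' @export
fit_flux_wells <- function(decay, mode = "background-subtracted", ...) {
  check_that("decay table must contain well_id" = "well_id" %in% names(decay))
  parts <- split(decay, interaction(decay$well_id, decay$experiment_id,
                                    decay$condition, drop = TRUE))
  rows <- lapply(parts, function(d) {
    f <- fit_halflife(normalize_decay(d, mode = mode),
                      well_id = d$well_id[1], experiment_id = d$experiment_id[1],
                      condition = d$condition[1], ...)
    data.frame(well_id = f$well_id, experiment_id = f$experiment_id,
               condition = f$condition, half_life = f$half_life, k = f$k,
               rss = f$rss, n_timepoints = f$n_timepoints, flagged = f$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Superplot-style nested aggregation of half-lives
#'
#' Two-level aggregation matching the superplot convention for nested
#' replicates: wells are first averaged within each experiment, then
#' per-experiment means are summarized per condition with n = the number of
#' experiments (not wells), so the SEM reflects biological rather than
#' technical replication.
#'
#' @param results Per-well fit table from [fit_flux_wells()].
#' @return List with `experiment_means` (condition, experiment_id, n_wells,
#'   half_life) and `condition_summary` (condition, n = experiments, mean,
#'   sd, sem; sd/sem are `NA` with a single experiment).
#' @export
aggregate_flux <- function(results) {
  check_that("at least one fit is required" = nrow(results) >= 1)
  ok <- results[!results$flagged & !is.na(results$half_life), , drop = FALSE]
  check_that("no unflagged half-life fits to aggregate" = nrow(ok) >= 1)
  em <- stats::aggregate(half_life ~ condition + experiment_id, data = ok,
                         FUN = mean)
  nw <- stats::aggregate(half_life ~ condition + experiment_id, data = ok,
                         FUN = length)
  em$n_wells <- nw$half_life
  em <- em[order(em$condition, em$experiment_id),
           c("condition", "experiment_id", "n_wells", "half_life")]
  cs <- lapply(split(em, em$condition, drop = TRUE), function(d) {
    data.frame(condition = d$condition[1], n = nrow(d),
               mean = mean(d$half_life),
               sd = if (nrow(d) > 1) stats::sd(d$half_life) else NA_real_,
               sem = sem(d$half_life), stringsAsFactors = FALSE)
  })
  cs <- do.call(rbind, cs)
  rownames(em) <- rownames(cs) <- NULL
  list(experiment_means = em, condition_summary = cs)
}
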