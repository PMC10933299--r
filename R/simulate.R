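#' Default FRAP acquisition schedule
#'
#' Post-bleach acquisition times matching the live-cell protocol: an image
#' every 5 s for the first minute, then every 10 s out to 5 min. Time zero is
#' the first post-bleach frame.
#'
#' @return Numeric vector of post-bleach times in seconds, starting at 0.
#' @export
frap_default_schedule <- function() {
  c(seq(0, 60, by = 5), seq(70, 300, by = 10))
}

#' Parameters for simulated FRAP recovery traces
#'
#' @param mobile_fraction Plateau recovery A (dimensionless, in `[0, 1.5]`).
#' @param rate Recovery rate constant tau in s^-1 (> 0).
#' @param noise_sd Standard deviation of additive Gaussian noise, in
#'   normalized-intensity units (>= 0).
#' @param schedule Strictly increasing post-bleach acquisition times in
#'   seconds, starting at 0 (the first post-bleach frame).
#' @param pre_bleach_count Number of pre-bleach frames (>= 1).
#' @param scale Raw-intensity scale factor: the simulated trace is emitted in
#'   arbitrary units equal to `scale` times the normalized value, so that
#'   [normalize_frap_trace()] has real work to do.
#' @param seed Integer seed for the trace's private random stream.
#' @return A list of class `frap_sim_params`.
#' @export
frap_sim_params <- function(mobile_fraction = 0.7, rate = log(2) / 30,
                            noise_sd = 0.02, schedule = frap_default_schedule(),
                            pre_bleach_count = 3L, scale = 1, seed = 1L) {
  check_that(
    "`mobile_fraction` must be in [0, 1.5]" =
      is.numeric(mobile_fraction) && mobile_fraction >= 0 && mobile_fraction <= 1.5,
    "`rate` must be a positive number" = is.numeric(rate) && rate > 0,
    "`noise_sd` must be non-negative" = is.numeric(noise_sd) && noise_sd >= 0,
    "`schedule` must be strictly increasing" =
      length(schedule) >= 3L && all(diff(schedule) > 0),
    "`schedule` must start at 0" = schedule[1] == 0,
    "`pre_bleach_count` must be >= 1" = pre_bleach_count >= 1,
    "`scale` must be positive" = scale > 0
  )
  structure(list(mobile_fraction = mobile_fraction, rate = rate,
                 noise_sd = noise_sd, schedule = schedule,
                 pre_bleach_count = as.integer(pre_bleach_count),
                 scale = scale, seed = as.integer(seed)),
            class = "frap_sim_params")
}

#' Simulate a FRAP recovery trace
#'
#' Pre-bleach frames sit at the full (unbleached) intensity; the first
#' post-bleach frame sits at the bleached floor; recovery then follows
#' `y(t) = A (1 - exp(-tau t))` with i.i.d. additive Gaussian noise.
#' The noiseless trace reproduces the model exactly at every sample time.
#'
#' @param params A [frap_sim_params()] object.
#' @param granule_id,genotype Labels copied into the output.
#' @param roi_radius_um Bleach-spot radius in micrometres.
#' @return A data frame of class `frap_trace` with columns `time_s`, `phase`
#'   (`"pre"`/`"post"`), `bleached_intensity`, `granule_id`, `genotype`,
#'   `roi_radius_um`, and a `truth` attribute carrying the generating
#'   `mobile_fraction` and `rate`.
#' @export
simulate_frap_trace <- function(params, granule_id = "g1", genotype = "WT",
                                roi_radius_um = 3.7) {
  stopifnot(inherits(params, "frap_sim_params"))
  pre_times <- -rev(seq_len(params$pre_bleach_count))
  post_times <- params$schedule
  model <- params$mobile_fraction * (1 - exp(-params$rate * post_times))
  values <- with_seed(params$seed, {
    n <- length(pre_times) + length(post_times)
    noise <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd) else numeric(n)
    c(rep(1, length(pre_times)), model) + noise
  })
  out <- data.frame(
    granule_id = granule_id,
    genotype = genotype,
    time_s = c(pre_times, post_times),
    phase = rep(c("pre", "post"), c(length(pre_times), length(post_times))),
    bleached_intensity = values * params$scale,
    roi_radius_um = roi_radius_um,
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(mobile_fraction = params$mobile_fraction,
                             rate = params$rate)
  class(out) <- c("frap_trace", "data.frame")
  out
}

#' Parameters for simulated two-channel cell images
#'
#' @param image_shape Integer vector `c(rows, cols)` in pixels.
#' @param cell_radius Cell (disk) radius in pixels; the cell must fit in the
#'   frame.
#' @param background_level,cell_level Intensities outside/inside the cell
#'   mask, arbitrary units.
#' @param puncta_count Number of Gaussian puncta (>= 0).
#' @param puncta_amplitude Peak intensity added by each punctum (ignored when
#'   `target_cv` is given for a punctate image).
#' @param puncta_sigma Gaussian width of each punctum in pixels.
#' @param read_noise_sd Additive Gaussian read noise SD (intensity units).
#' @param target_cv Optional design coefficient of variation for the in-mask
#'   reporter pixels. For a diffuse image (`puncta_count = 0`) this sets
#'   `read_noise_sd = target_cv * cell_level`; for a punctate image the
#'   puncta amplitude is solved numerically so the noiseless in-mask CV
#'   equals `target_cv` exactly.
#' @param seed Integer seed.
#' @return A list of class `image_sim_params`.
#' @export
image_sim_params <- function(image_shape = c(64L, 64L), cell_radius = 20,
                             background_level = 100, cell_level = 1000,
                             puncta_count = 0L, puncta_amplitude = 4000,
                             puncta_sigma = 2, read_noise_sd = 0,
                             target_cv = NULL, seed = 1L) {
  check_that(
    "`image_shape` must be two positive integers" =
      length(image_shape) == 2L && all(image_shape >= 4),
    "`cell_radius` too large for frame" =
      cell_radius > 0 && 2 * cell_radius < min(image_shape),
    "`puncta_count` must be >= 0" = puncta_count >= 0,
    "`read_noise_sd` must be >= 0" = read_noise_sd >= 0,
    "`cell_level` must be positive" = cell_level > 0,
    "`puncta_sigma` must be positive" = puncta_sigma > 0
  )
  if (!is.null(target_cv)) {
    check_that("`target_cv` must be positive" = target_cv > 0)
  }
  structure(list(image_shape = as.integer(image_shape), cell_radius = cell_radius,
                 background_level = background_level, cell_level = cell_level,
                 puncta_count = as.integer(puncta_count),
                 puncta_amplitude = puncta_amplitude, puncta_sigma = puncta_sigma,
                 read_noise_sd = read_noise_sd, target_cv = target_cv,
                 seed = as.integer(seed)),
            class = "image_sim_params")
}

#' Simulate a two-channel cell image with known ground truth
#'
#' Generates a reporter image, a morphology image and the exact cell mask for
#' one synthetic cell: a disk of uniform intensity on a darker background,
#' optionally decorated with Gaussian puncta, plus additive read noise.
#' The truth record stores the realized in-mask coefficient of variation so
#' downstream classification can be scored exactly.
#'
#' @param params An [image_sim_params()] object.
#' @return A list with elements `reporter`, `morphology` (numeric matrices),
#'   `mask` (logical matrix) and `truth` (data frame with `design_cv`,
#'   `realized_cv`, `puncta_count`, `seed`).
#' @export
simulate_cell_image <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  row_ix <- matrix(seq_len(nr), nr, nc)
  col_ix <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dist2 <- (row_ix - cx)^2 + (col_ix - cy)^2
  mask <- dist2 <= params$cell_radius^2

  with_seed(params$seed, {
    # Gaussian puncta centred well inside the mask
    spot <- matrix(0, nr, nc)
    if (params$puncta_count > 0) {
      rmax <- params$cell_radius - 2 * params$puncta_sigma
      if (rmax <= 0) rmax <- params$cell_radius / 2
      ang <- stats::runif(params$puncta_count, 0, 2 * pi)
      rad <- rmax * sqrt(stats::runif(params$puncta_count))
      px <- cx + rad * cos(ang)
      py <- cy + rad * sin(ang)
      for (k in seq_len(params$puncta_count)) {
        spot <- spot + exp(-((row_ix - px[k])^2 + (col_ix - py[k])^2) /
                             (2 * params$puncta_sigma^2))
      }
    }

    amplitude <- params$puncta_amplitude
    read_sd <- params$read_noise_sd
    if (!is.null(params$target_cv)) {
      if (params$puncta_count == 0) {
        read_sd <- params$target_cv * params$cell_level
      } else {
        # solve the puncta amplitude so the noiseless in-mask CV hits the design
        cv_of <- function(a) {
          px_in <- params$cell_level + a * spot[mask]
          stats::sd(px_in) * sqrt((length(px_in) - 1) / length(px_in)) / mean(px_in)
        }
        amplitude <- stats::uniroot(function(a) cv_of(a) - params$target_cv,
                                    lower = 0, upper = 1e6 * params$cell_level,
                                    tol = 1e-10)$root
      }
    }

    reporter <- matrix(params$background_level, nr, nc)
    reporter[mask] <- params$cell_level
    reporter <- reporter + amplitude * spot * mask
    morphology <- matrix(params$background_level, nr, nc)
    morphology[mask] <- params$cell_level
    if (read_sd > 0) {
      reporter <- reporter + matrix(stats::rnorm(nr * nc, 0, read_sd), nr, nc)
      morphology <- morphology + matrix(stats::rnorm(nr * nc, 0, read_sd), nr, nc)
    }
    reporter <- pmax(reporter, 0)
    morphology <- pmax(morphology, 0)

    px_in <- reporter[mask]
    realized_cv <- stats::sd(px_in) * sqrt((length(px_in) - 1) / length(px_in)) /
      mean(px_in)
    truth <- data.frame(
      design_cv = if (is.null(params$target_cv)) NA_real_ else params$target_cv,
      realized_cv = realized_cv,
      puncta_count = params$puncta_count,
      seed = params$seed
    )
    list(reporter = reporter, morphology = morphology, mask = mask, truth = truth)
  })
}

#' Parameters for simulated longitudinal cohorts
#'
#' Defines a cohort of single cells followed by daily imaging, with
#' genotype-dependent proportional hazards for death and for puncta
#' formation, lognormal day-1 expression, and experiment-level strata.
#'
#' Timing convention: cells enter the cohort at the first imaging day, so
#' latent death times are drawn from day 1 onward (every cell contributes a
#' day-1 observation), while latent puncta-formation times are drawn from
#' transfection (day 0), so some cells are already punctate at day 1.
#'
#' @param n_cells Number of cells.
#' @param groups Character vector of genotype labels; the first is the
#'   reference (log-hazard 0 by convention).
#' @param log_hazard_death,log_hazard_puncta Named (or positional) numeric
#'   vectors of per-group log hazards, reference = 0.
#' @param baseline_death_rate,baseline_puncta_rate Baseline exponential event
#'   rates per day (> 0).
#' @param expression_meanlog,expression_sdlog Lognormal parameters of the
#'   day-1 reporter intensity.
#' @param expression_effect_death,expression_effect_puncta Optional log-linear
#'   effect of standardized log day-1 expression on the respective hazard
#'   (0 = off).
#' @param day1_puncta_effect_death Optional extra log hazard of death for
#'   cells already punctate at day 1.
#' @param censor_day Administrative censoring day (>= first imaging day).
#' @param imaging_days Ordered integer imaging days, starting at day 1.
#' @param n_experiments Number of experimental replicates (strata).
#' @param wells_per_experiment Number of wells per experiment.
#' @param diffuse_cv_mean,diffuse_cv_sd,punctate_cv_mean,punctate_cv_sd
#'   Parameters of the truncated-normal CV regimes for diffuse
#'   (truncated at 0) and punctate (truncated above the classification
#'   threshold) observations.
#' @param cv_threshold Threshold separating the two regimes (used for the
#'   punctate truncation bound).
#' @param seed Integer seed.
#' @return A list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_cells = 2000L,
                              groups = c("iRFP", "WT", "A282V", "M446R",
                                         "P497H", "P497S", "P506T"),
                              log_hazard_death = stats::setNames(rep(0, length(groups)), groups),
                              log_hazard_puncta = stats::setNames(rep(0, length(groups)), groups),
                              baseline_death_rate = 0.11,
                              baseline_puncta_rate = 0.25,
                              expression_meanlog = log(500),
                              expression_sdlog = 0.5,
                              expression_effect_death = 0,
                              expression_effect_puncta = 0,
                              day1_puncta_effect_death = 0,
                              censor_day = 10,
                              imaging_days = 1:10,
                              n_experiments = 3L,
                              wells_per_experiment = 8L,
                              diffuse_cv_mean = 0.35, diffuse_cv_sd = 0.10,
                              punctate_cv_mean = 1.0, punctate_cv_sd = 0.15,
                              cv_threshold = 0.62,
                              seed = 1L) {
  check_that(
    "`groups` must be a non-empty character vector" =
      is.character(groups) && length(groups) >= 1L,
    "`n_cells` must be positive" = n_cells >= 1,
    "baseline rates must be positive" =
      baseline_death_rate > 0 && baseline_puncta_rate > 0,
    "`imaging_days` must be strictly increasing" = all(diff(imaging_days) > 0),
    "`censor_day` must not precede the first imaging day" =
      censor_day >= imaging_days[1],
    "`n_experiments` must be >= 1" = n_experiments >= 1
  )
  lh_d <- rep_len(log_hazard_death, length(groups))
  lh_p <- rep_len(log_hazard_puncta, length(groups))
  if (!is.null(names(log_hazard_death))) lh_d <- log_hazard_death[groups]
  if (!is.null(names(log_hazard_puncta))) lh_p <- log_hazard_puncta[groups]
  check_that("log hazards must be defined for every group" =
               !anyNA(lh_d) && !anyNA(lh_p))
  structure(list(n_cells = as.integer(n_cells), groups = groups,
                 log_hazard_death = stats::setNames(as.numeric(lh_d), groups),
                 log_hazard_puncta = stats::setNames(as.numeric(lh_p), groups),
                 baseline_death_rate = baseline_death_rate,
                 baseline_puncta_rate = baseline_puncta_rate,
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 expression_effect_death = expression_effect_death,
                 expression_effect_puncta = expression_effect_puncta,
                 day1_puncta_effect_death = day1_puncta_effect_death,
                 censor_day = censor_day, imaging_days = as.integer(imaging_days),
                 n_experiments = as.integer(n_experiments),
                 wells_per_experiment = as.integer(wells_per_experiment),
                 diffuse_cv_mean = diffuse_cv_mean, diffuse_cv_sd = diffuse_cv_sd,
                 punctate_cv_mean = punctate_cv_mean, punctate_cv_sd = punctate_cv_sd,
                 cv_threshold = cv_threshold, seed = as.integer(seed)),
            class = "cohort_sim_params")
}

# Truncated-normal draws by inverse-CDF (lower truncation only).
rtnorm_lower <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  stats::qnorm(u, mean, sd)
}

#' Simulate a longitudinal single-cell cohort
#'
#' Draws, per cell, a genotype, an experiment/well, a lognormal day-1
#' expression level, and latent death and puncta-formation times from
#' exponential proportional-hazards models; then emits the observed track:
#' one row per imaging day up to (and including) the day death is detected
#' or censoring, with a per-day reporter CV drawn from a punctate regime once
#' the latent puncta time has passed and a diffuse regime before.
#'
#' @param params A [cohort_sim_params()] object.
#' @return A list with `tracks` (long-format data frame: `cell_id`,
#'   `experiment_id`, `well`, `genotype`, `day`, `reporter_mean`,
#'   `reporter_sd`, `cv`, `alive`) and `truth` (one row per cell with latent
#'   event times, linear predictors and day-1 expression).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_cells
    group <- factor(sample(p$groups, n, replace = TRUE), levels = p$groups)
    experiment <- sample.int(p$n_experiments, n, replace = TRUE)
    well <- sprintf("E%d_W%02d", experiment,
                    sample.int(p$wells_per_experiment, n, replace = TRUE))
    expr1 <- stats::rlnorm(n, p$expression_meanlog, p$expression_sdlog)
    z_expr <- (log(expr1) - p$expression_meanlog) / p$expression_sdlog

    lp_puncta <- p$log_hazard_puncta[as.integer(group)] +
      p$expression_effect_puncta * z_expr
    latent_puncta <- stats::rexp(n, p$baseline_puncta_rate * exp(lp_puncta))
    day1_punctate <- latent_puncta <= p$imaging_days[1]

    lp_death <- p$log_hazard_death[as.integer(group)] +
      p$expression_effect_death * z_expr +
      p$day1_puncta_effect_death * day1_punctate
    latent_death <- p$imaging_days[1] +
      stats::rexp(n, p$baseline_death_rate * exp(lp_death))

    days <- p$imaging_days[p$imaging_days <= p$censor_day]
    # death is detected at the first imaging day at/after the latent time
    detect_idx <- findInterval(latent_death, days, left.open = TRUE) + 1L
    death_day <- ifelse(detect_idx <= length(days), days[pmin(detect_idx, length(days))], NA)
    last_day <- ifelse(is.na(death_day), days[length(days)], death_day)

    n_obs <- findInterval(last_day, days)
    cell_row <- rep(seq_len(n), n_obs)
    day <- unlist(lapply(n_obs, function(k) days[seq_len(k)]), use.names = FALSE)
    alive <- !(day == rep(death_day, n_obs)) | is.na(rep(death_day, n_obs))
    alive[is.na(alive)] <- TRUE

    punctate_now <- day >= rep(latent_puncta, n_obs)
    m <- length(day)
    cv <- numeric(m)
    cv[punctate_now] <- rtnorm_lower(sum(punctate_now), p$punctate_cv_mean,
                                     p$punctate_cv_sd, p$cv_threshold)
    cv[!punctate_now] <- rtnorm_lower(sum(!punctate_now), p$diffuse_cv_mean,
                                      p$diffuse_cv_sd, 0)
    # day-to-day multiplicative wobble around the cell's expression level
    mean_int <- rep(expr1, n_obs) * exp(stats::rnorm(m, 0, 0.05))
    mean_int[day == days[1]] <- expr1[cell_row[day == days[1]]]
    cv[!alive] <- NA_real_
    mean_int[!alive] <- NA_real_

    tracks <- data.frame(
      cell_id = sprintf("c%05d", cell_row),
      experiment_id = experiment[cell_row],
      well = well[cell_row],
      genotype = as.character(group)[cell_row],
      day = day,
      reporter_mean = mean_int,
      reporter_sd = cv * mean_int,
      cv = cv,
      alive = alive,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      cell_id = sprintf("c%05d", seq_len(n)),
      genotype = as.character(group),
      experiment_id = experiment,
      well = well,
      expression_day1 = expr1,
      latent_death_day = latent_death,
      latent_puncta_day = latent_puncta,
      lp_death = as.numeric(lp_death),
      lp_puncta = as.numeric(lp_puncta),
      day1_punctate = day1_punctate,
      stringsAsFactors = FALSE
    )
    list(tracks = tracks, truth = truth)
  })
}

#' Parameters for simulated photoconversion decay traces
#'
#' @param half_life Reporter half-life in hours (> 0).
#' @param T0_level Pre-conversion background intensity.
#' @param T1_level Post-conversion peak intensity (> `T0_level`).
#' @param noise_cv Multiplicative Gaussian noise CV on the hourly values.
#' @param hours Ordered post-conversion sampling times in hours.
#' @param n_wells,n_experiments Wells per experiment and experiments.
#' @param condition Condition label attached to every well.
#' @param seed Integer seed.
#' @return A list of class `decay_sim_params`.
#' @export
decay_sim_params <- function(half_life = 10, T0_level = 100, T1_level = 1100,
                             noise_cv = 0.02, hours = 1:14, n_wells = 6L,
                             n_experiments = 3L, condition = "DMSO", seed = 1L) {
  check_that(
    "`half_life` must be positive" = is.numeric(half_life) && half_life > 0,
    "`T1_level` must exceed `T0_level`" = T1_level > T0_level,
    "`noise_cv` must be >= 0" = noise_cv >= 0,
    "`hours` must be increasing and positive" =
      all(hours > 0) && all(diff(hours) > 0),
    "well/experiment counts must be >= 1" = n_wells >= 1 && n_experiments >= 1
  )
  structure(list(half_life = half_life, T0_level = T0_level,
                 T1_level = T1_level, noise_cv = noise_cv, hours = hours,
                 n_wells = as.integer(n_wells),
                 n_experiments = as.integer(n_experiments),
                 condition = condition, seed = as.integer(seed)),
            class = "decay_sim_params")
}

#' Simulate photoconverted-reporter decay traces
#'
#' Per well: a background row at `time_h = -1` (pre-conversion, T0), the
#' post-conversion peak at `time_h = 0` (T1), then hourly intensities
#' following `(T1 - T0) exp(-k t) + T0` with `k = ln 2 / half_life` and
#' multiplicative Gaussian noise. The noiseless trace satisfies the
#' mono-exponential model exactly.
#'
#' @param params A [decay_sim_params()] object.
#' @return A long-format data frame (`well_id`, `experiment_id`, `condition`,
#'   `time_h`, `tritc_intensity`) with a `truth` attribute carrying the
#'   generating `half_life` and rate `k`.
#' @export
simulate_decay_trace <- function(params) {
  stopifnot(inherits(params, "decay_sim_params"))
  p <- params
  k <- log(2) / p$half_life
  with_seed(p$seed, {
    rows <- lapply(seq_len(p$n_experiments), function(e) {
      lapply(seq_len(p$n_wells), function(w) {
        model <- (p$T1_level - p$T0_level) * exp(-k * p$hours) + p$T0_level
        noisy <- model * (1 + if (p$noise_cv > 0)
          stats::rnorm(length(model), 0, p$noise_cv) else 0)
        data.frame(
          well_id = sprintf("E%d_W%02d", e, w),
          experiment_id = e,
          condition = p$condition,
          time_h = c(-1, 0, p$hours),
          tritc_intensity = c(p$T0_level, p$T1_level, noisy),
          stringsAsFactors = FALSE
        )
      })
    })
    out <- do.call(rbind, unlist(rows, recursive = FALSE))
    attr(out, "truth") <- list(half_life = p$half_life, k = k)
    out
  })
}
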