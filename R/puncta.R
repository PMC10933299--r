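#' Coefficient of variation of in-mask pixel intensities
#'
#' SD/mean of the reporter pixels inside a cell mask — the per-cell statistic
#' used to distinguish diffuse from punctate reporter distributions. Invariant
#' under multiplication of all pixels by a positive constant.
#'
#' @param pixels Numeric vector of in-mask pixel intensities.
#' @param sd_convention `"population"` (divide by n, the default) or
#'   `"sample"` (divide by n - 1).
#' @return The dimensionless CV.
#' @export
cell_cv <- function(pixels, sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  pixels <- as.numeric(pixels)
  check_that("empty pixel set" = length(pixels) >= 1)
  m <- mean(pixels)
  if (!is.finite(m) || m <= 0) stop("mean intensity must be positive", call. = FALSE)
  if (length(pixels) == 1L) return(0)
  s <- stats::sd(pixels)
  if (sd_convention == "population") {
    s <- s * sqrt((length(pixels) - 1) / length(pixels))
  }
  s / m
}

#' Classify cells as diffuse or punctate by CV threshold
#'
#' A cell is called punctate when its reporter CV lies strictly above the
#' aggregate threshold (default 0.62).
#'
#' @param cv Numeric vector of per-cell CVs (>= 0).
#' @param threshold Classification threshold (> 0).
#' @return Character vector, `"punctate"` or `"diffuse"`.
#' @export
classify_punctate <- function(cv, threshold = 0.62) {
  check_that("`threshold` must be positive" = threshold > 0,
             "`cv` must be non-negative" = all(cv >= 0, na.rm = TRUE))
  ifelse(cv > threshold, "punctate", "diffuse")
}

#' Extract death and puncta-formation events from longitudinal tracks
#'
#' For every cell: the death event occurs at the first day the cell is
#' observed dead (right-censored at the last observation otherwise); the
#' puncta-formation event occurs at the first day the CV exceeds the
#' threshold, treated as absorbing, and is censored at the earlier of death
#' and last observation if the threshold is never crossed. Cells punctate at
#' their first observation are additionally flagged for day-1 subgroup
#' analyses.
#'
#' @param tracks Long-format track table (see [read_tracks()]): columns
#'   `cell_id`, `experiment_id`, `genotype`, `day`, `cv`, `alive`, and
#'   `reporter_mean`.
#' @param threshold CV classification threshold.
#' @return Data frame with one row per cell: `cell_id`, `genotype`,
#'   `experiment_id`, `death_time`, `death_event`, `puncta_time`,
#'   `puncta_event`, `day1_intensity`, `day1_cv`, `day1_punctate`.
#' @export
extract_events <- function(tracks, threshold = 0.62) {
  need <- c("cell_id", "experiment_id", "genotype", "day", "cv", "alive")
  check_that("tracks must contain the standard columns" = all(need %in% names(tracks)),
             "empty track table" = nrow(tracks) >= 1)
  tracks <- tracks[order(tracks$cell_id, tracks$day), , drop = FALSE]
  idx <- split(seq_len(nrow(tracks)), tracks$cell_id)

  one <- function(i) {
    d <- tracks[i, , drop = FALSE]
    dead <- which(!d$alive)
    if (length(dead) > 0) {
      death_time <- d$day[dead[1]]
      death_event <- 1L
    } else {
      death_time <- d$day[nrow(d)]
      death_event <- 0L
    }
    crossed <- which(d$alive & !is.na(d$cv) & d$cv > threshold)
    if (length(crossed) > 0) {
      puncta_time <- d$day[crossed[1]]
      puncta_event <- 1L
    } else {
      puncta_time <- death_time
      puncta_event <- 0L
    }
    c(death_time = death_time, death_event = death_event,
      puncta_time = puncta_time, puncta_event = puncta_event)
  }
  mat <- vapply(idx, one, c(death_time = 0, death_event = 0,
                            puncta_time = 0, puncta_event = 0))
  first_row <- vapply(idx, `[`, integer(1), 1L)
  has_mean <- "reporter_mean" %in% names(tracks)
  out <- data.frame(
    cell_id = names(idx),
    genotype = tracks$genotype[first_row],
    experiment_id = tracks$experiment_id[first_row],
    death_time = mat["death_time", ],
    death_event = as.integer(mat["death_event", ]),
    puncta_time = mat["puncta_time", ],
    puncta_event = as.integer(mat["puncta_event", ]),
    day1_intensity = if (has_mean) tracks$reporter_mean[first_row] else NA_real_,
    day1_cv = tracks$cv[first_row],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$day1_punctate <- !is.na(out$day1_cv) & out$day1_cv > threshold
  out
}

#' Percentage of living cells with puncta per day
#'
#' For each genotype and imaging day, the percentage of living cells that
#' have (ever) shown a punctate reporter distribution — puncta formation is
#' treated as an absorbing state. When experiment ids are present, the
#' percentage is also averaged across experiments with its SEM.
#'
#' @param tracks Long-format track table.
#' @param threshold CV classification threshold.
#' @return Data frame with columns `genotype`, `day`, `n_alive`,
#'   `n_punctate`, `percent` (pooled), `percent_mean` and `percent_sem`
#'   (across experiments). Days with no living cells in a group yield `NA`.
#' @export
percent_punctate_over_time <- function(tracks, threshold = 0.62) {
  check_that("empty track table" = nrow(tracks) >= 1)
  tracks <- tracks[order(tracks$cell_id, tracks$day), , drop = FALSE]
  crossed <- tracks$alive & !is.na(tracks$cv) & tracks$cv > threshold
  # absorbing: punctate from the first crossing onward, within each cell
  ever <- stats::ave(as.integer(crossed), tracks$cell_id, FUN = cummax) == 1L

  live <- tracks$alive
  key <- interaction(tracks$genotype, tracks$day, tracks$experiment_id, drop = FALSE)
  per_exp <- stats::aggregate(
    cbind(n_alive = as.integer(live), n_punctate = as.integer(live & ever)),
    by = list(genotype = tracks$genotype, day = tracks$day,
              experiment_id = tracks$experiment_id),
    FUN = sum
  )
  per_exp$percent <- ifelse(per_exp$n_alive > 0,
                            100 * per_exp$n_punctate / per_exp$n_alive, NA_real_)

  pooled <- stats::aggregate(
    cbind(n_alive = per_exp$n_alive, n_punctate = per_exp$n_punctate),
    by = list(genotype = per_exp$genotype, day = per_exp$day), FUN = sum
  )
  pooled$percent <- ifelse(pooled$n_alive > 0,
                           100 * pooled$n_punctate / pooled$n_alive, NA_real_)
  reps <- split(per_exp$percent, list(per_exp$genotype, per_exp$day), drop = FALSE)
  keyp <- paste(pooled$genotype, pooled$day, sep = ".")
  pooled$percent_mean <- vapply(keyp, function(k) {
    v <- reps[[k]]; v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  pooled$percent_sem <- vapply(keyp, function(k) sem(reps[[k]]), numeric(1))
  pooled[order(pooled$genotype, pooled$day), , drop = FALSE]
}

#' Group granule complexity scores and summarize
#'
#' Manually scored granule complexity (integer scores 1-4) is grouped into
#' low (1-2) and high (3-4) complexity classes; per-genotype summaries of the
#' scores, and of the mobile fraction per complexity class when available,
#' are returned.
#'
#' @param records Data frame with columns `granule_id`, `genotype`, `score`
#'   (integers 1-4) and optionally `mobile_fraction`.
#' @return List with `assignments` (records plus `complexity_class`),
#'   `score_summary` (per genotype: n, mean, median, sd of scores) and
#'   `mobility_summary` (per genotype and class: n, mean, median, sd of
#'   mobile fraction; `NULL` when no mobile fractions are supplied).
#' @export
group_complexity <- function(records) {
  check_that(
    "records must contain granule_id, genotype, score" =
      all(c("granule_id", "genotype", "score") %in% names(records)),
    "scores must be integers in 1..4" =
      all(records$score %in% 1:4)
  )
  records$complexity_class <- ifelse(records$score <= 2, "low", "high")
  summarize <- function(x) c(n = length(x), mean = mean(x),
                             median = stats::median(x), sd = stats::sd(x))
  sc <- stats::aggregate(score ~ genotype, data = records, FUN = summarize)
  score_summary <- data.frame(genotype = sc$genotype, n = sc$score[, "n"],
                              mean = sc$score[, "mean"],
                              median = sc$score[, "median"],
                              sd = sc$score[, "sd"], stringsAsFactors = FALSE)
  score_summary$sd[score_summary$n == 1] <- NA_real_
  score_summary$sd[is.nan(score_summary$sd)] <- 0

  mobility_summary <- NULL
  if ("mobile_fraction" %in% names(records) &&
      any(!is.na(records$mobile_fraction))) {
    mm <- records[!is.na(records$mobile_fraction), , drop = FALSE]
    mo <- stats::aggregate(mobile_fraction ~ genotype + complexity_class,
                           data = mm, FUN = summarize)
    mobility_summary <- data.frame(
      genotype = mo$genotype, complexity_class = mo$complexity_class,
      n = mo$mobile_fraction[, "n"], mean = mo$mobile_fraction[, "mean"],
      median = mo$mobile_fraction[, "median"], sd = mo$mobile_fraction[, "sd"],
      stringsAsFactors = FALSE)
    mobility_summary <- mobility_summary[order(mobility_summary$genotype,
                                               mobility_summary$complexity_class), ]
  }
  list(assignments = records, score_summary = score_summary,
       mobility_summary = mobility_summary)
}
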