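#' Fit a Cox proportional-hazards group contrast
#'
#' Stratified Cox regression of event times on a group factor, with Efron
#' handling of tied event times (imaging at discrete days produces heavy
#' ties). Returns one hazard ratio per non-reference group with Wald 95%
#' confidence limits and p-values, mirroring the risk tables of longitudinal
#' single-cell survival studies.
#'
#' @param records Data frame with columns `time` (> 0), `event` (0/1),
#'   `group`, and optionally `stratum`.
#' @param reference Reference group label (default: first level present).
#' @param strata Logical or column name: stratify baseline hazards by
#'   `stratum` (separate risk sets per experiment date).
#' @return An object of class `cox_result`: a list with `table` (term, n,
#'   hazard_ratio, ci_low, ci_high, p, beta, se, flagged), `reference`,
#'   `strata` description, `n_events`, and the underlying
#'   [survival::coxph()] fit in `model`.
#' @export
fit_cox <- function(records, reference = NULL, strata = "stratum") {
  check_that(
    "records must contain time, event, group" =
      all(c("time", "event", "group") %in% names(records)),
    "`time` must be positive" = all(records$time > 0),
    "`event` must be 0 or 1" = all(records$event %in% c(0L, 1L)),
    "at least one observed event is required" = sum(records$event) >= 1
  )
  g <- factor(records$group)
  check_that("at least two groups are required" = nlevels(g) >= 2)
  if (is.null(reference)) reference <- levels(g)[1]
  check_that("`reference` must be a present group label" =
               reference %in% levels(g))
  g <- stats::relevel(g, ref = reference)
  d <- data.frame(time = records$time, event = records$event, group = g)
  use_strata <- isFALSE(is.null(strata)) && !isFALSE(strata) &&
    strata %in% names(records)
  if (use_strata) d$stratum <- records[[strata]]
  fml <- if (use_strata) {
    survival::Surv(time, event) ~ group + survival::strata(stratum)
  } else {
    survival::Surv(time, event) ~ group
  }
  flagged_warn <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w), ignore.case = TRUE)) {
        flagged_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  terms <- sub("^group", "", names(beta))
  # monotone-likelihood (separation) shows up as runaway coefficients or SEs
  flagged <- flagged_warn | !is.finite(beta) | !is.finite(se) |
    abs(beta) > 15 | se > 100
  z <- beta / se
  tab_counts <- table(g)
  tab <- data.frame(
    term = terms,
    n = as.integer(tab_counts[terms]),
    hazard_ratio = exp(beta),
    ci_low = exp(beta - stats::qnorm(0.975) * se),
    ci_high = exp(beta + stats::qnorm(0.975) * se),
    p = 2 * stats::pnorm(-abs(z)),
    beta = beta,
    se = se,
    flagged = as.logical(flagged),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(
    table = tab,
    reference = reference,
    n_reference = as.integer(tab_counts[reference]),
    strata = if (use_strata) strata else "",
    n_events = sum(d$event),
    model = fit
  ), class = "cox_result")
}

#' Rank-based quintile binning
#'
#' Assigns each value to one of five near-equal bins by rank, lowest values
#' in quintile 1. Ties are resolved by stable first-occurrence order, so bin
#' sizes differ by at most one.
#'
#' @param values Numeric vector (length >= 5).
#' @param basis Label recording what was binned (`"expression"` or `"cv"`).
#' @return Data frame with columns `value`, `quintile` (integer 1-5),
#'   `basis`.
#' @export
quintile_bin <- function(values, basis = c("expression", "cv")) {
  basis <- match.arg(basis)
  n <- length(values)
  check_that("at least 5 values are required for quintile binning" = n >= 5,
             "values must be non-missing" = !anyNA(values))
  r <- rank(values, ties.method = "first")
  data.frame(value = values, quintile = as.integer(ceiling(5 * r / n)),
             basis = basis, stringsAsFactors = FALSE)
}

#' Hazard ratios across quintiles of expression or CV
#'
#' Within each group (population), cells are binned into quintiles of their
#' day-1 measurement (expression intensity or CV) and the hazard of each
#' quintile relative to the lowest quintile is estimated by stratified Cox
#' regression.
#'
#' @param events Per-cell event table (see [extract_events()] /
#'   [event_records()]): columns `time`, `event`, `group`, `stratum`, and the
#'   binning covariate.
#' @param basis `"expression"` (bins `day1_intensity`) or `"cv"` (bins
#'   `day1_cv`).
#' @param value_col Override for the column to bin on.
#' @return Data frame with one row per group x quintile: `group`, `quintile`,
#'   `n`, `hazard_ratio`, `ci_low`, `ci_high`, `p` (quintile 1 rows carry
#'   HR 1 by construction, as the reference).
#' @export
hazard_by_quintile <- function(events, basis = c("expression", "cv"),
                               value_col = NULL) {
  basis <- match.arg(basis)
  if (is.null(value_col)) {
    value_col <- if (basis == "expression") "day1_intensity" else "day1_cv"
  }
  check_that("binning covariate missing from events" =
               value_col %in% names(events))
  out <- lapply(split(events, events$group, drop = TRUE), function(d) {
    grp <- as.character(d$group[1])
    qs <- quintile_bin(d[[value_col]], basis = basis)
    d$quintile <- qs$quintile
    check_that("empty quintile" = all(tabulate(d$quintile, 5) > 0))
    rec <- data.frame(time = d$time, event = d$event,
                      group = paste0("Q", d$quintile),
                      stratum = if ("stratum" %in% names(d)) d$stratum else 1)
    res <- fit_cox(rec, reference = "Q1", strata = "stratum")
    ref_row <- data.frame(term = "Q1", n = res$n_reference, hazard_ratio = 1,
                          ci_low = 1, ci_high = 1, p = NA_real_,
                          beta = 0, se = NA_real_, flagged = FALSE,
                          stringsAsFactors = FALSE)
    tab <- rbind(ref_row, res$table)
    data.frame(group = grp, quintile = as.integer(sub("^Q", "", tab$term)),
               n = tab$n, hazard_ratio = tab$hazard_ratio, ci_low = tab$ci_low,
               ci_high = tab$ci_high, p = tab$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$group, out$quintile), , drop = FALSE]
}

#' Diffuse-versus-punctate subgroup hazard analysis
#'
#' Splits each genotype by whether the reporter was punctate on the first
#' imaging day, then fits two contrast families: (a) each diffuse and
#' punctate subgroup against the control population, and (b) within each
#' genotype, punctate against diffuse.
#'
#' @param events Per-cell event table with `time`, `event`, `group`,
#'   `stratum` and a logical `day1_punctate` column.
#' @param control Control group label (its punctate status is ignored; it is
#'   the reference arm of family (a)).
#' @return List with two data frames, `vs_control` and `within_genotype`,
#'   each in risk-table layout (`group`, `subgroup`, `n`, `hazard_ratio`,
#'   `ci_low`, `ci_high`, `p`). Empty subgroups are omitted with a warning.
#' @export
diffuse_vs_punctate_analysis <- function(events, control) {
  check_that(
    "events must contain day1_punctate" = "day1_punctate" %in% names(events),
    "`control` must be present in the data" =
      control %in% as.character(events$group)
  )
  ctrl <- events[events$group == control, , drop = FALSE]
  check_that("control group is empty" = nrow(ctrl) > 0)
  genos <- setdiff(unique(as.character(events$group)), control)
  has_stratum <- "stratum" %in% names(events)

  vs_control <- list(); within <- list()
  for (g in genos) {
    dg <- events[events$group == g, , drop = FALSE]
    for (state in c(FALSE, TRUE)) {
      sub <- dg[dg$day1_punctate == state, , drop = FALSE]
      lab <- if (state) "punctate" else "diffuse"
      if (nrow(sub) == 0) {
        warning(sprintf("subgroup %s/%s has no members; omitted", g, lab),
                call. = FALSE)
        next
      }
      d2 <- rbind(
        data.frame(time = ctrl$time, event = ctrl$event, group = control,
                   stratum = if (has_stratum) ctrl$stratum else 1),
        data.frame(time = sub$time, event = sub$event, group = g,
                   stratum = if (has_stratum) sub$stratum else 1)
      )
      if (sum(d2$event) == 0) next
      res <- fit_cox(d2, reference = control, strata = "stratum")
      vs_control[[paste(g, lab)]] <- data.frame(
        group = g, subgroup = lab, n = res$table$n,
        hazard_ratio = res$table$hazard_ratio, ci_low = res$table$ci_low,
        ci_high = res$table$ci_high, p = res$table$p, stringsAsFactors = FALSE)
    }
    both <- dg[!is.na(dg$day1_punctate), , drop = FALSE]
    if (length(unique(both$day1_punctate)) == 2 && sum(both$event) > 0) {
      d3 <- data.frame(time = both$time, event = both$event,
                       group = ifelse(both$day1_punctate, "punctate", "diffuse"),
                       stratum = if (has_stratum) both$stratum else 1)
      res <- fit_cox(d3, reference = "diffuse", strata = "stratum")
      within[[g]] <- data.frame(
        group = g, subgroup = "punctate vs diffuse", n = res$table$n,
        hazard_ratio = res$table$hazard_ratio, ci_low = res$table$ci_low,
        ci_high = res$table$ci_high, p = res$table$p, stringsAsFactors = FALSE)
    } else {
      warning(sprintf("genotype %s lacks both day-1 states; within-genotype contrast omitted", g),
              call. = FALSE)
    }
  }
  list(vs_control = do.call(rbind, c(vs_control, list(make.row.names = FALSE))),
       within_genotype = do.call(rbind, c(within, list(make.row.names = FALSE))))
}

#' Build event records for Cox analysis from extracted events
#'
#' Reshapes the per-cell output of [extract_events()] into the `time`/
#' `event`/`group`/`stratum` layout used by the hazard functions, for either
#' the death or the puncta-formation endpoint.
#'
#' @param events Output of [extract_events()].
#' @param type `"death"` or `"puncta"`.
#' @return Data frame with columns `cell_id`, `time`, `event`, `group`,
#'   `stratum`, `day1_intensity`, `day1_cv`, `day1_punctate`.
#' @export
event_records <- function(events, type = c("death", "puncta")) {
  type <- match.arg(type)
  time <- if (type == "death") events$death_time else events$puncta_time
  ev <- if (type == "death") events$death_event else events$puncta_event
  data.frame(cell_id = events$cell_id, time = time, event = ev,
             group = events$genotype, stratum = events$experiment_id,
             day1_intensity = events$day1_intensity, day1_cv = events$day1_cv,
             day1_punctate = events$day1_punctate, stringsAsFactors = FALSE)
}

#' Format Cox results as a publication-style risk table
#'
#' Renders hazard ratios with four decimal places, confidence bounds, and
#' p-values in scientific notation below 1e-3; optionally writes the table
#' to CSV.
#'
#' @param results A `cox_result` object or a data frame with columns
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p` plus identifier columns.
#' @param path Optional CSV output path.
#' @return Data frame of formatted character columns (identifiers untouched).
#' @export
risk_table_report <- function(results, path = NULL) {
  if (inherits(results, "cox_result")) {
    tab <- results$table
    tab <- rbind(
      data.frame(term = results$reference, n = results$n_reference,
                 hazard_ratio = 1, ci_low = 1, ci_high = 1, p = NA_real_,
                 beta = 0, se = NA_real_, flagged = FALSE,
                 stringsAsFactors = FALSE),
      tab)
    tab <- tab[, c("term", "n", "hazard_ratio", "ci_low", "ci_high", "p")]
  } else {
    tab <- as.data.frame(results)
  }
  check_that("at least one result row is required" = nrow(tab) >= 1)
  fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.4f", x))
  fmt_p <- function(p) ifelse(is.na(p), "",
                              ifelse(p < 1e-3, sprintf("%.2e", p), sprintf("%.4f", p)))
  for (col in intersect(c("hazard_ratio", "ci_low", "ci_high"), names(tab))) {
    tab[[col]] <- fmt_num(tab[[col]])
  }
  if ("p" %in% names(tab)) tab$p <- fmt_p(tab$p)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  tab
}
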