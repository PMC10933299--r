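#' Normalize a FRAP recovery trace
#'
#' Applies the standard two-point affine normalization: when a whole-granule
#' channel is present, each timepoint is first expressed as the ratio of
#' bleached-ROI to whole-granule integrated density; the series is then
#' mapped so the mean of the pre-bleach values is 1 and the first post-bleach
#' value is 0.
#'
#' @param trace Data frame with columns `time_s`, `phase` (`"pre"`/`"post"`),
#'   `bleached_intensity` and optionally `whole_intensity` (e.g. from
#'   [simulate_frap_trace()] or [read_frap_traces()]).
#' @return A data frame of class `frap_norm` with columns `time_s`, `phase`,
#'   `value`; post-bleach times are re-expressed relative to the first
#'   post-bleach frame (t = 0).
#' @export
normalize_frap_trace <- function(trace) {
  need <- c("time_s", "phase", "bleached_intensity")
  check_that(
    "trace must contain time_s, phase and bleached_intensity" =
      all(need %in% names(trace))
  )
  trace <- trace[order(trace$time_s), , drop = FALSE]
  pre <- trace$phase == "pre"
  post <- trace$phase == "post"
  check_that(
    "at least 2 pre-bleach and 3 post-bleach samples are required" =
      sum(pre) >= 2 && sum(post) >= 3
  )
  y <- trace$bleached_intensity
  if ("whole_intensity" %in% names(trace) && !all(is.na(trace$whole_intensity))) {
    check_that("whole_intensity must be positive where present" =
                 all(trace$whole_intensity > 0, na.rm = TRUE))
    y <- y / trace$whole_intensity
  }
  pre_mean <- mean(y[pre])
  post0 <- y[post][which.min(trace$time_s[post])]
  depth <- pre_mean - post0
  if (depth == 0) stop("zero bleach depth", call. = FALSE)
  t0 <- min(trace$time_s[post])
  out <- data.frame(
    time_s = trace$time_s - ifelse(trace$phase == "post", t0, 0),
    phase = trace$phase,
    value = (y - post0) / depth,
    stringsAsFactors = FALSE
  )
  # already-normalized input (pre mean 1, first post 0) maps to itself
  class(out) <- c("frap_norm", "data.frame")
  out
}

#' Fit a mono-exponential FRAP recovery curve
#'
#' Least-squares fit of `y(t) = A (1 - exp(-tau t))` to the post-bleach
#' portion of a normalized recovery series, where `A` is the mobile fraction
#' and `tau` the recovery rate constant. Initial values follow a simple
#' plateau/half-rise heuristic; `A` is bounded to `[0, 1.5]` and `tau` to
#' `(0, 10]` per second.
#'
#' @param norm A normalized trace from [normalize_frap_trace()], or any data
#'   frame with columns `time_s`, `phase`, `value`.
#' @param granule_id,genotype Optional labels stored in the fit.
#' @return An object of class `frap_fit` with components `mobile_fraction`,
#'   `rate`, `t_half`, `rss`, `n_points`, `converged`, and the fitted data.
#' @seealso [half_time()], [diffusion_coefficient()], [viscosity()],
#'   [frap_physics()]
#' @export
fit_recovery <- function(norm, granule_id = NA_character_,
                         genotype = NA_character_) {
  check_that("`norm` must have columns time_s, phase, value" =
               all(c("time_s", "phase", "value") %in% names(norm)))
  d <- norm[norm$phase == "post", , drop = FALSE]
  d <- d[order(d$time_s), , drop = FALSE]
  check_that("at least 3 post-bleach points are required" = nrow(d) >= 3,
             "post-bleach times must start at 0" = min(d$time_s) == 0)
  t <- d$time_s
  y <- d$value
  if (stats::sd(y) == 0) stop("unidentifiable tau: constant series", call. = FALSE)

  a0 <- max(utils::tail(y, 3))
  a0 <- min(max(a0, 1e-3), 1.5)
  i_half <- which(y >= a0 / 2)[1]
  t_half0 <- if (!is.na(i_half) && t[i_half] > 0) t[i_half] else stats::median(t[t > 0])
  tau0 <- min(max(log(2) / t_half0, 1e-4), 10)

  fit <- minpack.lm::nlsLM(
    y ~ A * (1 - exp(-tau * t)),
    start = list(A = a0, tau = tau0),
    lower = c(A = 0, tau = 1e-8), upper = c(A = 1.5, tau = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  if (cf[["tau"]] <= 0) stop("unidentifiable tau", call. = FALSE)
  structure(list(
    mobile_fraction = unname(cf[["A"]]),
    rate = unname(cf[["tau"]]),
    t_half = half_time(cf[["tau"]]),
    rss = sum(stats::resid(fit)^2),
    n_points = nrow(d),
    converged = fit$convInfo$isConv %||% TRUE,
    granule_id = granule_id,
    genotype = genotype,
    data = d
  ), class = "frap_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Half-maximal recovery time from a rate constant
#'
#' `t_half = ln 2 / tau` for a mono-exponential recovery with rate `tau`.
#'
#' @param tau Rate constant in s^-1 (> 0).
#' @return Time to half-maximal recovery in seconds.
#' @export
half_time <- function(tau) {
  check_that("`tau` must be positive" = is.numeric(tau) && all(tau > 0))
  log(2) / tau
}

#' Effective diffusion coefficient from FRAP half-time
#'
#' `D = 0.88 r^2 / (4 t_half)` for a circular bleach spot of radius `r`.
#'
#' @param roi_radius_um Bleach-spot radius in micrometres (> 0).
#' @param t_half_s Half-maximal recovery time in seconds (> 0).
#' @return Diffusion coefficient in um^2/s.
#' @export
diffusion_coefficient <- function(roi_radius_um, t_half_s) {
  check_that("inputs must be positive" =
               all(roi_radius_um > 0) && all(t_half_s > 0))
  0.88 * roi_radius_um^2 / (4 * t_half_s)
}

#' Minimum Stokes radius of a globular protein
#'
#' `R_min = (0.66 M)^(1/3)` with the molecular weight `M` in daltons; the
#' formula yields the radius in angstroms, reported here in nanometres.
#'
#' @param molecular_weight Molecular weight in daltons (> 0).
#' @return Stokes radius in nanometres.
#' @export
stokes_radius <- function(molecular_weight) {
  check_that("`molecular_weight` must be positive" = all(molecular_weight > 0))
  (0.66 * molecular_weight)^(1 / 3) / 10
}

#' Viscosity from the Einstein-Stokes relation
#'
#' Inverts `D = k_B T / (6 pi eta r)` for the viscosity `eta`, with
#' `k_B = 1.380649e-23` J/K.
#'
#' @param D_um2_s Diffusion coefficient in um^2/s (> 0).
#' @param stokes_radius_nm Particle Stokes radius in nanometres (> 0).
#' @param temperature_K Absolute temperature in kelvin (default 310 K,
#'   cell-culture conditions).
#' @return Viscosity in Pa s.
#' @export
viscosity <- function(D_um2_s, stokes_radius_nm = 4.5, temperature_K = 310) {
  check_that("inputs must be positive" =
               all(D_um2_s > 0) && all(stokes_radius_nm > 0) && all(temperature_K > 0))
  k_b <- 1.380649e-23
  D_si <- D_um2_s * 1e-12      # m^2/s
  r_si <- stokes_radius_nm * 1e-9
  k_b * temperature_K / (6 * pi * D_si * r_si)
}

#' Derived physical quantities for a FRAP fit
#'
#' Augments a [fit_recovery()] result with the diffusion coefficient and
#' apparent viscosity of the bleached structure.
#'
#' @param fit A `frap_fit` object.
#' @param roi_radius_um Bleach-spot radius in micrometres.
#' @param stokes_radius_nm Assumed Stokes radius of the diffusing species in
#'   nanometres.
#' @param temperature_K Absolute temperature in kelvin.
#' @return The fit, with `diffusion_um2_s`, `viscosity_pa_s`,
#'   `stokes_radius_nm`, `roi_radius_um` and `temperature_K` added.
#' @export
frap_physics <- function(fit, roi_radius_um = 3.7, stokes_radius_nm = 4.5,
                         temperature_K = 310) {
  stopifnot(inherits(fit, "frap_fit"))
  fit$roi_radius_um <- roi_radius_um
  fit$temperature_K <- temperature_K
  fit$stokes_radius_nm <- stokes_radius_nm
  fit$diffusion_um2_s <- diffusion_coefficient(roi_radius_um, fit$t_half)
  fit$viscosity_pa_s <- viscosity(fit$diffusion_um2_s, stokes_radius_nm,
                                  temperature_K)
  fit
}

#' Summarize recovery curves across granules
#'
#' Computes per-timepoint mean and SEM of normalized recovery across granules
#' within each genotype. Optionally each granule's series is first divided by
#' its fitted mobile fraction ("plateau normalization"), so curves with
#' different plateaus can be compared on kinetics alone.
#'
#' @param norm_list Named list of normalized traces (names = granule ids), or
#'   a long data frame with columns `granule_id`, `genotype`, `time_s`,
#'   `phase`, `value`.
#' @param genotypes Character vector of genotype labels, one per granule
#'   (ignored when `norm_list` is a long data frame).
#' @param fits Named list of `frap_fit` objects (required when
#'   `plateau_normalize = TRUE`).
#' @param plateau_normalize Divide each granule's series by its fitted mobile
#'   fraction before averaging.
#' @return Data frame with columns `genotype`, `time_s`, `mean`, `sem`, `n`.
#' @export
summarize_recovery <- function(norm_list, genotypes = NULL, fits = NULL,
                               plateau_normalize = FALSE) {
  if (is.data.frame(norm_list)) {
    long <- norm_list
    check_that("long input needs granule_id, genotype, time_s, phase, value" =
                 all(c("granule_id", "genotype", "time_s", "phase", "value") %in%
                       names(long)))
  } else {
    check_that("`norm_list` must be non-empty" = length(norm_list) >= 1,
               "`genotypes` must label every granule" =
                 !is.null(genotypes) && length(genotypes) == length(norm_list))
    ids <- names(norm_list) %||% sprintf("g%d", seq_along(norm_list))
    long <- do.call(rbind, Map(function(d, id, g) {
      data.frame(granule_id = id, genotype = g, d, stringsAsFactors = FALSE)
    }, norm_list, ids, genotypes))
  }
  long <- long[long$phase == "post", , drop = FALSE]
  check_that("no post-bleach samples to summarize" = nrow(long) > 0)
  if (plateau_normalize) {
    check_that("`fits` must be a named list covering every granule" =
                 !is.null(fits) && all(unique(long$granule_id) %in% names(fits)))
    a <- vapply(fits, function(f) f$mobile_fraction, numeric(1))
    long$value <- long$value / a[long$granule_id]
  }
  agg <- stats::aggregate(value ~ genotype + time_s, data = long,
                          FUN = function(v) c(mean = mean(v), sem = sem(v),
                                              n = length(v)))
  out <- data.frame(genotype = agg$genotype, time_s = agg$time_s,
                    mean = agg$value[, "mean"], sem = agg$value[, "sem"],
                    n = agg$value[, "n"], stringsAsFactors = FALSE)
  out$sem[is.na(out$sem) & out$n == 1] <- 0
  out$sem[out$n > 1 & is.na(out$sem)] <- 0
  out[order(out$genotype, out$time_s), , drop = FALSE]
}
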