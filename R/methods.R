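#' @export
print.frap_fit <- function(x, digits = 4, ...) {
  cat("Mono-exponential FRAP recovery fit\n")
  if (!is.na(x$granule_id)) cat("  granule:", x$granule_id,
                                if (!is.na(x$genotype)) paste0("(", x$genotype, ")"), "\n")
  cat(sprintf("  mobile fraction A : %.*f\n", digits, x$mobile_fraction))
  cat(sprintf("  rate tau          : %.*g s^-1\n", digits, x$rate))
  cat(sprintf("  t_half            : %.*g s\n", digits, x$t_half))
  if (!is.null(x$viscosity_pa_s)) {
    cat(sprintf("  D                 : %.*g um^2/s\n", digits, x$diffusion_um2_s))
    cat(sprintf("  viscosity         : %.*g Pa s (r_s = %g nm, T = %g K)\n",
                digits, x$viscosity_pa_s, x$stokes_radius_nm, x$temperature_K))
  }
  cat(sprintf("  RSS %.3g on %d post-bleach points\n", x$rss, x$n_points))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(A = object$mobile_fraction, tau = object$rate)
}

#' @export
summary.frap_fit <- function(object, ...) {
  out <- data.frame(
    granule_id = object$granule_id, genotype = object$genotype,
    mobile_fraction = object$mobile_fraction, rate = object$rate,
    t_half_s = object$t_half,
    diffusion_um2_s = object$diffusion_um2_s %||% NA_real_,
    viscosity_pa_s = object$viscosity_pa_s %||% NA_real_,
    rss = object$rss, n_points = object$n_points,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary.frap_fit", "data.frame")
  out
}

#' @export
predict.frap_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time_s
  object$mobile_fraction * (1 - exp(-object$rate * times))
}

#' @export
residuals.frap_fit <- function(object, ...) {
  object$data$value - predict(object)
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$data$time_s, x$data$value, xlab = "time after bleach (s)",
                 ylab = "normalized recovery",
                 main = if (!is.na(x$granule_id)) x$granule_id else "FRAP recovery",
                 ...)
  tt <- seq(0, max(x$data$time_s), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  graphics::abline(h = x$mobile_fraction, lty = 3)
  invisible(x)
}

#' @export
simulate.frap_fit <- function(object, nsim = 1, seed = NULL, noise_sd = 0.02, ...) {
  seed <- seed %||% 1L
  lapply(seq_len(nsim), function(i) {
    simulate_frap_trace(frap_sim_params(
      mobile_fraction = object$mobile_fraction, rate = object$rate,
      noise_sd = noise_sd, schedule = sort(unique(object$data$time_s)),
      seed = substream_seed(seed, i)))
  })
}

#' @export
print.flux_fit <- function(x, digits = 4, ...) {
  cat("Mono-exponential reporter decay fit\n")
  if (!is.na(x$well_id)) cat("  well:", x$well_id, "\n")
  cat(sprintf("  k         : %.*g h^-1\n", digits, x$k))
  cat(sprintf("  half-life : %.*g h\n", digits, x$half_life))
  cat(sprintf("  RSS %.3g on %d timepoints (%s normalization)\n",
              x$rss, x$n_timepoints, x$mode))
  if (isTRUE(x$flagged)) cat("  ** flagged: non-decaying series **\n")
  invisible(x)
}

#' @export
coef.flux_fit <- function(object, ...) {
  c(k = object$k, scale = object$scale)
}

#' @export
predict.flux_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time_h
  object$scale * exp(-object$k * times)
}

#' @export
residuals.flux_fit <- function(object, ...) {
  object$data$value - predict(object)
}

#' @export
plot.flux_fit <- function(x, ...) {
  graphics::plot(x$data$time_h, x$data$value, xlab = "time after conversion (h)",
                 ylab = "normalized intensity", ...)
  tt <- seq(0, max(x$data$time_h), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "steelblue", lwd = 2)
  invisible(x)
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional hazards contrasts (reference:", x$reference, ")\n")
  if (!is.null(x$strata) && nzchar(x$strata)) cat("  stratified by", x$strata, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
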