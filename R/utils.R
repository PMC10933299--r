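#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so that seeded generators do not disturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a reproducible sub-seed for an independent generator substream.
# Offsets keep the substreams of one pipeline run distinct; the modulus keeps
# the result a valid 32-bit integer seed.
substream_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

# Stop unless all named conditions hold; names are the error messages.
check_that <- function(...) {
  conds <- list(...)
  msgs <- names(conds)
  for (i in seq_along(conds)) {
    if (!isTRUE(all(conds[[i]]))) stop(msgs[i], call. = FALSE)
  }
  invisible(TRUE)
}

# Standard error of the mean; NA when fewer than two values.
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
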