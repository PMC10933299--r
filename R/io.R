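#' Read and validate a longitudinal track table
#'
#' Reads the long-format per-cell track CSV (one row per cell per imaging
#' day). The CV is computed as `reporter_sd / reporter_mean` when absent;
#' a `cv` column present in the file is used verbatim, never recomputed.
#'
#' @param path CSV path (UTF-8, header required) with columns `cell_id`,
#'   `experiment_id`, `well`, `genotype`, `day`, `reporter_mean`,
#'   `reporter_sd`, `alive` and optionally `cv`.
#' @return Validated data frame sorted by `cell_id`, `day`.
#' @export
read_tracks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_tracks(d)
}

#' Validate an in-memory track table
#'
#' @param d Data frame in the [read_tracks()] layout.
#' @return The table, sorted and with `cv` filled in where absent.
#' @export
validate_tracks <- function(d) {
  need <- c("cell_id", "experiment_id", "well", "genotype", "day",
            "reporter_mean", "reporter_sd", "alive")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d$alive <- as.logical(d$alive)
  check_that("`day` must be >= 1" = all(d$day >= 1, na.rm = TRUE))
  dup <- duplicated(d[, c("cell_id", "day")])
  if (any(dup)) {
    stop(sprintf("duplicate (cell_id, day) at row %d: %s day %s",
                 which(dup)[1], d$cell_id[which(dup)[1]], d$day[which(dup)[1]]),
         call. = FALSE)
  }
  d <- d[order(d$cell_id, d$day), , drop = FALSE]
  # a dead cell must not reappear alive
  resurrect <- stats::ave(as.integer(!d$alive), d$cell_id, FUN = cummax) == 1L &
    d$alive
  if (any(resurrect)) {
    stop(sprintf("cell %s is observed alive after death",
                 d$cell_id[which(resurrect)[1]]), call. = FALSE)
  }
  if (!"cv" %in% names(d)) {
    check_that("reporter_mean must be positive for living observations" =
                 all(d$reporter_mean[d$alive] > 0, na.rm = TRUE))
    d$cv <- d$reporter_sd / d$reporter_mean
  }
  rownames(d) <- NULL
  d
}

#' Write a track table to CSV
#'
#' @param tracks Track table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read FRAP traces from CSV
#'
#' @param path CSV with columns `granule_id`, `genotype`, `time_s`, `phase`
#'   (`pre`/`post`), `bleached_intensity`, optionally `whole_intensity` and
#'   `roi_radius_um`.
#' @return A named list of per-granule data frames.
#' @export
read_frap_traces <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("granule_id", "genotype", "time_s", "phase", "bleached_intensity")
  check_that("missing required FRAP trace columns" = all(need %in% names(d)),
             "phase must be 'pre' or 'post'" = all(d$phase %in% c("pre", "post")))
  split(d, d$granule_id, drop = TRUE)
}

#' Read a decay table from CSV
#'
#' @param path CSV with columns `well_id`, `experiment_id`, `condition`,
#'   `time_h` (-1 = pre-conversion background, 0 = post-conversion peak),
#'   `tritc_intensity`.
#' @return Data frame.
#' @export
read_decay <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("well_id", "experiment_id", "condition", "time_h", "tritc_intensity")
  check_that("missing required decay columns" = all(need %in% names(d)))
  d
}

#' Write a 16-bit grayscale TIFF image
#'
#' @param img Numeric matrix of intensities in `[0, 65535]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  check_that("image values must lie in [0, 65535]" =
               all(img >= 0) && all(img <= 65535))
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit grayscale TIFF image
#'
#' @param path TIFF path (single plane, grayscale).
#' @return Numeric matrix of raw integer intensities.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  check_that("image must be single-plane grayscale" = length(dim(img)) == 2)
  img
}

# Otsu threshold on the morphology channel; EBImage supplies the method.
otsu_mask <- function(morphology) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("mask-free image reading needs the EBImage package for Otsu thresholding; ",
         "supply a mask instead", call. = FALSE)
  }
  rng <- range(morphology)
  if (diff(rng) == 0) stop("morphology channel is constant; cannot segment",
                           call. = FALSE)
  scaled <- (morphology - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  morphology > rng[1] + thr * diff(rng)
}

#' Per-cell intensity statistics from an image pair
#'
#' Computes in-mask mean, SD and CV of the reporter channel. When no mask is
#' given, the cell mask is obtained by Otsu thresholding of the morphology
#' channel. A labeled (integer) mask yields one row per label.
#'
#' @param reporter,morphology Numeric matrices (or TIFF paths) of matching
#'   dimensions.
#' @param mask Optional logical or integer-labeled matrix (or TIFF path).
#' @param sd_convention Passed to [cell_cv()].
#' @return Data frame with columns `region`, `n_pixels`, `reporter_mean`,
#'   `reporter_sd`, `cv`.
#' @export
read_images <- function(reporter, morphology, mask = NULL,
                        sd_convention = "population") {
  if (is.character(reporter)) reporter <- read_image_tiff(reporter)
  if (is.character(morphology)) morphology <- read_image_tiff(morphology)
  if (is.character(mask)) mask <- read_image_tiff(mask)
  check_that("reporter and morphology dimensions must match" =
               identical(dim(reporter), dim(morphology)))
  if (is.null(mask)) {
    mask <- otsu_mask(morphology)
  }
  check_that("mask dimensions must match the images" =
               identical(dim(mask), dim(reporter)))
  labels <- if (is.logical(mask)) as.integer(mask) else as.integer(round(mask))
  ids <- sort(unique(labels[labels > 0]))
  check_that("empty mask" = length(ids) > 0)
  rows <- lapply(ids, function(id) {
    px <- reporter[labels == id]
    cv <- cell_cv(px, sd_convention = sd_convention)
    m <- mean(px)
    s <- cv * m
    data.frame(region = id, n_pixels = length(px), reporter_mean = m,
               reporter_sd = s, cv = cv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
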