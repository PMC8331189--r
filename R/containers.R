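#' @useDynLib mitoquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov anova lm median qnorm quantile rbinom rnbinom rnorm
#'   rpois runif sd TukeyHSD aggregate ptukey pf pnorm setNames qtukey
#' @importFrom utils write.csv read.csv head
NULL

#' Single-channel calibrated image
#'
#' The elementary raster container of the pipeline: a 2D non-negative
#' intensity matrix plus its physical calibration (micrometres per pixel)
#' and the role the channel plays in the tandem-reporter design.
#'
#' @param data numeric matrix of finite, non-negative intensities.
#' @param pixel_size physical pixel size in micrometres per pixel (> 0).
#' @param role one of `"red"` (mCherry), `"green"` (GFP), `"label"`
#'   (immunolabel, e.g. TH/Iba1/ATPB) or `"nuclei"`.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(data, pixel_size, role = c("red", "green", "label", "nuclei")) {
  role <- match.arg(role)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix")
  if (any(!is.finite(data)))
    stop("channel intensities must all be finite")
  if (any(data < 0))
    stop("channel intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/pixel)")
  structure(list(data = data, pixel_size = pixel_size, role = role),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image: %s, %d x %d px, %.4g um/px, range [%.3g, %.3g]>\n",
              x$role, nrow(x$data), ncol(x$data), x$pixel_size,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Co-registered tandem-reporter image
#'
#' Bundles the mCherry (red) and GFP (green) channels of one field of view,
#' optionally with an immunolabel channel, plus the experimental metadata
#' the downstream statistics need (subject, genotype, treatment).
#'
#' @param red,green `channel_image` objects sharing shape and calibration.
#' @param label optional immunolabel `channel_image` (same shape/calibration).
#' @param image_id,subject_id identifiers carried into every output record.
#' @param genotype one of `"WT"`, `"G2019S"`, `"KO"`.
#' @param treatment one of `"none"`, `"vehicle"`, `"inhibitor"`, `"DFP"`, `"EBSS"`.
#' @return An object of class `reporter_image`.
#' @export
reporter_image <- function(red, green, label = NULL,
                           image_id = "img", subject_id = "subject",
                           genotype = c("WT", "G2019S", "KO"),
                           treatment = c("none", "vehicle", "inhibitor", "DFP", "EBSS")) {
  genotype <- match.arg(genotype)
  treatment <- match.arg(treatment)
  stopifnot(inherits(red, "channel_image"), inherits(green, "channel_image"))
  chans <- list(red, green)
  if (!is.null(label)) {
    stopifnot(inherits(label, "channel_image"))
    chans <- c(chans, list(label))
  }
  dims <- vapply(chans, function(ch) dim(ch$data), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels of a reporter_image must share the same shape")
  px <- vapply(chans, function(ch) ch$pixel_size, numeric(1))
  if (any(abs(px - px[1]) > 1e-12))
    stop("all channels of a reporter_image must share the same pixel size")
  structure(list(red = red, green = green, label = label,
                 image_id = image_id, subject_id = subject_id,
                 genotype = genotype, treatment = treatment),
            class = "reporter_image")
}

#' @export
print.reporter_image <- function(x, ...) {
  cat(sprintf("<reporter_image '%s' (%s, %s/%s): %d x %d px, %.4g um/px%s>\n",
              x$image_id, x$subject_id, x$genotype, x$treatment,
              nrow(x$red$data), ncol(x$red$data), x$red$pixel_size,
              if (is.null(x$label)) "" else ", +label"))
  invisible(x)
}

#' Red/green ratio image
#'
#' Per-pixel acidification index `(red + 1) / (green + 1)`, capped. The +1
#' pseudocount keeps the ratio finite and monotone where GFP is fully
#' quenched; the cap bounds the dynamic range for thresholding.
#'
#' @param red,green co-registered `channel_image` objects.
#' @param ratio_max cap applied to the ratio (default 100).
#' @return An object of class `ratio_image` with fields `values`,
#'   `pixel_size` and `rule`.
#' @export
compute_ratio_image <- function(red, green, ratio_max = 100) {
  stopifnot(inherits(red, "channel_image"), inherits(green, "channel_image"))
  if (!identical(dim(red$data), dim(green$data)))
    stop("red and green channels differ in shape")
  vals <- pmin((red$data + 1) / (green$data + 1), ratio_max)
  structure(list(values = vals, pixel_size = red$pixel_size,
                 rule = sprintf("(red+1)/(green+1) capped at %g", ratio_max),
                 ratio_max = ratio_max),
            class = "ratio_image")
}

#' Boolean region mask with calibrated area
#'
#' @param mask logical matrix.
#' @param pixel_size micrometres per pixel.
#' @param role what the region delineates: whole `"tissue"`, an immunolabelled
#'   `"cell_type_stain"`, a `"cell_body"`, or a `"single_cell_roi"`.
#' @param source id of the channel the mask was derived from (free text).
#' @return An object of class `region_mask`; `area_um2` is the true-pixel
#'   count times `pixel_size^2`.
#' @export
region_mask <- function(mask, pixel_size,
                        role = c("tissue", "cell_type_stain", "cell_body", "single_cell_roi"),
                        source = NA_character_) {
  role <- match.arg(role)
  if (!is.matrix(mask) || !is.logical(mask)) stop("`mask` must be a logical matrix")
  if (anyNA(mask)) stop("`mask` must not contain NA")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("`pixel_size` must be > 0")
  structure(list(mask = mask, pixel_size = pixel_size, role = role,
                 area_um2 = sum(mask) * pixel_size^2, source = source),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask: %s, %d/%d px true, %.4g um^2>\n",
              x$role, sum(x$mask), length(x$mask), x$area_um2))
  invisible(x)
}

#' Threshold configuration for puncta detection
#'
#' One frozen set of thresholds per organ / experiment set, mirroring the
#' original analysis where the same ratio-channel threshold was reused
#' across an experimental batch.
#'
#' @param green_thr tissue-detection threshold on the (filtered) green channel.
#' @param red_thr second red threshold applied to high-ratio pixels
#'   (mitolysosome detection).
#' @param red_high_thr red threshold selecting candidate puncta in the
#'   general-autophagy mode.
#' @param ratio_thr_high red/green ratio above which a pixel/object counts
#'   as acidified (mitolysosome or autolysosome).
#' @param min_area_px minimum object area in pixels (>= 1).
#' @param connectivity pixel connectivity for object labelling, 4 or 8.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(green_thr = 15, red_thr = 50, red_high_thr = 50,
                             ratio_thr_high = 2, min_area_px = 4,
                             connectivity = 8) {
  stopifnot(green_thr >= 0, red_thr >= 0, red_high_thr >= 0, ratio_thr_high >= 0,
            min_area_px >= 1, connectivity %in% c(4, 8))
  structure(list(green_thr = green_thr, red_thr = red_thr,
                 red_high_thr = red_high_thr, ratio_thr_high = ratio_thr_high,
                 min_area_px = as.integer(min_area_px),
                 connectivity = as.integer(connectivity)),
            class = "threshold_config")
}

# Derive the seed of a named substream from the top-level seed.
# All generator randomness flows through these, so a test can replay one
# substream (e.g. the count draws) without replaying the whole scene.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
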