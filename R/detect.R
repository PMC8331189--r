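# Puncta detection: despeckle filter, ratio image, double-threshold
# mitolysosome detection, and autophagosome/autolysosome classification.

#' Despeckle a channel with a median "fine filter"
#'
#' Square-window median filter (window `2*radius + 1`) with edge
#' replication, the standard noise-suppression step applied to both
#' channels before the ratio image is built.
#'
#' @param channel a `channel_image`.
#' @param radius window radius in pixels (>= 1; default 1 gives 3x3).
#' @return The filtered `channel_image` (same shape and calibration).
#' @export
fine_filter <- function(channel, radius = 1) {
  stopifnot(inherits(channel, "channel_image"))
  if (length(channel$data) == 0) stop("cannot filter an empty image")
  if (radius < 1) stop("radius must be >= 1")
  channel$data <- median_filter_cpp(channel$data, as.integer(radius))
  channel
}

#' Threshold a channel into a region mask
#'
#' @param channel a `channel_image`.
#' @param thr intensity threshold (pixels `>= thr` are kept).
#' @param role role recorded on the resulting [region_mask()].
#' @return A `region_mask` with its calibrated area in um^2.
#' @export
threshold_mask <- function(channel, thr, role = "tissue") {
  stopifnot(inherits(channel, "channel_image"), thr >= 0)
  region_mask(channel$data >= thr, channel$pixel_size, role = role,
              source = channel$role)
}

#' Label connected components of a boolean mask
#'
#' Thin wrapper over the compiled two-pass union-find labeller.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask))
  label_components_cpp(mask, as.integer(connectivity))
}

# Build a puncta_set from a label matrix plus the intensity rasters.
# Coordinates are 0-based row/col; areas reported in px and um^2.
puncta_from_labels <- function(labels, red, green, ratio, pixel_size, cfg,
                               image_id = NA_character_, mask_role = NA_character_) {
  n <- attr(labels, "n_components")
  rows <- list(); pixels <- list()
  keep <- 0L
  if (n > 0) {
    idx_all <- which(labels > 0)
    lab_vals <- labels[idx_all]
    nr <- nrow(labels)
    for (k in seq_len(n)) {
      idx <- idx_all[lab_vals == k]
      if (length(idx) < cfg$min_area_px) next
      keep <- keep + 1L
      i0 <- (idx - 1L) %% nr        # 0-based row
      j0 <- (idx - 1L) %/% nr       # 0-based col
      rows[[keep]] <- data.frame(
        id = keep,
        centroid_row = mean(i0), centroid_col = mean(j0),
        area_px = length(idx),
        area_um2 = length(idx) * pixel_size^2,
        mean_red = mean(red[idx]), mean_green = mean(green[idx]),
        mean_ratio = mean(ratio[idx]))
      pixels[[keep]] <- idx
    }
  }
  objects <- if (keep > 0) do.call(rbind, rows) else
    data.frame(id = integer(), centroid_row = numeric(), centroid_col = numeric(),
               area_px = integer(), area_um2 = numeric(), mean_red = numeric(),
               mean_green = numeric(), mean_ratio = numeric())
  structure(list(objects = objects, pixels = pixels,
                 pixel_size = pixel_size, config = cfg,
                 image_id = image_id, mask_role = mask_role,
                 warnings = character()),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cls <- if ("class" %in% names(x$objects)) table(x$objects$class) else NULL
  cat(sprintf("<puncta_set: %d objects%s>\n", nrow(x$objects),
              if (is.null(cls)) "" else
                paste0(" (", paste(names(cls), cls, sep = "=", collapse = ", "), ")")))
  invisible(x)
}

#' Detect mitolysosomes by double thresholding
#'
#' Candidate pixels must have a high red/green ratio (`>= ratio_thr_high`)
#' AND a high red intensity (`>= red_thr`, the second threshold that rejects
#' spurious high-ratio pixels in areas of low reporter expression), within
#' the region of interest. Connected components at the configured
#' connectivity with area `>= min_area_px` become mitolysosome puncta.
#'
#' @param ratio a `ratio_image`.
#' @param red the (filtered) red `channel_image`.
#' @param region a `region_mask` restricting detection (tissue or cell type).
#' @param cfg a [threshold_config()].
#' @param green optional green channel, used only for object statistics.
#' @return A `puncta_set`; all objects carry class `"mitolysosome"`. An
#'   empty region yields an empty set with a warning record, not an error.
#' @export
detect_mitolysosomes <- function(ratio, red, region, cfg = threshold_config(),
                                 green = NULL) {
  stopifnot(inherits(ratio, "ratio_image"), inherits(red, "channel_image"),
            inherits(region, "region_mask"), inherits(cfg, "threshold_config"))
  if (!identical(dim(ratio$values), dim(red$data)) ||
      !identical(dim(ratio$values), dim(region$mask)))
    stop("ratio, red and region must be co-registered (same shape)")
  g <- if (is.null(green)) matrix(NA_real_, nrow(red$data), ncol(red$data)) else green$data
  cand <- (ratio$values >= cfg$ratio_thr_high) & (red$data >= cfg$red_thr) & region$mask
  labels <- label_components(cand, cfg$connectivity)
  ps <- puncta_from_labels(labels, red$data, g, ratio$values, red$pixel_size,
                           cfg, mask_role = region$role)
  if (nrow(ps$objects) > 0) ps$objects$class <- "mitolysosome"
  else ps$objects$class <- character(0)
  if (sum(region$mask) == 0)
    ps$warnings <- c(ps$warnings, "empty region mask: no detection possible")
  ps
}

#' Detect and classify autophagosomes vs autolysosomes (auto-QC)
#'
#' High-intensity red pixels (`>= red_high_thr`) inside the region are
#' labelled into objects; each object is classed `"autolysosome"` if its
#' mean red/green ratio is `>= ratio_thr_high`, else `"autophagosome"`.
#' Classification is object-level by default so one object cannot straddle
#' the threshold and be counted twice; `pixelwise = TRUE` retains the
#' pixel-level variant (objects are then split by the thresholded ratio
#' before labelling) for fidelity checks.
#'
#' @inheritParams detect_mitolysosomes
#' @param pixelwise classify pixels before labelling instead of objects after.
#' @return A `puncta_set` whose classes partition the detected objects.
#' @export
detect_and_classify_auto_puncta <- function(red, ratio, region,
                                            cfg = threshold_config(),
                                            green = NULL, pixelwise = FALSE) {
  stopifnot(inherits(ratio, "ratio_image"), inherits(red, "channel_image"),
            inherits(region, "region_mask"), inherits(cfg, "threshold_config"))
  if (!identical(dim(ratio$values), dim(red$data)) ||
      !identical(dim(ratio$values), dim(region$mask)))
    stop("red, ratio and region must be co-registered (same shape)")
  g <- if (is.null(green)) matrix(NA_real_, nrow(red$data), ncol(red$data)) else green$data
  cand <- (red$data >= cfg$red_high_thr) & region$mask
  if (!pixelwise) {
    labels <- label_components(cand, cfg$connectivity)
    ps <- puncta_from_labels(labels, red$data, g, ratio$values, red$pixel_size,
                             cfg, mask_role = region$role)
    ps$objects$class <- ifelse(ps$objects$mean_ratio >= cfg$ratio_thr_high,
                               "autolysosome", "autophagosome")
    if (nrow(ps$objects) == 0) ps$objects$class <- character(0)
  } else {
    high <- cand & (ratio$values >= cfg$ratio_thr_high)
    low <- cand & !high
    ps_al <- puncta_from_labels(label_components(high, cfg$connectivity),
                                red$data, g, ratio$values, red$pixel_size, cfg,
                                mask_role = region$role)
    ps_ap <- puncta_from_labels(label_components(low, cfg$connectivity),
                                red$data, g, ratio$values, red$pixel_size, cfg,
                                mask_role = region$role)
    if (nrow(ps_al$objects) > 0) ps_al$objects$class <- "autolysosome"
    else ps_al$objects$class <- character(0)
    if (nrow(ps_ap$objects) > 0) ps_ap$objects$class <- "autophagosome"
    else ps_ap$objects$class <- character(0)
    obj <- rbind(ps_al$objects, ps_ap$objects)
    if (nrow(obj) > 0) obj$id <- seq_len(nrow(obj))
    ps <- ps_al
    ps$objects <- obj
    ps$pixels <- c(ps_al$pixels, ps_ap$pixels)
  }
  if (sum(region$mask) == 0)
    ps$warnings <- c(ps$warnings, "empty region mask: no detection possible")
  ps
}

#' Assign puncta to cells by centroid membership
#'
#' Each punctum is assigned to the (single) cell ROI containing its
#' centroid; puncta outside every ROI are counted separately.
#'
#' @param puncta a `puncta_set`.
#' @param cell_rois list of pairwise-disjoint single-cell `region_mask`es.
#' @return A data frame with one row per cell (`cell_id`, `n_puncta`) and
#'   attribute `n_outside` for puncta falling in no ROI.
#' @export
count_per_cell <- function(puncta, cell_rois) {
  stopifnot(inherits(puncta, "puncta_set"))
  if (length(cell_rois) == 0) stop("need at least one cell ROI")
  dims <- dim(cell_rois[[1]]$mask)
  acc <- matrix(0L, dims[1], dims[2])
  for (rm in cell_rois) {
    stopifnot(inherits(rm, "region_mask"))
    acc <- acc + rm$mask
  }
  if (any(acc > 1L)) stop("cell ROIs overlap; they must be pairwise disjoint")
  counts <- integer(length(cell_rois))
  outside <- 0L
  for (k in seq_len(nrow(puncta$objects))) {
    i <- round(puncta$objects$centroid_row[k]) + 1L
    j <- round(puncta$objects$centroid_col[k]) + 1L
    hit <- FALSE
    for (c_id in seq_along(cell_rois)) {
      if (cell_rois[[c_id]]$mask[i, j]) {
        counts[c_id] <- counts[c_id] + 1L
        hit <- TRUE
        break
      }
    }
    if (!hit) outside <- outside + 1L
  }
  out <- data.frame(cell_id = seq_along(cell_rois), n_puncta = counts)
  attr(out, "n_outside") <- outside
  out
}

#' Run the standard mito-QC quantitation on one reporter image
#'
#' Convenience composition of the canonical in vivo recipe: fine-filter both
#' channels, build the ratio image, detect tissue (or use a supplied
#' region), then double-threshold mitolysosomes.
#'
#' @param img a `reporter_image`.
#' @param cfg a [threshold_config()].
#' @param region optional `region_mask` (tissue or cell-type stain);
#'   defaults to the full frame. Pass [threshold_mask()] of the green
#'   channel for explicit tissue detection, or [cell_type_mask()] to
#'   restrict to an immunolabelled population.
#' @param filter_radius fine-filter radius (0 skips filtering).
#' @return A `puncta_set` of mitolysosomes.
#' @export
quantify_mitophagy <- function(img, cfg = threshold_config(), region = NULL,
                               filter_radius = 1) {
  stopifnot(inherits(img, "reporter_image"))
  red <- img$red; green <- img$green
  if (filter_radius >= 1) {
    red <- fine_filter(red, filter_radius)
    green <- fine_filter(green, filter_radius)
  }
  ratio <- compute_ratio_image(red, green)
  if (is.null(region))
    region <- region_mask(matrix(TRUE, nrow(red$data), ncol(red$data)),
                          red$pixel_size, role = "tissue", source = "full frame")
  ps <- detect_mitolysosomes(ratio, red, region, cfg, green = green)
  ps$image_id <- img$image_id
  ps
}

#' Run the standard auto-QC quantitation on one reporter image
#'
#' Fine-filter, ratio image, then red-threshold candidates classified into
#' autophagosomes and autolysosomes by their mean ratio.
#'
#' @inheritParams quantify_mitophagy
#' @return A `puncta_set` with a class column partitioning the objects.
#' @export
quantify_autophagy <- function(img, cfg = threshold_config(), region = NULL,
                               filter_radius = 1) {
  stopifnot(inherits(img, "reporter_image"))
  red <- img$red; green <- img$green
  if (filter_radius >= 1) {
    red <- fine_filter(red, filter_radius)
    green <- fine_filter(green, filter_radius)
  }
  ratio <- compute_ratio_image(red, green)
  if (is.null(region))
    region <- region_mask(matrix(TRUE, nrow(red$data), ncol(red$data)),
                          red$pixel_size, role = "tissue", source = "full frame")
  ps <- detect_and_classify_auto_puncta(red, ratio, region, cfg, green = green)
  ps$image_id <- img$image_id
  ps
}
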