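# Cell-type-resolved measurement: immunolabel masks, cell-body counting,
# normalization per stained area / per cell body, object-based colocalization.

#' Threshold the immunolabel channel into a cell-type mask
#'
#' @param label the immunolabel `channel_image` (TH, Iba1, GFAP, calbindin,
#'   ATPB, ...).
#' @param thr intensity threshold.
#' @return A `region_mask` with role `"cell_type_stain"`.
#' @export
cell_type_mask <- function(label, thr) {
  if (is.null(label)) stop("immunolabel channel is missing")
  stopifnot(inherits(label, "channel_image"))
  threshold_mask(label, thr, role = "cell_type_stain")
}

#' Count cell bodies in a stain mask
#'
#' Connected components of the mask whose calibrated area falls inside a
#' soma-scale window are counted as cell bodies; smaller specks and larger
#' merged sheets are excluded.
#'
#' @param mask a `region_mask` with role `cell_type_stain` or `cell_body`.
#' @param min_soma_area_um2,max_soma_area_um2 accepted soma area window.
#' @param connectivity pixel connectivity (default 8).
#' @return Integer count of cell bodies.
#' @export
count_cell_bodies <- function(mask, min_soma_area_um2 = 30,
                              max_soma_area_um2 = 700, connectivity = 8) {
  stopifnot(inherits(mask, "region_mask"))
  if (!mask$role %in% c("cell_type_stain", "cell_body"))
    stop("mask role must be 'cell_type_stain' or 'cell_body'")
  if (min_soma_area_um2 > max_soma_area_um2)
    stop("min_soma_area_um2 must not exceed max_soma_area_um2")
  labels <- label_components(mask$mask, connectivity)
  n <- attr(labels, "n_components")
  if (n == 0) return(0L)
  areas_px <- tabulate(labels[labels > 0], nbins = n)
  areas_um2 <- areas_px * mask$pixel_size^2
  sum(areas_um2 >= min_soma_area_um2 & areas_um2 <= max_soma_area_um2)
}

#' Normalize a count per stained area
#'
#' @param count object count (>= 0).
#' @param mask the `region_mask` whose calibrated area is the denominator.
#' @return Density per um^2, or `NA` (flagged, no error) if the mask is empty.
#' @export
normalize_per_area <- function(count, mask) {
  stopifnot(inherits(mask, "region_mask"), count >= 0)
  if (mask$area_um2 <= 0) {
    warning("zero stained area: density flagged as missing")
    return(NA_real_)
  }
  count / mask$area_um2
}

#' Normalize a count per cell body
#'
#' @param count object count (>= 0).
#' @param n_cells number of cell bodies in the same field (>= 0).
#' @return Count per cell, or `NA` (flagged) when `n_cells` is 0.
#' @export
normalize_per_cell <- function(count, n_cells) {
  stopifnot(count >= 0, n_cells >= 0)
  if (n_cells == 0) {
    warning("no cell bodies in field: per-cell rate flagged as missing")
    return(NA_real_)
  }
  count / n_cells
}

#' Object-based colocalization of puncta with a mask
#'
#' An object is colocalized when its pixel overlap with the mask satisfies
#' the rule: at least `min_overlap_px` shared pixels (default 1) and at
#' least a fraction `min_overlap_frac` of its own area (default 0).
#' Percentages are computed separately per object class, as
#' `100 * colocalized / total`.
#'
#' @param puncta a `puncta_set` (with a `class` column).
#' @param mito_mask a co-registered `region_mask` (e.g. thresholded ATPB).
#' @param min_overlap_px minimum shared pixel count.
#' @param min_overlap_frac minimum shared fraction of the object's area.
#' @return A data frame with one row per class: `class`, `n_total`,
#'   `n_colocalized`, `percent` (`NA` when the class has no objects).
#'   An `overall` row pools all classes.
#' @export
colocalize_puncta_with_mask <- function(puncta, mito_mask,
                                        min_overlap_px = 1,
                                        min_overlap_frac = 0) {
  stopifnot(inherits(puncta, "puncta_set"), inherits(mito_mask, "region_mask"))
  obj <- puncta$objects
  classes <- if (nrow(obj) > 0) sort(unique(obj$class)) else character(0)
  coloc <- logical(nrow(obj))
  for (k in seq_len(nrow(obj))) {
    shared <- sum(mito_mask$mask[puncta$pixels[[k]]])
    coloc[k] <- shared >= min_overlap_px &&
      shared / obj$area_px[k] >= min_overlap_frac
  }
  per_class <- lapply(c(classes, "overall"), function(cl) {
    sel <- if (cl == "overall") rep(TRUE, nrow(obj)) else obj$class == cl
    n_tot <- sum(sel)
    n_col <- sum(coloc[sel])
    data.frame(class = cl, n_total = n_tot, n_colocalized = n_col,
               percent = if (n_tot > 0) 100 * n_col / n_tot else NA_real_)
  })
  out <- do.call(rbind, per_class)
  if (nrow(obj) == 0)
    attr(out, "warning") <- "empty puncta set: percentages flagged missing"
  out
}

#' Assemble a per-image quantitation record
#'
#' One row of the pipeline's tidy output: counts by class, stained area,
#' cell bodies, and the derived densities.
#'
#' @param img the source `reporter_image` (metadata provider).
#' @param puncta a `puncta_set` from this image.
#' @param stain_mask optional cell-type `region_mask` (for per-area density).
#' @param n_cell_bodies optional cell-body count (for per-cell rate).
#' @param coloc optional result of [colocalize_puncta_with_mask()].
#' @param cell_type free-text cell-type tag (e.g. "TH", "Iba1").
#' @return A one-row data frame (a QuantRecord).
#' @export
quant_record <- function(img, puncta, stain_mask = NULL, n_cell_bodies = NA,
                         coloc = NULL, cell_type = NA_character_) {
  obj <- puncta$objects
  n_mito <- sum(obj$class == "mitolysosome")
  n_ap <- sum(obj$class == "autophagosome")
  n_al <- sum(obj$class == "autolysosome")
  n_total <- nrow(obj)
  area <- if (is.null(stain_mask)) NA_real_ else stain_mask$area_um2
  dens <- if (is.null(stain_mask)) NA_real_ else {
    if (stain_mask$area_um2 > 0) n_total / stain_mask$area_um2 else NA_real_
  }
  per_cell <- if (is.na(n_cell_bodies) || n_cell_bodies == 0) NA_real_
              else n_total / n_cell_bodies
  coloc_pct <- if (is.null(coloc)) NA_real_
               else coloc$percent[coloc$class == "overall"]
  data.frame(image_id = img$image_id, subject_id = img$subject_id,
             genotype = img$genotype, treatment = img$treatment,
             cell_type = cell_type,
             n_mitolysosomes = n_mito, n_autophagosomes = n_ap,
             n_autolysosomes = n_al,
             stained_area_um2 = area, n_cell_bodies = n_cell_bodies,
             density_per_um2 = dens, count_per_cell_body = per_cell,
             colocalized_percent = coloc_pct,
             stringsAsFactors = FALSE)
}
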