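# Synthetic tandem-reporter scenes with per-object ground truth.
#
# The generator emulates what the detector must separate: a curvilinear
# mitochondrial network emitting in both red and green, punctate acidified
# compartments whose green signal is quenched, an optional immunolabel
# channel marking a cell subpopulation, then PSF blur and shot/read noise.
# Ground truth is frozen before any degradation is applied.
#
# Randomness is split over named substreams of the scene seed, each consumed
# in a documented order so tests can replay one stream independently:
#   "counts"  - per-cell object counts, one vectorized draw per class in the
#               order mitolysosome, autophagosome, autolysosome
#   "layout"  - cell placement, punctum placement, network strokes
#   "labels"  - label-positive cell flags: rbinom(n_cells, 1, label_fraction)
#   "overlap" - immunolabel overlap flags: rbinom(n_objects, 1, overlap_fraction)
#               in object-id order (autophagosomes first, then autolysosomes)
#   "noise"   - Poisson/Gaussian degradation

#' Specification of a synthetic reporter scene
#'
#' Defines the stated world of a simulated micrograph: geometry, biology
#' (object counts and quenching) and optics (PSF, noise). Defaults emulate a
#' 63x confocal field of primary MEFs: 0.2 um pixels, soma-scale cells,
#' a handful of mitolysosomes per cell, strong (90%) GFP quenching inside
#' acidified compartments.
#'
#' @param image_shape integer vector (rows, cols) in pixels.
#' @param pixel_size um per pixel.
#' @param n_cells number of cells placed in the field.
#' @param mito_density fraction of each cell's area covered by the
#'   mitochondrial network.
#' @param n_mitolysosomes_per_cell,n_autophagosomes_per_cell,n_autolysosomes_per_cell
#'   count distributions as `count_dist(mean, dispersion)` (or a bare number,
#'   taken as an exact deterministic count).
#' @param quench_factor fraction of GFP intensity retained inside acidified
#'   compartments, in [0, 1]; 0 = complete quench.
#' @param label_fraction fraction of cells positive for the immunolabel.
#' @param overlap_fraction fraction of auto-QC puncta designed to overlap the
#'   mitochondria immunolabel.
#' @param background_level camera background intensity (all channels).
#' @param red_gain,green_gain network/cytosol fluorophore brightness.
#' @param punctum_gain punctum brightness above background (red channel).
#' @param psf_sigma Gaussian PSF sigma in pixels; 0 disables blur.
#' @param noise_model list with `poisson_scale` (expected photons per
#'   intensity unit; 0 disables shot noise) and `gaussian_sd` (read noise in
#'   intensity units; 0 disables).
#' @param cell_radius_px,punctum_radius_px,network_width_px,min_gap_px
#'   morphology knobs: cell disk radius, punctum radius range, network stroke
#'   width range, minimum gap between punctum footprints.
#' @param seed integer scene seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(256L, 256L),
                       pixel_size = 0.2,
                       n_cells = 4L,
                       mito_density = 0.15,
                       n_mitolysosomes_per_cell = count_dist(4, Inf),
                       n_autophagosomes_per_cell = count_dist(0, Inf),
                       n_autolysosomes_per_cell = count_dist(0, Inf),
                       quench_factor = 0.1,
                       label_fraction = 1,
                       overlap_fraction = 0,
                       background_level = 10,
                       red_gain = 100,
                       green_gain = 100,
                       punctum_gain = 150,
                       psf_sigma = 1,
                       noise_model = list(poisson_scale = 1, gaussian_sd = 2),
                       cell_radius_px = 30L,
                       punctum_radius_px = c(2L, 3L),
                       network_width_px = c(2L, 4L),
                       min_gap_px = 4L,
                       seed = 1L) {
  as_dist <- function(x) if (is.numeric(x) && length(x) == 1L) count_dist(x, 0) else x
  spec <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
               n_cells = as.integer(n_cells), mito_density = mito_density,
               n_mitolysosomes_per_cell = as_dist(n_mitolysosomes_per_cell),
               n_autophagosomes_per_cell = as_dist(n_autophagosomes_per_cell),
               n_autolysosomes_per_cell = as_dist(n_autolysosomes_per_cell),
               quench_factor = quench_factor, label_fraction = label_fraction,
               overlap_fraction = overlap_fraction,
               background_level = background_level,
               red_gain = red_gain, green_gain = green_gain,
               punctum_gain = punctum_gain, psf_sigma = psf_sigma,
               noise_model = noise_model,
               cell_radius_px = as.integer(cell_radius_px),
               punctum_radius_px = as.integer(punctum_radius_px),
               network_width_px = as.integer(network_width_px),
               min_gap_px = as.integer(min_gap_px),
               seed = as.integer(seed))
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

#' Count distribution for per-cell object numbers
#'
#' @param mean expected count per cell.
#' @param dispersion negative-binomial size parameter; `Inf` gives Poisson,
#'   `0` a deterministic count equal to `mean` (which must then be integer).
#' @export
count_dist <- function(mean, dispersion = Inf) {
  stopifnot(is.numeric(mean), mean >= 0, is.numeric(dispersion), dispersion >= 0)
  if (dispersion == 0 && mean != round(mean))
    stop("a deterministic count distribution needs an integer mean")
  list(mean = mean, dispersion = dispersion)
}

validate_scene_spec <- function(spec) {
  num_fields <- c("pixel_size", "mito_density", "quench_factor", "label_fraction",
                  "overlap_fraction", "background_level", "red_gain", "green_gain",
                  "punctum_gain", "psf_sigma")
  for (f in num_fields)
    if (!is.numeric(spec[[f]]) || any(!is.finite(spec[[f]])))
      stop(sprintf("scene spec field '%s' must be finite numeric", f))
  if (spec$quench_factor < 0 || spec$quench_factor > 1)
    stop("quench_factor must be in [0, 1]")
  if (spec$label_fraction < 0 || spec$label_fraction > 1)
    stop("label_fraction must be in [0, 1]")
  if (spec$overlap_fraction < 0 || spec$overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]")
  if (spec$pixel_size <= 0) stop("pixel_size must be > 0")
  if (length(spec$image_shape) != 2L || any(spec$image_shape < 16L))
    stop("image_shape must be (rows, cols), each >= 16")
  if (spec$n_cells < 1L) stop("n_cells must be >= 1")
  if (any(!is.finite(unlist(spec$noise_model))) || any(unlist(spec$noise_model) < 0))
    stop("noise_model values must be finite and >= 0")
  invisible(spec)
}

#' Noise settings giving a target punctum signal-to-noise ratio
#'
#' Solves the Poisson scale so that the shot-noise SNR at a punctum,
#' `gain * s / sqrt((gain + background) * s)`, equals `snr`; read noise is
#' set to 10% of the background level.
#'
#' @param spec a `scene_spec`.
#' @param snr target signal-to-noise ratio at punctum peak.
#' @return The spec with its `noise_model` replaced.
#' @export
noise_for_snr <- function(spec, snr) {
  s <- snr^2 * (spec$punctum_gain + spec$background_level) / spec$punctum_gain^2
  spec$noise_model <- list(poisson_scale = s, gaussian_sd = 0.1 * spec$background_level)
  spec
}

# ---- low-level raster helpers -------------------------------------------

disk_pixels <- function(ci, cj, r, nr, nc) {
  # 1-based matrix indices of the disk; clipped to the image
  i <- max(1L, floor(ci - r)):min(nr, ceiling(ci + r))
  j <- max(1L, floor(cj - r)):min(nc, ceiling(cj + r))
  g <- expand.grid(i = i, j = j)
  keep <- (g$i - ci)^2 + (g$j - cj)^2 <= r^2
  g[keep, , drop = FALSE]
}

paint_disk <- function(img, ci, cj, r, value, add = TRUE) {
  px <- disk_pixels(ci, cj, r, nrow(img), ncol(img))
  idx <- cbind(px$i, px$j)
  img[idx] <- if (add) img[idx] + value else value
  img
}

gaussian_blur <- function(m, sigma) {
  # separable convolution, kernel truncated (exactly zero) beyond 3*sigma,
  # zero padding: applied to background-free signal rasters only
  if (sigma <= 0) return(m)
  R <- as.integer(ceiling(3 * sigma))
  k <- stats::dnorm(seq(-R, R), sd = sigma)
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L * R, nc)
  pad[(R + 1L):(R + nr), ] <- m
  out <- matrix(0, nr, nc)
  for (t in seq_along(k)) out <- out + k[t] * pad[t:(t + nr - 1L), , drop = FALSE]
  pad <- matrix(0, nr, nc + 2L * R)
  pad[, (R + 1L):(R + nc)] <- out
  out <- matrix(0, nr, nc)
  for (t in seq_along(k)) out <- out + k[t] * pad[, t:(t + nc - 1L), drop = FALSE]
  out
}

apply_noise <- function(m, noise_model) {
  s <- noise_model$poisson_scale
  g <- noise_model$gaussian_sd
  if (s > 0) m <- matrix(rpois(length(m), pmax(m, 0) * s) / s, nrow(m), ncol(m))
  if (g > 0) m <- m + matrix(rnorm(length(m), 0, g), nrow(m), ncol(m))
  pmax(m, 0)
}

draw_counts <- function(dist, n) {
  if (dist$dispersion == 0) rep(as.integer(dist$mean), n)
  else if (is.infinite(dist$dispersion)) rpois(n, dist$mean)
  else rnbinom(n, size = dist$dispersion, mu = dist$mean)
}

# ---- placement -----------------------------------------------------------

place_cells <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  r <- spec$cell_radius_px
  if (2 * r + 2 > min(nr, nc))
    stop("image too small for the requested cell radius")
  centers <- matrix(NA_real_, spec$n_cells, 2)
  for (c_id in seq_len(spec$n_cells)) {
    ok <- FALSE
    for (att in 1:2000) {
      ci <- runif(1, r + 1, nr - r)
      cj <- runif(1, r + 1, nc - r)
      if (c_id == 1 ||
          all((centers[seq_len(c_id - 1), 1] - ci)^2 +
              (centers[seq_len(c_id - 1), 2] - cj)^2 > (2 * r + 2)^2)) {
        centers[c_id, ] <- c(ci, cj); ok <- TRUE; break
      }
    }
    if (!ok) stop("image too small to place the requested number of cells")
  }
  centers
}

place_puncta <- function(spec, cell_centers, counts_by_class) {
  # rejection sampling: puncta of all classes share one exclusion list so
  # footprints never overlap (keeps ground-truth counts unambiguous)
  placed <- data.frame(cell_id = integer(), class = character(),
                       ci = numeric(), cj = numeric(), r = integer())
  rmin <- spec$punctum_radius_px[1]; rmax <- spec$punctum_radius_px[2]
  gap <- spec$min_gap_px
  cr <- spec$cell_radius_px
  for (cls in names(counts_by_class)) {
    counts <- counts_by_class[[cls]]
    for (c_id in seq_along(counts)) {
      for (k in seq_len(counts[c_id])) {
        r <- if (rmin == rmax) rmin else sample(rmin:rmax, 1)
        ok <- FALSE
        for (att in 1:2000) {
          rho <- (cr - r - 1) * sqrt(runif(1))
          th <- runif(1, 0, 2 * pi)
          ci <- cell_centers[c_id, 1] + rho * cos(th)
          cj <- cell_centers[c_id, 2] + rho * sin(th)
          if (nrow(placed) == 0 ||
              all((placed$ci - ci)^2 + (placed$cj - cj)^2 >
                  (placed$r + r + gap)^2)) {
            placed <- rbind(placed, data.frame(cell_id = c_id, class = cls,
                                               ci = ci, cj = cj, r = r))
            ok <- TRUE; break
          }
        }
        if (!ok) stop("image too small to place requested puncta without overlap")
      }
    }
  }
  placed
}

draw_network <- function(spec, cell_centers, puncta, nr, nc) {
  # random-walk curvilinear strokes per cell; strokes keep clear of punctum
  # footprints by a blur-aware margin so quenched puncta stay network-free
  net <- matrix(0, nr, nc)
  blur_margin <- ceiling(3 * spec$psf_sigma * sqrt(2)) + 1
  cr <- spec$cell_radius_px
  target_per_cell <- spec$mito_density * pi * cr^2
  for (c_id in seq_len(nrow(cell_centers))) {
    pc <- puncta[puncta$cell_id == c_id, , drop = FALSE]
    painted <- 0
    steps <- 0
    w <- if (spec$network_width_px[1] == spec$network_width_px[2])
      spec$network_width_px[1] else
      sample(spec$network_width_px[1]:spec$network_width_px[2], 1)
    pos <- cell_centers[c_id, ] + runif(2, -cr / 3, cr / 3)
    ang <- runif(1, 0, 2 * pi)
    while (painted < target_per_cell && steps < 5000) {
      steps <- steps + 1
      ang <- ang + rnorm(1, 0, 0.5)
      pos <- pos + c(cos(ang), sin(ang)) * 1.5
      d_center <- sqrt(sum((pos - cell_centers[c_id, ])^2))
      if (d_center > cr - w) { # bounce back toward the cell centre
        ang <- atan2(cell_centers[c_id, 2] - pos[2],
                     cell_centers[c_id, 1] - pos[1])
        pos <- cell_centers[c_id, ] +
          (pos - cell_centers[c_id, ]) * (cr - w) / d_center
      }
      clear <- nrow(pc) == 0 ||
        all((pc$ci - pos[1])^2 + (pc$cj - pos[2])^2 >
            (pc$r + w / 2 + blur_margin)^2)
      if (clear) {
        px <- disk_pixels(pos[1], pos[2], w / 2, nr, nc)
        idx <- cbind(px$i, px$j)
        painted <- painted + sum(net[idx] == 0)
        net[idx] <- 1
      }
    }
  }
  net
}

# ---- scene assembly ------------------------------------------------------

rasterize_puncta <- function(puncta, nr, nc) {
  # returns signal raster (unit amplitude) and per-object pixel stats
  sig <- matrix(0, nr, nc)
  stats <- vector("list", nrow(puncta))
  for (k in seq_len(nrow(puncta))) {
    px <- disk_pixels(puncta$ci[k], puncta$cj[k], puncta$r[k], nr, nc)
    sig[cbind(px$i, px$j)] <- 1
    stats[[k]] <- data.frame(area_px = nrow(px),
                             centroid_row = mean(px$i) - 1, # 0-based
                             centroid_col = mean(px$j) - 1)
  }
  list(signal = sig, stats = do.call(rbind, stats))
}

finish_channels <- function(spec, rasters) {
  # blur signal, add background, then noise; order: PSF -> Poisson -> Gaussian
  lapply(rasters, function(m) {
    m <- gaussian_blur(m, spec$psf_sigma)
    m <- m + spec$background_level
    apply_noise(m, spec$noise_model)
  })
}

build_cell_masks <- function(spec, cell_centers) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  labels <- matrix(0L, nr, nc)
  masks <- vector("list", nrow(cell_centers))
  for (c_id in seq_len(nrow(cell_centers))) {
    m <- matrix(FALSE, nr, nc)
    px <- disk_pixels(cell_centers[c_id, 1], cell_centers[c_id, 2],
                      spec$cell_radius_px, nr, nc)
    m[cbind(px$i, px$j)] <- TRUE
    labels[cbind(px$i, px$j)] <- c_id
    masks[[c_id]] <- region_mask(m, spec$pixel_size, role = "single_cell_roi",
                                 source = sprintf("cell_%02d", c_id))
  }
  list(masks = masks, labels = labels)
}

render_scene_core <- function(spec, classes, with_label, label_mode) {
  validate_scene_spec(spec)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]

  set.seed(substream_seed(spec$seed, "counts"))
  counts_by_class <- list()
  for (cls in c("mitolysosome", "autophagosome", "autolysosome"))
    if (cls %in% classes)
      counts_by_class[[cls]] <- draw_counts(spec[[switch(cls,
        mitolysosome = "n_mitolysosomes_per_cell",
        autophagosome = "n_autophagosomes_per_cell",
        autolysosome = "n_autolysosomes_per_cell")]], spec$n_cells)

  set.seed(substream_seed(spec$seed, "layout"))
  # a fresh layout is retried a few times before rejecting: rejection
  # sampling can jam below true capacity on an unlucky draw
  layout <- NULL
  for (attempt in 1:5) {
    layout <- tryCatch({
      cc <- place_cells(spec)
      list(cells = cc, puncta = place_puncta(spec, cc, counts_by_class))
    }, error = function(e) e)
    if (!inherits(layout, "error")) break
  }
  if (inherits(layout, "error")) stop(conditionMessage(layout))
  cell_centers <- layout$cells
  puncta <- layout$puncta
  net <- if (spec$mito_density > 0 && label_mode != "puncta_overlap")
    draw_network(spec, cell_centers, puncta, nr, nc) else matrix(0, nr, nc)
  cyto <- matrix(0, nr, nc)
  if (label_mode == "puncta_overlap") {
    # auto-QC: diffuse cytosolic reporter instead of a mitochondrial network
    for (c_id in seq_len(nrow(cell_centers)))
      cyto <- paint_disk(cyto, cell_centers[c_id, 1], cell_centers[c_id, 2],
                         spec$cell_radius_px, 1, add = FALSE)
  }

  # per-class quench applied to the green punctum signal
  green_scale <- c(mitolysosome = spec$quench_factor,
                   autophagosome = 1,
                   autolysosome = spec$quench_factor)

  red_sig <- net * spec$red_gain + cyto * 0.2 * spec$red_gain
  green_sig <- net * spec$green_gain + cyto * 0.2 * spec$green_gain
  obj_stats <- NULL
  if (nrow(puncta) > 0) {
    for (cls in unique(puncta$class)) {
      sel <- puncta[puncta$class == cls, , drop = FALSE]
      ras <- rasterize_puncta(sel, nr, nc)
      red_sig <- red_sig + ras$signal * spec$punctum_gain
      green_sig <- green_sig + ras$signal * spec$punctum_gain * green_scale[[cls]]
      obj_stats <- rbind(obj_stats, cbind(sel, ras$stats))
    }
    # restore object-id order: cell then class then placement order
    obj_stats <- obj_stats[order(match(obj_stats$class, classes),
                                 obj_stats$cell_id), , drop = FALSE]
  }

  # immunolabel channel + ground-truth membership (pre-degradation)
  label_sig <- NULL
  label_mask_truth <- matrix(FALSE, nr, nc)
  label_pos_cells <- logical(spec$n_cells)
  inside <- rep(NA, if (is.null(obj_stats)) 0 else nrow(obj_stats))
  if (with_label && label_mode == "cells") {
    set.seed(substream_seed(spec$seed, "labels"))
    flags <- rbinom(spec$n_cells, 1, spec$label_fraction) == 1
    label_pos_cells <- flags
    label_sig <- matrix(0, nr, nc)
    for (c_id in which(flags)) {
      label_sig <- paint_disk(label_sig, cell_centers[c_id, 1],
                              cell_centers[c_id, 2], spec$cell_radius_px,
                              1, add = FALSE)
      label_mask_truth <- paint_disk(label_mask_truth, cell_centers[c_id, 1],
                                     cell_centers[c_id, 2],
                                     spec$cell_radius_px, TRUE, add = FALSE)
    }
    label_sig <- label_sig * spec$red_gain
    if (!is.null(obj_stats))
      inside <- label_mask_truth[cbind(round(obj_stats$centroid_row) + 1,
                                       round(obj_stats$centroid_col) + 1)]
  } else if (with_label && label_mode == "puncta_overlap") {
    set.seed(substream_seed(spec$seed, "overlap"))
    n_obj <- if (is.null(obj_stats)) 0L else nrow(obj_stats)
    flags <- if (n_obj > 0) rbinom(n_obj, 1, spec$overlap_fraction) == 1 else logical(0)
    inside <- flags
    label_sig <- matrix(0, nr, nc)
    if (any(flags)) {
      for (k in which(flags)) {
        label_sig <- paint_disk(label_sig, obj_stats$ci[k], obj_stats$cj[k],
                                obj_stats$r[k] + 1, 1, add = FALSE)
        label_mask_truth <- paint_disk(label_mask_truth, obj_stats$ci[k],
                                       obj_stats$cj[k], obj_stats$r[k] + 1,
                                       TRUE, add = FALSE)
      }
    }
    label_sig <- label_sig * spec$red_gain
  }

  set.seed(substream_seed(spec$seed, "noise"))
  rasters <- list(red = red_sig, green = green_sig)
  if (!is.null(label_sig)) rasters$label <- label_sig
  chans <- finish_channels(spec, rasters)

  img <- reporter_image(
    red = channel_image(chans$red, spec$pixel_size, "red"),
    green = channel_image(chans$green, spec$pixel_size, "green"),
    label = if (!is.null(label_sig))
      channel_image(chans$label, spec$pixel_size, "label") else NULL,
    image_id = sprintf("scene_seed%d", spec$seed))

  cells <- build_cell_masks(spec, cell_centers)

  objects <- if (is.null(obj_stats)) {
    data.frame(object_id = integer(), cell_id = integer(), class = character(),
               centroid_row = numeric(), centroid_col = numeric(),
               area_px = integer(), inside_label_mask = logical())
  } else {
    data.frame(object_id = seq_len(nrow(obj_stats)),
               cell_id = obj_stats$cell_id, class = obj_stats$class,
               centroid_row = obj_stats$centroid_row,
               centroid_col = obj_stats$centroid_col,
               area_px = obj_stats$area_px,
               inside_label_mask = inside)
  }
  per_cell <- data.frame(
    cell_id = seq_len(spec$n_cells),
    n_mitolysosomes = vapply(seq_len(spec$n_cells), function(c_id)
      sum(objects$class == "mitolysosome" & objects$cell_id == c_id), integer(1)),
    label_positive = label_pos_cells)

  list(image = img, cell_masks = cells$masks, cell_labels = cells$labels,
       truth = list(objects = objects, cells = per_cell,
                    label_mask = label_mask_truth),
       spec = spec)
}

#' Render a synthetic MEF field (mito-QC reporter)
#'
#' Mitochondrial networks emitting in red and green plus mitolysosomes whose
#' green signal is scaled by `quench_factor`; PSF blur then noise applied
#' last; ground truth recorded before degradation.
#'
#' @param spec a `scene_spec`.
#' @return A list with `image` (a `reporter_image`), `cell_masks` (list of
#'   single-cell `region_mask`es), `cell_labels` (integer label matrix),
#'   `truth` (`$objects` per-object table, `$cells` per-cell summary) and
#'   the `spec`.
#' @export
render_mef_scene <- function(spec) {
  render_scene_core(spec, classes = "mitolysosome",
                    with_label = FALSE, label_mode = "none")
}

#' Render a synthetic tissue field with an immunolabel channel
#'
#' As [render_mef_scene()], plus a third channel painting a random subset
#' (`label_fraction`) of the cells as soma-scale immunolabelled blobs.
#' Ground truth marks which puncta fall inside label-positive regions.
#'
#' @inheritParams render_mef_scene
#' @return As [render_mef_scene()]; `truth$label_mask` holds the
#'   pre-degradation label mask, `truth$cells$label_positive` the flags.
#' @export
render_tissue_scene <- function(spec) {
  render_scene_core(spec, classes = "mitolysosome",
                    with_label = TRUE, label_mode = "cells")
}

#' Render a synthetic auto-QC field (autophagosomes and autolysosomes)
#'
#' Autophagosomes are red+green puncta, autolysosomes red-only (green scaled
#' by `quench_factor`), over a diffuse cytosolic reporter signal. A fraction
#' `overlap_fraction` of puncta (each class) is overlaid with a
#' mitochondria-immunolabel blob; the designed overlap flags are recorded in
#' the ground truth (`truth$objects$inside_label_mask`).
#'
#' @inheritParams render_mef_scene
#' @export
render_autoqc_scene <- function(spec) {
  render_scene_core(spec, classes = c("autophagosome", "autolysosome"),
                    with_label = TRUE, label_mode = "puncta_overlap")
}
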