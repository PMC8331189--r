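# Detection engine: filter, ratio, thresholds, labelling, classification.

test_that("fine_filter: constant image, hot pixel, and the sliding-window oracle", {
  const <- flat_channel(7)
  expect_equal(fine_filter(const)$data, const$data)

  hot <- flat_channel(5)
  hot$data[5, 5] <- 500
  expect_equal(fine_filter(hot, 1)$data, matrix(5, 9, 9))

  set.seed(42)
  for (radius in 1:2) {
    ch <- flat_channel(0)
    ch$data <- matrix(runif(81, 0, 100), 9, 9)
    expect_equal(fine_filter(ch, radius)$data,
                 median_filter_oracle(ch$data, radius))
  }
  expect_error(fine_filter(flat_channel(1), 0), "radius")
})

test_that("ratio image: identity, zero-division guard, elementwise oracle", {
  r <- flat_channel(20, role = "red"); g <- flat_channel(20, role = "green")
  expect_true(all(compute_ratio_image(r, g)$values == 1))

  r$data[1, 1] <- 99; g$data[1, 1] <- 0
  ri <- compute_ratio_image(r, g)
  expect_equal(ri$values[1, 1], 100)          # (99+1)/(0+1), at the cap
  expect_true(all(is.finite(ri$values)))

  set.seed(7)
  rm3 <- matrix(sample(0:500, 9), 3, 3); gm3 <- matrix(sample(0:500, 9), 3, 3)
  rr <- channel_image(rm3 + 0, 0.1, "red"); gg <- channel_image(gm3 + 0, 0.1, "green")
  oracle <- matrix(pmin((rm3 + 1) / (gm3 + 1), 100), 3, 3)
  expect_equal(compute_ratio_image(rr, gg)$values, oracle)

  expect_error(compute_ratio_image(rr, flat_channel(1, 5, 5, role = "green")),
               "shape")
})

test_that("threshold_mask: extremes and the comparison-count oracle", {
  set.seed(8)
  ch <- channel_image(matrix(runif(100, 0, 10), 10, 10), 0.5, "green")
  m0 <- threshold_mask(ch, 0)
  expect_true(all(m0$mask))
  expect_equal(m0$area_um2, 100 * 0.25)
  expect_equal(sum(threshold_mask(ch, 11)$mask), 0)
  thr <- median(ch$data)
  expect_equal(sum(threshold_mask(ch, thr)$mask), sum(ch$data >= thr))
})

test_that("connected components match brute-force flood fill (property)", {
  set.seed(123)
  for (rep in 1:60) {
    nr <- sample(3:32, 1); nc <- sample(3:32, 1)
    mask <- matrix(runif(nr * nc) < runif(1, 0.2, 0.7), nr, nc)
    for (conn in c(4L, 8L)) {
      got <- label_components(mask, conn)
      want <- flood_fill_labels(mask, conn)
      expect_identical(canonical_partition(got), canonical_partition(want))
      expect_equal(attr(got, "n_components"), max(want))
    }
  }
})

test_that("detect_mitolysosomes: trivial fields and empty-region behaviour", {
  px <- 0.2
  bg <- channel_image(matrix(1, 32, 32), px, "red")
  grn <- channel_image(matrix(1, 32, 32), px, "green")
  ratio <- compute_ratio_image(bg, grn)
  region <- region_mask(matrix(TRUE, 32, 32), px)
  cfg <- threshold_config()
  expect_equal(nrow(detect_mitolysosomes(ratio, bg, region, cfg)$objects), 0)

  # one disk passing both thresholds -> exactly one punctum
  red <- matrix(1, 32, 32)
  for (i in 14:18) for (j in 14:18)
    if ((i - 16)^2 + (j - 16)^2 <= 6) red[i, j] <- 200
  redc <- channel_image(red, px, "red")
  ratio2 <- compute_ratio_image(redc, grn)
  ps <- detect_mitolysosomes(ratio2, redc, region, cfg)
  expect_equal(nrow(ps$objects), 1)
  expect_equal(ps$objects$class, "mitolysosome")
  expect_equal(ps$objects$area_um2, ps$objects$area_px * px^2)

  empty <- region_mask(matrix(FALSE, 32, 32), px)
  ps0 <- detect_mitolysosomes(ratio2, redc, empty, cfg)
  expect_equal(nrow(ps0$objects), 0)
  expect_match(ps0$warnings, "empty region")
})

test_that("noise-free detection recovers ground truth and respects quench monotonicity", {
  for (s in 1:5) {
    sc <- render_mef_scene(small_spec(seed = s))
    ps <- quantify_mitophagy(sc$image)
    expect_equal(nrow(ps$objects), nrow(sc$truth$objects))
  }
  # lowering quench_factor (stronger quench) never decreases the count
  counts <- vapply(c(0.5, 0.3, 0.1, 0), function(q) {
    sc <- render_mef_scene(small_spec(seed = 3, quench_factor = q))
    nrow(quantify_mitophagy(sc$image)$objects)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("raising thresholds never increases the mitolysosome count", {
  sc <- render_mef_scene(small_spec(seed = 4))
  img <- sc$image
  n_at <- function(ratio_thr, red_thr) {
    cfg <- threshold_config(ratio_thr_high = ratio_thr, red_thr = red_thr)
    nrow(quantify_mitophagy(img, cfg)$objects)
  }
  base <- n_at(2, 50)
  expect_lte(n_at(3, 50), base)
  expect_lte(n_at(5, 50), n_at(3, 50))
  expect_lte(n_at(2, 100), base)
  expect_lte(n_at(2, 160), n_at(2, 100))
})

test_that("auto-QC classification: partition, extremes, ground-truth fidelity", {
  sp <- scene_spec(image_shape = c(224L, 224L), n_cells = 3L,
                   cell_radius_px = 32L, punctum_radius_px = c(2L, 3L),
                   n_autophagosomes_per_cell = count_dist(5, 0),
                   n_autolysosomes_per_cell = count_dist(5, 0),
                   n_mitolysosomes_per_cell = count_dist(0, 0),
                   noise_model = noise_off, seed = 30)
  sc <- render_autoqc_scene(sp)
  ps <- quantify_autophagy(sc$image)
  # partition invariant
  expect_equal(sum(ps$objects$class == "autophagosome") +
               sum(ps$objects$class == "autolysosome"),
               nrow(ps$objects))
  # fidelity: every detected object's class matches truth via centroid lookup
  expect_equal(nrow(ps$objects), nrow(sc$truth$objects))
  m <- match_to_truth(ps, sc$truth$objects)
  expect_equal(sort(m), seq_len(nrow(sc$truth$objects)))
  expect_equal(ps$objects$class, sc$truth$objects$class[m])

  # all objects green ~ red -> all autophagosomes
  spa <- scene_spec(image_shape = c(128L, 128L), n_cells = 2L,
                    cell_radius_px = 24L,
                    n_autophagosomes_per_cell = count_dist(4, 0),
                    n_autolysosomes_per_cell = count_dist(0, 0),
                    n_mitolysosomes_per_cell = count_dist(0, 0),
                    noise_model = noise_off, seed = 31)
  psa <- quantify_autophagy(render_autoqc_scene(spa)$image)
  expect_equal(unique(psa$objects$class), "autophagosome")

  # full-quench autolysosomes only -> all autolysosomes
  spl <- scene_spec(image_shape = c(128L, 128L), n_cells = 2L,
                    cell_radius_px = 24L, quench_factor = 0,
                    n_autophagosomes_per_cell = count_dist(0, 0),
                    n_autolysosomes_per_cell = count_dist(4, 0),
                    n_mitolysosomes_per_cell = count_dist(0, 0),
                    noise_model = noise_off, seed = 32)
  psl <- quantify_autophagy(render_autoqc_scene(spl)$image)
  expect_equal(unique(psl$objects$class), "autolysosome")
})

test_that("count_per_cell assigns puncta by centroid and reports strays", {
  sc <- render_mef_scene(small_spec(seed = 13))
  ps <- quantify_mitophagy(sc$image)
  per_cell <- count_per_cell(ps, sc$cell_masks)
  # oracle: explicit centroid-in-ROI loop over every cell mask
  oracle <- vapply(sc$cell_masks, function(rm)
    sum(points_in_mask_oracle(ps$objects$centroid_row,
                              ps$objects$centroid_col, rm$mask)),
    integer(1))
  expect_equal(per_cell$n_puncta, unname(oracle))
  expect_equal(sum(per_cell$n_puncta) + attr(per_cell, "n_outside"),
               nrow(ps$objects))

  # one ROI covering the image: per-cell count = total count
  full <- list(region_mask(matrix(TRUE, 128, 128), 0.2, "single_cell_roi"))
  expect_equal(count_per_cell(ps, full)$n_puncta, nrow(ps$objects))
  # empty puncta set: zero everywhere
  ps0 <- quantify_mitophagy(render_mef_scene(
    small_spec(seed = 14, n_mitolysosomes_per_cell = count_dist(0, 0)))$image)
  expect_true(all(count_per_cell(ps0, sc$cell_masks)$n_puncta == 0))
  # overlapping ROIs are rejected
  expect_error(count_per_cell(ps, list(full[[1]], full[[1]])), "overlap")
})
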