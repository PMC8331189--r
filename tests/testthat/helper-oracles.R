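# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: flood fill instead of union-find labelling,
# explicit loops instead of vectorized ops.

# Recursive flood fill (stack-based) connected-component labelling.
flood_fill_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  nb <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    nb <- rbind(nb, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    stack <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- cur
    while (nrow(stack) > 0) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        ii <- p[1] + nb[k, 1]; jj <- p[2] + nb[k, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack <- rbind(stack, c(ii, jj))
        }
      }
    }
  }
  lab
}

# Canonical form of a labelling: list of sorted pixel-index sets, ordered by
# their smallest member, so two labellings compare equal iff they induce the
# same partition.
canonical_partition <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0) return(list())
  groups <- split(idx, lab[idx])
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, min, numeric(1)))]
}

# Per-pixel sliding-window median with edge replication, brute force.
median_filter_oracle <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- pmin(pmax((i - radius):(i + radius), 1), nr)
    jj <- pmin(pmax((j - radius):(j + radius), 1), nc)
    out[i, j] <- median(m[ii, jj])
  }
  out
}

# Sort-drop-average trimmed mean.
trimmed_mean_oracle <- function(x, trim) {
  k <- floor(trim * length(x))
  s <- sort(x)
  mean(s[(k + 1):(length(s) - k)])
}

# Centroid-in-mask membership, explicit loop (0-based centroids).
points_in_mask_oracle <- function(rows0, cols0, mask) {
  out <- logical(length(rows0))
  for (k in seq_along(rows0))
    out[k] <- mask[round(rows0[k]) + 1, round(cols0[k]) + 1]
  out
}

# ---- shared fixtures ----------------------------------------------------

noise_off <- list(poisson_scale = 0, gaussian_sd = 0)

# Small, fast scene for unit tests (not the acceptance stated world).
small_spec <- function(seed = 1, ...) {
  args <- list(image_shape = c(128L, 128L), n_cells = 2L, cell_radius_px = 24L,
               n_mitolysosomes_per_cell = count_dist(3, Inf),
               noise_model = noise_off, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scene_spec, args)
}

flat_channel <- function(value, nr = 9, nc = 9, pixel_size = 0.2, role = "red") {
  channel_image(matrix(value, nr, nc), pixel_size, role)
}

# Match detected puncta to ground-truth objects by nearest centroid.
match_to_truth <- function(puncta, truth) {
  vapply(seq_len(nrow(puncta$objects)), function(k) {
    d2 <- (truth$centroid_row - puncta$objects$centroid_row[k])^2 +
          (truth$centroid_col - puncta$objects$centroid_col[k])^2
    which.min(d2)
  }, integer(1))
}
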