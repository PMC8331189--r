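# Formats and configuration.
#
# No TIFF package is available in the target environment, so the package
# carries a minimal baseline TIFF 6.0 codec: little-endian, uncompressed,
# grayscale, one IFD per channel (multi-page), 8/16-bit unsigned or 32-bit
# float samples, single strip per page. Channel roles and the pixel size
# are serialized in the ImageDescription tag as "key=value;..." text.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L,
               ImageDescription = 270L, StripOffsets = 273L,
               RowsPerStrip = 278L, StripByteCounts = 279L,
               SampleFormat = 339L)

#' Write a multi-channel grayscale TIFF
#'
#' One TIFF page (IFD) per channel, uncompressed, little-endian. The first
#' page's ImageDescription records the channel order and the pixel size so
#' the file round-trips through [read_reporter_image()].
#'
#' @param channels named list of numeric matrices (names = channel roles,
#'   e.g. `red`, `green`, `label`) sharing one shape.
#' @param path output file path.
#' @param pixel_size um per pixel, stored in the description.
#' @param bits 8 or 16 (unsigned integer, data rounded and clamped), 32
#'   (IEEE single float, the default) or 64 (IEEE double, lossless).
#' @return `path`, invisibly.
#' @export
write_channels_tiff <- function(channels, path, pixel_size, bits = 32) {
  stopifnot(length(channels) >= 1, !is.null(names(channels)),
            bits %in% c(8, 16, 32, 64))
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1) stop("channels must share one shape")
  nr <- dims[[1]][1]; nc <- dims[[1]][2]
  desc <- sprintf("mitoquant;pixel_size_um=%.10g;channels=%s",
                  pixel_size, paste(names(channels), collapse = ","))
  desc_raw <- c(charToRaw(desc), as.raw(0))
  sample_format <- if (bits >= 32) 3L else 1L
  bytes_pp <- bits / 8
  strip_len <- nr * nc * bytes_pp

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  wi(42, 2)
  wi(8, 4)                           # offset of the first IFD
  offset <- 8L                       # first IFD right after header
  n_pages <- length(channels)
  for (p in seq_len(n_pages)) {
    use_desc <- p == 1L
    n_entries <- 9L + as.integer(use_desc)
    ifd_size <- 2L + n_entries * 12L + 4L
    data_off <- offset + ifd_size    # [description][strip]
    desc_off <- data_off
    strip_off <- data_off + if (use_desc) length(desc_raw) else 0L
    next_ifd <- if (p < n_pages) strip_off + strip_len else 0L
    # IFD (written sequentially; file position is already at `offset`)
    wi(n_entries, 2)
    entry <- function(tag, type, count, value) {
      wi(tag, 2); wi(type, 2); wi(count, 4); wi(value, 4)
    }
    entry(TIFF_TAGS["ImageWidth"], 4L, 1L, nc)
    entry(TIFF_TAGS["ImageLength"], 4L, 1L, nr)
    entry(TIFF_TAGS["BitsPerSample"], 3L, 1L, bits)
    entry(TIFF_TAGS["Compression"], 3L, 1L, 1L)
    entry(TIFF_TAGS["Photometric"], 3L, 1L, 1L)  # BlackIsZero
    if (use_desc)
      entry(TIFF_TAGS["ImageDescription"], 2L, length(desc_raw), desc_off)
    entry(TIFF_TAGS["StripOffsets"], 4L, 1L, strip_off)
    entry(TIFF_TAGS["RowsPerStrip"], 4L, 1L, nr)
    entry(TIFF_TAGS["StripByteCounts"], 4L, 1L, strip_len)
    entry(TIFF_TAGS["SampleFormat"], 3L, 1L, sample_format)
    wi(next_ifd, 4)
    if (use_desc) writeBin(desc_raw, con)
    # pixel data, row-major (TIFF scanline order)
    m <- channels[[p]]
    v <- as.vector(t(m))
    if (bits >= 32) {
      writeBin(as.numeric(v), con, size = bytes_pp, endian = "little")
    } else {
      v <- pmin(pmax(round(v), 0), 2^bits - 1)
      writeBin(as.integer(v), con, size = bytes_pp, endian = "little")
    }
    offset <- strip_off + strip_len
  }
  invisible(path)
}

read_tiff_pages <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(as.integer(raw_all[off + 1:4])) *
                             c(1, 256, 65536, 16777216))
  if (rawToChar(raw_all[1:2]) != "II" || u16(2) != 42)
    stop("not a little-endian TIFF file: ", path)
  ifd_off <- u32(4)
  pages <- list()
  description <- NULL
  while (ifd_off != 0) {
    n <- u16(ifd_off)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- u16(base); type <- u16(base + 2); count <- u32(base + 4)
      inline_sizes <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)
      vsize <- inline_sizes[type] * count
      val_off <- if (vsize <= 4) base + 8 else u32(base + 8)
      value <- if (type == 2) {
        rawToChar(raw_all[val_off + seq_len(count - 1)])
      } else if (type == 3) {
        vapply(seq_len(count) - 1, function(k) u16(val_off + 2 * k), numeric(1))
      } else {
        vapply(seq_len(count) - 1, function(k) u32(val_off + 4 * k), numeric(1))
      }
      tags[[as.character(tag)]] <- value
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[tag])]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF page lacks required tag ", tag)
        default
      } else v
    }
    if ((cmp <- need("Compression", 1)) != 1)
      stop("unsupported TIFF compression scheme: ", cmp)
    nc <- need("ImageWidth"); nr <- need("ImageLength")
    bits <- need("BitsPerSample")
    fmt <- need("SampleFormat", 1)
    strip_off <- need("StripOffsets")
    if (length(strip_off) != 1) stop("multi-strip TIFF not supported")
    npx <- nr * nc
    if (fmt == 3) {
      v <- readBin(raw_all[strip_off + seq_len(npx * bits / 8)], "numeric",
                   n = npx, size = bits / 8, endian = "little")
    } else if (fmt == 1) {
      v <- readBin(raw_all[strip_off + seq_len(npx * bits / 8)], "integer",
                   n = npx, size = bits / 8, signed = FALSE, endian = "little")
    } else stop("unsupported TIFF sample format: ", fmt)
    pages[[length(pages) + 1]] <- matrix(v, nr, nc, byrow = TRUE)
    d <- tags[[as.character(TIFF_TAGS["ImageDescription"])]]
    if (!is.null(d) && is.null(description)) description <- d
    ifd_off <- u32(ifd_off + 2 + n * 12)
  }
  list(pages = pages, description = description)
}

parse_tiff_description <- function(desc) {
  out <- list(pixel_size = NA_real_, channels = NULL)
  if (is.null(desc)) return(out)
  for (part in strsplit(desc, ";")[[1]]) {
    kv <- strsplit(part, "=")[[1]]
    if (length(kv) != 2) next
    if (kv[1] == "pixel_size_um")
      out$pixel_size <- suppressWarnings(as.numeric(kv[2]))
    if (kv[1] == "channels") out$channels <- strsplit(kv[2], ",")[[1]]
  }
  out
}

#' Read a reporter image from a multi-page TIFF
#'
#' Maps TIFF pages to channel roles using, in order of precedence, the
#' `channel_order` in `config`, then the channel list embedded in the
#' file's ImageDescription. Pixel size comes from the description or from
#' `config$pixel_size_um`; if neither is present the read fails rather
#' than assuming a default calibration.
#'
#' @param path TIFF file path.
#' @param config optional list with `channel_order` (character vector of
#'   roles in page order, or named list role -> page index),
#'   `pixel_size_um` override, and metadata fields `image_id`,
#'   `subject_id`, `genotype`, `treatment`.
#' @return A `reporter_image`.
#' @export
read_reporter_image <- function(path, config = list()) {
  tf <- read_tiff_pages(path)
  meta <- parse_tiff_description(tf$description)
  roles <- config$channel_order
  if (is.null(roles)) roles <- meta$channels
  if (is.null(roles)) stop("channel order not declared in config or file: ", path)
  if (is.list(roles)) {
    idx <- unlist(roles)
    roles2 <- names(roles)
  } else {
    idx <- seq_along(roles)
    roles2 <- roles
  }
  if (max(idx) > length(tf$pages))
    stop(sprintf("config demands channel '%s' (page %d) but file has %d pages",
                 roles2[which.max(idx)], max(idx), length(tf$pages)))
  px <- config$pixel_size_um
  if (is.null(px)) px <- meta$pixel_size
  if (is.null(px) || is.na(px))
    stop("no pixel-size calibration in file metadata or config override: ", path)
  chan <- setNames(lapply(seq_along(idx), function(k)
    channel_image(tf$pages[[idx[k]]], px, roles2[k])), roles2)
  for (r in c("red", "green"))
    if (!r %in% roles2) stop("required channel role missing: ", r)
  reporter_image(red = chan$red, green = chan$green, label = chan$label,
                 image_id = if (is.null(config$image_id))
                   tools::file_path_sans_ext(basename(path)) else config$image_id,
                 subject_id = if (is.null(config$subject_id)) "subject"
                   else config$subject_id,
                 genotype = if (is.null(config$genotype)) "WT" else config$genotype,
                 treatment = if (is.null(config$treatment)) "none" else config$treatment)
}

#' Write a rendered scene to TIFF + ground-truth TSV
#'
#' Channels are written in the declared fixed order (red, green, then label
#' if present); the ground-truth object table accompanies the image as a
#' tab-separated file.
#'
#' @param scene a scene as returned by the `render_*_scene()` generators.
#' @param path output TIFF path; the truth table goes to
#'   `<path without extension>_truth.tsv`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_scene <- function(scene, path) {
  chans <- list(red = scene$image$red$data, green = scene$image$green$data)
  if (!is.null(scene$image$label)) chans$label <- scene$image$label$data
  write_channels_tiff(chans, path, scene$image$red$pixel_size, bits = 64)
  truth_path <- paste0(tools::file_path_sans_ext(path), "_truth.tsv")
  write.table(scene$truth$objects, truth_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(image = path, truth = truth_path))
}

#' Pipeline configuration
#'
#' Everything the orchestrated run needs, YAML-serializable. Threshold
#' sub-config is a [threshold_config()]; the remaining fields mirror the
#' knobs of the individual stages.
#'
#' @param channel_order channel roles in TIFF page order.
#' @param thresholds a [threshold_config()].
#' @param trim_fraction trimmed-mean fraction for the mitophagic threshold.
#' @param coloc_min_overlap_px,coloc_min_overlap_frac colocalization rule.
#' @param soma_area_um2 cell-body area window (min, max) in um^2.
#' @param filter_radius fine-filter radius.
#' @param seed top-level seed.
#' @param out_dir output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(channel_order = c("red", "green"),
                            thresholds = threshold_config(),
                            trim_fraction = 0.2,
                            coloc_min_overlap_px = 1,
                            coloc_min_overlap_frac = 0,
                            soma_area_um2 = c(30, 700),
                            filter_radius = 1,
                            seed = 1L,
                            out_dir = "results") {
  stopifnot(inherits(thresholds, "threshold_config"))
  structure(list(channel_order = channel_order, thresholds = thresholds,
                 trim_fraction = trim_fraction,
                 coloc_min_overlap_px = coloc_min_overlap_px,
                 coloc_min_overlap_frac = coloc_min_overlap_frac,
                 soma_area_um2 = soma_area_um2,
                 filter_radius = filter_radius,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` (for writing).
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  thr <- do.call(threshold_config, x$thresholds)
  x$thresholds <- NULL
  do.call(pipeline_config, c(x, list(thresholds = thr)))
}

#' Run manifest for reproducibility
#'
#' Records the config hash (md5 of its canonical YAML), package version,
#' input files with checksums, and a timestamp. Identical inputs and
#' config yield an identical `config_hash`/`input_md5` block.
#'
#' @param config a `pipeline_config`.
#' @param input_files character vector of input paths (may be empty).
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(config, input_files = character(0)) {
  tmp <- tempfile(fileext = ".yaml")
  write_pipeline_config(config, tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  sums <- if (length(input_files) > 0) tools::md5sum(input_files) else
    setNames(character(0), character(0))
  structure(list(config_hash = h,
                 package_version = as.character(utils::packageVersion("mitoquant")),
                 inputs = data.frame(file = names(sums), md5 = unname(sums),
                                     stringsAsFactors = FALSE),
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "run_manifest")
}
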