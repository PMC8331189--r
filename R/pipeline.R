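# Orchestration: simulate -> detect -> normalize -> stats, plus the CLI.

quant_outcome_for_mode <- function(mode) {
  switch(mode, mito = "n_mitolysosomes", auto = "n_autolysosomes",
         stop("unknown mode: ", mode))
}

#' Simulate a seeded set of reporter scenes with metadata
#'
#' Renders `n_scenes` scenes per subject from a base spec, assigning each
#' subject a genotype/treatment from the design table. Scene seeds are
#' derived deterministically from the top-level seed.
#'
#' @param base_spec a [scene_spec()] serving as the stated world; its seed
#'   field is overridden per scene.
#' @param design data frame with columns `subject_id`, `genotype`,
#'   `treatment` (one row per subject).
#' @param images_per_subject scenes rendered per subject.
#' @param seed top-level seed.
#' @param kind `"mef"`, `"tissue"` or `"autoqc"`.
#' @return List of scene lists (as from the `render_*_scene()` functions),
#'   each with its `reporter_image` metadata filled in.
#' @export
simulate_scenes <- function(base_spec, design, images_per_subject = 3,
                            seed = 1L, kind = c("mef", "tissue", "autoqc")) {
  kind <- match.arg(kind)
  render <- switch(kind, mef = render_mef_scene, tissue = render_tissue_scene,
                   autoqc = render_autoqc_scene)
  scenes <- list()
  k <- 0L
  for (s in seq_len(nrow(design))) {
    for (im in seq_len(images_per_subject)) {
      k <- k + 1L
      sp <- base_spec
      sp$seed <- substream_seed(seed, sprintf("scene_%d", k))
      sc <- render(sp)
      sc$image$subject_id <- design$subject_id[s]
      sc$image$genotype <- design$genotype[s]
      sc$image$treatment <- if ("treatment" %in% names(design))
        design$treatment[s] else "none"
      sc$image$image_id <- sprintf("%s_img%02d", design$subject_id[s], im)
      scenes[[k]] <- sc
    }
  }
  scenes
}

#' Run the full quantitation pipeline
#'
#' Detection -> per-image records -> per-subject summaries -> group
#' statistics, written as comma-separated tables plus a sidecar data
#' dictionary and a run manifest. Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @param images list of inputs: `reporter_image` objects, rendered scene
#'   lists (from `render_*_scene()` / [simulate_scenes()]), or TIFF paths.
#' @param mode `"mito"` (mitolysosome counts) or `"auto"`
#'   (autophagosome/autolysosome counts).
#' @param write if `TRUE` (default) write tables under `config$out_dir`.
#' @return Invisible list with `records`, `summaries`, `stats` (or NULL),
#'   `manifest` and `files`.
#' @export
run_pipeline <- function(config, images = list(), mode = c("mito", "auto"),
                         write = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "pipeline_config"))
  input_paths <- character(0)
  records <- NULL
  for (x in images) {
    img <- x
    if (is.character(x)) {
      input_paths <- c(input_paths, x)
      img <- tryCatch(read_reporter_image(x, list(channel_order = config$channel_order)),
                      error = function(e)
                        stop("stage read_reporter_image failed on '", x, "': ",
                             conditionMessage(e)))
    } else if (is.list(x) && !inherits(x, "reporter_image") && !is.null(x$image)) {
      img <- x$image
    }
    ps <- tryCatch(
      if (mode == "mito")
        quantify_mitophagy(img, config$thresholds,
                           filter_radius = config$filter_radius)
      else
        quantify_autophagy(img, config$thresholds,
                           filter_radius = config$filter_radius),
      error = function(e) stop("stage detect failed on image '", img$image_id,
                               "': ", conditionMessage(e)))
    records <- rbind(records, quant_record(img, ps))
  }
  if (is.null(records)) {
    warning("empty image list: writing empty outputs")
    records <- quant_record(reporter_image(
      channel_image(matrix(0, 2, 2), 1, "red"),
      channel_image(matrix(0, 2, 2), 1, "green")),
      structure(list(objects = data.frame(class = character()), pixels = list()),
                class = "puncta_set"))[0, ]
  }
  outcome <- quant_outcome_for_mode(mode)
  summaries <- if (nrow(records) > 0)
    summarize_by_subject(records, outcome = outcome) else NULL
  stats_res <- NULL
  if (!is.null(summaries) && length(unique(summaries$genotype)) >= 2 &&
      min(table(summaries$genotype)) >= 2) {
    two_way <- length(unique(summaries$treatment)) >= 2
    stats_res <- anova_tukey(summaries,
                             factors = if (two_way) c("genotype", "treatment")
                                       else "genotype")
  }
  manifest <- run_manifest(config, input_paths)
  files <- character(0)
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write.csv(records, p("records.csv"), row.names = FALSE)
    files <- p("records.csv")
    if (!is.null(summaries)) {
      write.csv(summaries, p("summaries.csv"), row.names = FALSE)
      files <- c(files, p("summaries.csv"))
    }
    if (!is.null(stats_res)) {
      write.csv(stats_res$anova, p("anova.csv"), row.names = FALSE)
      write.csv(stats_res$tukey, p("tukey.csv"), row.names = FALSE)
      files <- c(files, p("anova.csv"), p("tukey.csv"))
    }
    write.csv(quant_data_dictionary(), p("data_dictionary.csv"), row.names = FALSE)
    yaml::write_yaml(list(config_hash = manifest$config_hash,
                          package_version = manifest$package_version,
                          inputs = manifest$inputs$file,
                          input_md5 = manifest$inputs$md5,
                          timestamp = manifest$timestamp),
                     p("manifest.yaml"))
    files <- c(files, p("data_dictionary.csv"), p("manifest.yaml"))
  }
  invisible(list(records = records, summaries = summaries, stats = stats_res,
                 manifest = manifest, files = files))
}

quant_data_dictionary <- function() {
  data.frame(column = c("image_id", "subject_id", "genotype", "treatment",
                        "cell_type", "n_mitolysosomes", "n_autophagosomes",
                        "n_autolysosomes", "stained_area_um2", "n_cell_bodies",
                        "density_per_um2", "count_per_cell_body",
                        "colocalized_percent"),
             description = c(
               "field-of-view identifier",
               "biological subject (mouse or culture)",
               "Lrrk2 genotype: WT, G2019S or KO",
               "treatment arm: none, vehicle, inhibitor, DFP or EBSS",
               "immunolabelled population (TH, Iba1, GFAP, calbindin, ATPB)",
               "mitolysosome count in the analysed region",
               "autophagosome count (auto-QC mode)",
               "autolysosome count (auto-QC mode)",
               "calibrated area of the cell-type stain, um^2",
               "cell bodies counted in the stain mask",
               "objects per um^2 of stained area",
               "objects per cell body",
               "percent of objects colocalized with the organelle mask"),
             stringsAsFactors = FALSE)
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `quantify-mito`, `quantify-auto`, `coloc`,
#' `stats`, `run`. See `mitoquant_cli(c("<cmd>", "--help"))` or the
#' package README. Intended to be called from the `inst/cli/mitoquant`
#' Rscript wrapper.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
mitoquant_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mitoquant <command> [options]",
    "commands:",
    "  simulate      --out DIR [--config FILE] [--n-scenes N] [--seed S] [--kind mef|tissue|autoqc]",
    "  quantify-mito --images DIR --out DIR [--config FILE]",
    "  quantify-auto --images DIR --out DIR [--config FILE]",
    "  coloc         --images DIR --out DIR [--config FILE]",
    "  stats         --in RECORDS.csv --out DIR [--factors genotype[,treatment]]",
    "  run           --images DIR --out DIR [--config FILE] [--mode mito|auto]",
    sep = "\n")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
         else pipeline_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$out)) cfg$out_dir <- opts$out

  status <- 0L
  if (cmd == "simulate") {
    n <- as.integer(opts[["n-scenes"]] %||% 5)
    kind <- opts$kind %||% "mef"
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    design <- data.frame(subject_id = "sim", genotype = "WT", treatment = "none")
    scenes <- simulate_scenes(scene_spec(seed = cfg$seed), design,
                              images_per_subject = n, seed = cfg$seed,
                              kind = kind)
    for (i in seq_along(scenes))
      write_scene(scenes[[i]],
                  file.path(cfg$out_dir, sprintf("scene_%03d.tiff", i)))
    message("wrote ", n, " scenes to ", cfg$out_dir)
  } else if (cmd %in% c("quantify-mito", "quantify-auto", "run")) {
    mode <- if (cmd == "quantify-auto") "auto" else opts$mode %||% "mito"
    paths <- list.files(opts$images, pattern = "\\.tiff?$", full.names = TRUE)
    res <- run_pipeline(cfg, as.list(paths), mode = mode)
    message("wrote: ", paste(res$files, collapse = ", "))
  } else if (cmd == "coloc") {
    paths <- list.files(opts$images, pattern = "\\.tiff?$", full.names = TRUE)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- NULL
    for (p in paths) {
      img <- read_reporter_image(p, list(channel_order = cfg$channel_order))
      if (is.null(img$label)) stop("coloc requires a label channel: ", p)
      ps <- quantify_autophagy(img, cfg$thresholds,
                               filter_radius = cfg$filter_radius)
      cm <- cell_type_mask(fine_filter(img$label, cfg$filter_radius),
                           cfg$thresholds$red_thr)
      cc <- colocalize_puncta_with_mask(ps, cm, cfg$coloc_min_overlap_px,
                                        cfg$coloc_min_overlap_frac)
      cc$image_id <- img$image_id
      out <- rbind(out, cc)
    }
    write.csv(out, file.path(cfg$out_dir, "colocalization.csv"),
              row.names = FALSE)
    message("wrote ", file.path(cfg$out_dir, "colocalization.csv"))
  } else if (cmd == "stats") {
    records <- read.csv(opts[["in"]])
    factors <- strsplit(opts$factors %||% "genotype", ",")[[1]]
    summaries <- summarize_by_subject(records)
    res <- anova_tukey(summaries, factors = factors)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(res$anova, file.path(cfg$out_dir, "anova.csv"), row.names = FALSE)
    write.csv(res$tukey, file.path(cfg$out_dir, "tukey.csv"), row.names = FALSE)
    print(res)
  } else {
    message(usage)
    status <- 1L
  }
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        opts[[key]] <- args[i + 1]; i <- i + 2
      } else {
        opts[[key]] <- TRUE; i <- i + 1
      }
    } else i <- i + 1
  }
  opts
}
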