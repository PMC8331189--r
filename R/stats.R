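# Study-level statistics: trimmed-mean mitophagic threshold, percentage of
# mitophagic cells, per-subject summarization, ANOVA + Tukey HSD, TEM score
# aggregation, and the two-sample power calculation.

#' Symmetric truncated (trimmed) mean
#'
#' Sorts the values, drops `floor(trim_fraction * n)` from each end, and
#' averages the remainder.
#'
#' @param values non-empty numeric vector.
#' @param trim_fraction fraction trimmed from each tail, in [0, 0.5).
#' @return The trimmed mean.
#' @export
truncated_mean <- function(values, trim_fraction = 0.2) {
  if (length(values) == 0) stop("`values` must be non-empty")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must be in [0, 0.5)")
  k <- floor(trim_fraction * length(values))
  s <- sort(values)
  kept <- s[(k + 1):(length(s) - k)]
  if (length(kept) == 0) stop("trimming left no values")
  mean(kept)
}

#' Mitophagic-cell count threshold from a reference condition
#'
#' Computes the per-cell mitolysosome count above which a cell is called
#' mitophagic, from the distribution in the designated reference condition
#' (untreated WT cells). Outliers influence only this threshold, never the
#' classified data. Two rules are provided: a symmetric trimmed mean
#' (default) or the upper interquartile fence `Q3 + 1.5 * IQR`.
#'
#' @param reference_counts per-cell mitolysosome counts from untreated WT.
#' @param trim_fraction trim fraction for the `"trimmed_mean"` method.
#' @param method `"trimmed_mean"` or `"iqr_fence"`.
#' @return An object of class `mitophagic_threshold` with fields `value`,
#'   `method`, `trim_fraction`, `n_reference`.
#' @export
mitophagic_threshold <- function(reference_counts, trim_fraction = 0.2,
                                 method = c("trimmed_mean", "iqr_fence")) {
  method <- match.arg(method)
  if (length(reference_counts) == 0) stop("reference counts must be non-empty")
  if (any(reference_counts < 0)) stop("counts must be >= 0")
  value <- switch(method,
    trimmed_mean = truncated_mean(reference_counts, trim_fraction),
    iqr_fence = {
      q <- quantile(reference_counts, c(0.25, 0.75), names = FALSE, type = 7)
      q[2] + 1.5 * (q[2] - q[1])
    })
  structure(list(value = value, method = method,
                 trim_fraction = if (method == "trimmed_mean") trim_fraction else NA,
                 n_reference = length(reference_counts)),
            class = "mitophagic_threshold")
}

#' Percentage of mitophagic cells
#'
#' A cell is mitophagic iff its mitolysosome count is strictly above the
#' threshold ("above which"); ties go to non-mitophagic. All cells are
#' classified — the trimming that produced the threshold never removes
#' cells here.
#'
#' @param per_cell_counts per-cell mitolysosome counts (>= 0).
#' @param threshold a [mitophagic_threshold()] or a bare number.
#' @return Percentage in [0, 100].
#' @export
classify_mitophagic_cells <- function(per_cell_counts, threshold) {
  if (length(per_cell_counts) == 0) stop("no cells to classify")
  if (any(per_cell_counts < 0)) stop("counts must be >= 0")
  thr <- if (inherits(threshold, "mitophagic_threshold")) threshold$value else threshold
  100 * sum(per_cell_counts > thr) / length(per_cell_counts)
}

#' Collapse image-level records to one mean per subject
#'
#' The subject (mouse, culture) is the unit of analysis downstream; image
#' values within a subject are averaged unweighted.
#'
#' @param records data frame of per-image records with `subject_id` plus
#'   grouping metadata columns.
#' @param outcome name of the outcome column to average.
#' @param by extra grouping columns kept in the output (default genotype,
#'   treatment, cell_type when present).
#' @return Data frame with one row per subject (x grouping), columns
#'   `subject_id`, the groups, `mean_outcome`, `n_images`.
#' @export
summarize_by_subject <- function(records, outcome = "density_per_um2",
                                 by = intersect(c("genotype", "treatment", "cell_type"),
                                                names(records))) {
  if (!"subject_id" %in% names(records) || anyNA(records$subject_id))
    stop("every record needs a subject_id")
  if (!outcome %in% names(records)) stop("unknown outcome column: ", outcome)
  keys <- c("subject_id", by)
  # manual split keeps groups whose metadata (e.g. cell_type) is NA
  gk <- do.call(paste, c(lapply(records[keys], as.character), sep = "\r"))
  idx <- split(seq_len(nrow(records)), gk)
  agg <- do.call(rbind, lapply(idx, function(i) {
    row <- records[i[1], keys, drop = FALSE]
    row$mean_outcome <- mean(records[[outcome]][i])
    row$n_images <- length(i)
    row
  }))
  rownames(agg) <- NULL
  agg[order(agg$subject_id), , drop = FALSE]
}

stars_for_p <- function(p) {
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", "ns"))))
}

# Type-II sums of squares by nested-model RSS comparison (two-way design).
type2_anova_two_way <- function(data, outcome, fA, fB) {
  f <- function(fml) sum(stats::residuals(lm(fml, data = data))^2)
  rss_full <- f(stats::as.formula(paste(outcome, "~", fA, "*", fB)))
  rss_AB <- f(stats::as.formula(paste(outcome, "~", fA, "+", fB)))
  rss_A <- f(stats::as.formula(paste(outcome, "~", fA)))
  rss_B <- f(stats::as.formula(paste(outcome, "~", fB)))
  n <- nrow(data)
  a <- nlevels(factor(data[[fA]])); b <- nlevels(factor(data[[fB]]))
  df <- c(A = a - 1L, B = b - 1L, AB = (a - 1L) * (b - 1L))
  df_res <- n - a * b
  ss <- c(A = rss_B - rss_AB, B = rss_A - rss_AB, AB = rss_AB - rss_full)
  ms_res <- rss_full / df_res
  Fv <- (ss / df) / ms_res
  p <- pf(Fv, df, df_res, lower.tail = FALSE)
  data.frame(term = c(fA, fB, paste0(fA, ":", fB), "Residuals"),
             df = c(df, df_res), sum_sq = c(ss, rss_full),
             F_value = c(Fv, NA), p_value = c(p, NA),
             row.names = NULL)
}

#' One- or two-way ANOVA followed by Tukey HSD
#'
#' On subject-level means: one-way on a single factor, or two-way with
#' interaction (type-II sums of squares, appropriate for the unbalanced
#' group sizes that arise with unequal cohort sizes). The Tukey HSD
#' compares all cell means (factor-level combinations for two-way) with
#' Tukey-Kramer adjustment, and attaches the conventional significance
#' stars at 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param summaries data frame of subject summaries.
#' @param outcome outcome column name (default `"mean_outcome"`).
#' @param factors one or two factor column names.
#' @return A list of class `anova_tukey_result` with `anova` (term table)
#'   and `tukey` (pairwise table with `diff`, `lwr`, `upr`, `p_adj`,
#'   `stars`), plus `empty_cells` naming factor combinations with no data.
#' @export
anova_tukey <- function(summaries, outcome = "mean_outcome", factors) {
  stopifnot(length(factors) %in% 1:2, all(factors %in% names(summaries)),
            outcome %in% names(summaries))
  d <- summaries
  for (f in factors) d[[f]] <- factor(d[[f]])
  for (f in factors)
    if (nlevels(d[[f]]) < 2) stop("factor '", f, "' needs >= 2 levels")

  if (length(factors) == 2) {
    tab <- table(d[[factors[1]]], d[[factors[2]]])
    empty <- which(tab == 0, arr.ind = TRUE)
    empty_cells <- if (nrow(empty) > 0)
      paste(rownames(tab)[empty[, 1]], colnames(tab)[empty[, 2]], sep = ":")
      else character(0)
    if (length(empty_cells) > 0)
      warning("empty design cells: ", paste(empty_cells, collapse = ", "))
    an <- type2_anova_two_way(d, outcome, factors[1], factors[2])
    cell <- interaction(d[[factors[1]]], d[[factors[2]]], sep = ":", drop = TRUE)
  } else {
    fit1 <- aov(stats::as.formula(paste(outcome, "~", factors[1])), data = d)
    a <- anova(fit1)
    an <- data.frame(term = c(factors[1], "Residuals"),
                     df = a$Df, sum_sq = a$`Sum Sq`,
                     F_value = a$`F value`, p_value = a$`Pr(>F)`,
                     row.names = NULL)
    empty_cells <- character(0)
    cell <- d[[factors[1]]]
  }

  dc <- data.frame(y = d[[outcome]], cell = cell)
  fit_cells <- aov(y ~ cell, data = dc)
  tk <- TukeyHSD(fit_cells)$cell
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      stars = stars_for_p(tk[, "p adj"]),
                      row.names = NULL)
  structure(list(anova = an, tukey = tukey, empty_cells = empty_cells,
                 factors = factors, outcome = outcome),
            class = "anova_tukey_result")
}

#' @export
print.anova_tukey_result <- function(x, ...) {
  cat("ANOVA (", paste(x$factors, collapse = " x "), ") on ", x$outcome, "\n", sep = "")
  print(x$anova, digits = 4)
  cat("\nTukey HSD:\n")
  print(x$tukey, digits = 4)
  invisible(x)
}

#' Two-sample, two-sided sample-size calculation for comparing means
#'
#' Normal-approximation equality design:
#' `n = 2 * sd^2 * (z_{1-alpha/2} + z_{power})^2 / delta^2` per group, with
#' `delta = effect_fraction * mu`.
#'
#' @param mu reference mean.
#' @param sd reference standard deviation (> 0).
#' @param effect_fraction relative change to detect (> 0), e.g. 0.4 for 40%.
#' @param alpha two-sided type-I error (default 0.05).
#' @param power target power (default 0.8).
#' @return List with `n_unrounded` and `n_per_group` (nearest integer,
#'   floored at 1).
#' @export
sample_size_two_means <- function(mu, sd, effect_fraction, alpha = 0.05,
                                  power = 0.8) {
  stopifnot(sd > 0, effect_fraction > 0, alpha > 0, alpha < 1,
            power > 0, power < 1)
  delta <- effect_fraction * mu
  if (delta == 0) stop("effect size delta is zero")
  n <- 2 * sd^2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 / delta^2
  list(n_unrounded = n, n_per_group = max(1L, as.integer(round(n))))
}

#' Analytic power of the two-sample design at a given n
#'
#' Companion to [sample_size_two_means()]: normal-approximation power of
#' the two-sided two-sample comparison at `n` per group.
#'
#' @inheritParams sample_size_two_means
#' @param n per-group sample size.
#' @return Power in (0, 1).
#' @export
power_two_means <- function(n, mu, sd, effect_fraction, alpha = 0.05) {
  delta <- effect_fraction * mu
  se <- sd * sqrt(2 / n)
  z <- qnorm(1 - alpha / 2)
  pnorm(abs(delta) / se - z) + pnorm(-abs(delta) / se - z)
}

#' Aggregate TEM autolysosome scores into percentages and folds
#'
#' Per experiment and arm: percentage of autolysosomes containing
#' mitochondria = `100 * with_mito / total`; fold change is each arm's
#' percentage divided by its experiment's control percentage (control
#' normalized to 1).
#'
#' @param scores data frame with columns `experiment`, `arm`,
#'   `n_with_mito`, `n_total` (per image or pre-pooled; rows are summed
#'   within experiment x arm).
#' @param control_arm name of the control arm (default `"control"`).
#' @return Data frame with `experiment`, `arm`, `percent`, `fold`
#'   (`NA`-flagged when the control percentage is 0).
#' @export
tem_scores <- function(scores, control_arm = "control") {
  stopifnot(all(c("experiment", "arm", "n_with_mito", "n_total") %in% names(scores)))
  if (!control_arm %in% scores$arm)
    stop("every experiment needs a control arm ('", control_arm, "')")
  agg <- aggregate(cbind(n_with_mito, n_total) ~ experiment + arm,
                   data = scores, FUN = sum)
  agg$percent <- 100 * agg$n_with_mito / agg$n_total
  agg$fold <- NA_real_
  for (ex in unique(agg$experiment)) {
    sel <- agg$experiment == ex
    ctrl <- agg$percent[sel & agg$arm == control_arm]
    if (length(ctrl) != 1)
      stop("experiment '", ex, "' lacks a single control arm")
    if (ctrl == 0) {
      warning("control percentage is 0 in experiment '", ex,
              "': fold flagged missing")
      agg$fold[sel] <- NA_real_
    } else {
      agg$fold[sel] <- agg$percent[sel] / ctrl
    }
  }
  agg[order(agg$experiment, agg$arm != control_arm, agg$arm),
      c("experiment", "arm", "n_with_mito", "n_total", "percent", "fold")]
}
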