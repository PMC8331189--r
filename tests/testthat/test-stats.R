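# Study statistics: trimmed mean, mitophagic classification, subject
# summaries, ANOVA + Tukey, power, TEM aggregation.

test_that("truncated_mean: constants, no-trim, and the sort-based oracle", {
  expect_equal(truncated_mean(rep(3.7, 10), 0.2), 3.7)
  set.seed(1)
  x <- rnorm(31)
  expect_equal(truncated_mean(x, 0), mean(x))
  expect_equal(truncated_mean(c(0, 1, 2, 3, 100), 0.2), 2)  # drop 0 and 100
  for (i in 1:50) {
    x <- runif(sample(3:40, 1), -10, 10)
    tr <- runif(1, 0, 0.49)
    expect_equal(truncated_mean(x, tr), trimmed_mean_oracle(x, tr))
  }
  expect_error(truncated_mean(numeric(0)), "non-empty")
  expect_error(truncated_mean(1:5, 0.5), "trim_fraction")
})

test_that("mitophagic threshold and cell classification", {
  expect_equal(classify_mitophagic_cells(c(0, 0, 0), 0.5), 0)
  expect_equal(classify_mitophagic_cells(c(5, 6, 7), 1), 100)
  # strict inequality: ties go to non-mitophagic
  expect_equal(classify_mitophagic_cells(c(2, 2, 3), 2), 100 / 3)

  thr <- mitophagic_threshold(c(0, 1, 1, 2, 2, 3, 50), trim_fraction = 0.2)
  expect_equal(thr$value, truncated_mean(c(0, 1, 1, 2, 2, 3, 50), 0.2))
  fence <- mitophagic_threshold(c(0, 1, 1, 2, 2, 3, 50), method = "iqr_fence")
  q <- quantile(c(0, 1, 1, 2, 2, 3, 50), c(0.25, 0.75), names = FALSE)
  expect_equal(fence$value, q[2] + 1.5 * (q[2] - q[1]))

  # scale invariance: rescaling counts and threshold together is a no-op
  cts <- c(0, 2, 5, 9, 1)
  expect_equal(classify_mitophagic_cells(cts, 3),
               classify_mitophagic_cells(cts * 7, 3 * 7))

  # mixture-design oracle: 30% high-count cells recovered within 2 points
  set.seed(99)
  pcts <- vapply(1:50, function(i) {
    n <- 400
    hi <- rbinom(n, 1, 0.3) == 1
    counts <- ifelse(hi, rpois(n, 15), rpois(n, 1))
    classify_mitophagic_cells(counts, 5)
  }, numeric(1))
  expect_lt(abs(mean(pcts) - 30), 2)
})

test_that("summarize_by_subject equals an explicit group-by loop", {
  rec <- data.frame(subject_id = rep(c("m1", "m2", "m3"), each = 4),
                    genotype = rep(c("WT", "G2019S", "KO"), each = 4),
                    treatment = "none",
                    density_per_um2 = c(2, 4, 3, 3, 8, 9, 10, 9, 1, 1, 2, 0))
  s <- summarize_by_subject(rec)
  expect_equal(nrow(s), 3)
  for (m in unique(rec$subject_id)) {
    expect_equal(s$mean_outcome[s$subject_id == m],
                 mean(rec$density_per_um2[rec$subject_id == m]))
  }
  expect_true(all(s$n_images == 4))
  one <- summarize_by_subject(rec[1, , drop = FALSE])
  expect_equal(one$mean_outcome, rec$density_per_um2[1])
  rec_bad <- rec; rec_bad$subject_id[1] <- NA
  expect_error(summarize_by_subject(rec_bad), "subject_id")
})

test_that("one-way ANOVA + Tukey match an explicit sums-of-squares oracle", {
  # fixed fixture: 3 genotypes x 6 subjects
  set.seed(7)
  d <- data.frame(genotype = rep(c("WT", "G2019S", "KO"), each = 6),
                  mean_outcome = c(10.2, 11.1, 9.8, 10.5, 10.9, 10.0,
                                   7.4, 8.1, 7.9, 8.6, 7.2, 8.0,
                                   12.9, 13.4, 12.1, 13.0, 12.6, 13.8))
  res <- anova_tukey(d, factors = "genotype")

  # oracle: explicit group sums of squares and studentized-range p-values
  groups <- split(d$mean_outcome, d$genotype)
  n <- nrow(d); k <- length(groups)
  gm <- mean(d$mean_outcome)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- n - k
  Fo <- (ssb / df1) / (ssw / df2)
  po <- pf(Fo, df1, df2, lower.tail = FALSE)
  expect_equal(res$anova$df[1:2], c(df1, df2))
  expect_equal(res$anova$F_value[1], Fo, tolerance = 1e-8)
  expect_equal(res$anova$p_value[1], po, tolerance = 1e-8)

  mse <- ssw / df2
  for (r in seq_len(nrow(res$tukey))) {
    pair <- strsplit(res$tukey$comparison[r], "-")[[1]]
    g1 <- groups[[pair[1]]]; g2 <- groups[[pair[2]]]
    diff <- mean(g1) - mean(g2)
    se <- sqrt(mse / 2 * (1 / length(g1) + 1 / length(g2)))
    p_adj <- ptukey(abs(diff) / se, k, df2, lower.tail = FALSE)
    expect_equal(res$tukey$diff[r], diff, tolerance = 1e-8)
    expect_equal(res$tukey$p_adj[r], p_adj, tolerance = 1e-8)
  }
  # stars are a pure function of adjusted p
  expect_equal(res$tukey$stars,
               ifelse(res$tukey$p_adj < 1e-4, "****",
               ifelse(res$tukey$p_adj < 1e-3, "***",
               ifelse(res$tukey$p_adj < 0.01, "**",
               ifelse(res$tukey$p_adj < 0.05, "*", "ns")))))
})

test_that("identical groups give F ~ 0 and p_adj ~ 1; labels don't matter", {
  d <- data.frame(genotype = rep(c("WT", "KO"), each = 5),
                  mean_outcome = rep(c(4, 5, 6, 5, 4), 2))
  res <- anova_tukey(d, factors = "genotype")
  expect_lt(res$anova$F_value[1], 1e-20)
  expect_gt(min(res$tukey$p_adj), 1 - 1e-10)

  set.seed(11)
  d2 <- data.frame(genotype = rep(c("WT", "G2019S", "KO"), each = 5),
                   mean_outcome = rnorm(15))
  perm <- d2
  perm$genotype <- factor(perm$genotype,
                          levels = c("KO", "WT", "G2019S"))  # relabel order
  r1 <- anova_tukey(d2, factors = "genotype")
  r2 <- anova_tukey(perm, factors = "genotype")
  expect_equal(r1$anova$F_value[1], r2$anova$F_value[1])
  expect_equal(sort(r1$tukey$p_adj), sort(r2$tukey$p_adj))
})

test_that("two-way type-II ANOVA matches a direct least-squares oracle", {
  # unbalanced design mimicking cohort sizes n = 5 vs 10
  set.seed(21)
  d <- data.frame(
    genotype = c(rep("WT", 10), rep("G2019S", 10), rep("KO", 5),
                 rep("WT", 10), rep("G2019S", 10), rep("KO", 5)),
    treatment = rep(c("vehicle", "inhibitor"), each = 25),
    mean_outcome = rnorm(50, rep(c(10, 8, 12, 14, 13, 15), c(10, 10, 5, 10, 10, 5))))
  res <- anova_tukey(d, factors = c("genotype", "treatment"))

  rss <- function(X, y) {
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }
  y <- d$mean_outcome
  A <- factor(d$genotype); B <- factor(d$treatment)
  XA <- model.matrix(~A); XB <- model.matrix(~B)
  XAB <- model.matrix(~A + B); Xfull <- model.matrix(~A * B)
  ss_A <- rss(XB, y) - rss(XAB, y)
  ss_B <- rss(XA, y) - rss(XAB, y)
  ss_I <- rss(XAB, y) - rss(Xfull, y)
  df_res <- nrow(d) - ncol(Xfull)
  ms_res <- rss(Xfull, y) / df_res
  expect_equal(res$anova$F_value[1], (ss_A / 2) / ms_res, tolerance = 1e-8)
  expect_equal(res$anova$F_value[2], (ss_B / 1) / ms_res, tolerance = 1e-8)
  expect_equal(res$anova$F_value[3], (ss_I / 2) / ms_res, tolerance = 1e-8)
  expect_equal(res$anova$df, c(2, 1, 2, df_res))
  # Tukey over all 6 cell means
  expect_equal(nrow(res$tukey), choose(6, 2))
  expect_true(all(res$tukey$p_adj >= 0 & res$tukey$p_adj <= 1))
})

test_that("sample size: worked example, huge effect, closed-form oracle, monotonicity", {
  # pilot data: mean 60.6, SD 19.8, detect a 40% change at alpha .05, power .8
  res <- sample_size_two_means(60.6, 19.8, 0.4)
  expect_equal(res$n_per_group, 10L)
  expect_gt(res$n_unrounded, 10); expect_lt(res$n_unrounded, 11)

  expect_equal(sample_size_two_means(60.6, 19.8, 10)$n_per_group, 1L)

  # power 0.5 makes the power quantile vanish
  r5 <- sample_size_two_means(50, 10, 0.2, alpha = 0.05, power = 0.5)
  delta <- 0.2 * 50
  expect_equal(r5$n_unrounded, 2 * 100 * qnorm(0.975)^2 / delta^2,
               tolerance = 1e-12)

  n0 <- sample_size_two_means(60, 20, 0.3)$n_unrounded
  expect_lt(sample_size_two_means(60, 20, 0.5)$n_unrounded, n0)  # bigger delta
  expect_gt(sample_size_two_means(60, 30, 0.3)$n_unrounded, n0)  # bigger sd
  expect_gt(sample_size_two_means(60, 20, 0.3, power = 0.9)$n_unrounded, n0)
})

test_that("tem_scores: folds against designed enrichment", {
  s <- data.frame(experiment = c("e1", "e1", "e2", "e2"),
                  arm = c("control", "treated", "control", "treated"),
                  n_with_mito = c(10, 20, 8, 16), n_total = c(100, 100, 80, 80))
  res <- tem_scores(s)
  expect_equal(res$fold[res$arm == "control"], c(1, 1))
  expect_equal(res$fold[res$arm == "treated"], c(2, 2))

  # equal arms -> fold 1
  eq <- data.frame(experiment = "e", arm = c("control", "treated"),
                   n_with_mito = c(5, 5), n_total = c(50, 50))
  expect_equal(tem_scores(eq)$fold, c(1, 1))

  # zero control percentage flags the fold
  z <- data.frame(experiment = "e", arm = c("control", "treated"),
                  n_with_mito = c(0, 5), n_total = c(50, 50))
  expect_warning(rz <- tem_scores(z), "flagged")
  expect_true(all(is.na(rz$fold)))

  # three simulated experiments with designed 1.3x enrichment
  set.seed(5)
  folds <- numeric(0)
  for (rep in 1:20) {
    sim <- do.call(rbind, lapply(1:3, function(e) {
      data.frame(experiment = paste0("e", e), arm = c("control", "treated"),
                 n_with_mito = c(rbinom(1, 350, 0.30), rbinom(1, 500, 0.39)),
                 n_total = c(350, 500))
    }))
    r <- tem_scores(sim)
    folds <- c(folds, r$fold[r$arm == "treated"])
  }
  expect_lt(abs(mean(folds) - 1.3), 0.05)
})
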