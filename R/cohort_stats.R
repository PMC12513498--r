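#' Welch's two-sample t-test
#'
#' Unpaired two-tailed t-test with Welch's unequal-variance (Satterthwaite)
#' degrees of freedom, from raw values or published group summaries.
#'
#' @param a,b numeric vectors (each `n >= 2`). Alternatively supply
#'   `summary_a`/`summary_b`.
#' @param summary_a,summary_b optional lists `list(mean=, sd=, n=)`; when
#'   both are given `a`/`b` are ignored and the statistic is computed from
#'   the summaries.
#' @return A `comparison_result`: list with group `means`, `sds`, `ns`,
#'   `statistic`, `df`, `p_value`, `method = "welch_t"`.
#' @export
#' @examples
#' welch_t(rnorm(10), rnorm(10, 1))
welch_t <- function(a = NULL, b = NULL, summary_a = NULL, summary_b = NULL) {
  if (!is.null(summary_a) && !is.null(summary_b)) {
    m <- c(summary_a$mean, summary_b$mean)
    s <- c(summary_a$sd, summary_b$sd)
    n <- c(summary_a$n, summary_b$n)
    if (any(n < 2)) stop("each group needs n >= 2")
    se2 <- s^2 / n
    stat <- (m[1] - m[2]) / sqrt(sum(se2))
    df <- sum(se2)^2 / sum(se2^2 / (n - 1))
    p <- 2 * pt(-abs(stat), df)
  } else {
    if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
    tt <- t.test(a, b, var.equal = FALSE)
    m <- c(mean(a), mean(b)); s <- c(sd(a), sd(b)); n <- c(length(a), length(b))
    stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  structure(list(means = m, sds = s, ns = n, statistic = stat, df = df,
                 p_value = p, method = "welch_t"),
            class = "comparison_result")
}

#' Pearson correlation
#'
#' @param x,y numeric vectors, `n >= 3`, nonzero variance.
#' @return A `comparison_result` with `estimate` (r), `statistic`, `df`,
#'   `p_value`, `method = "pearson"`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need paired vectors, n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  ct <- cor.test(x, y, method = "pearson")
  structure(list(estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 ns = length(x), method = "pearson"),
            class = "comparison_result")
}

#' Compare one variable across groups
#'
#' The test menu used for cohort panels: Welch t (two groups), one-way ANOVA
#' with Tukey's multiple-comparison post hoc, or Kruskal-Wallis with
#' pairwise Wilcoxon (Holm-adjusted) post hoc for non-normal data.
#'
#' @param values numeric vector.
#' @param groups factor of the same length.
#' @param method `"welch_t"`, `"anova_tukey"` or `"kruskal"`.
#' @return A `comparison_result`; for the post-hoc methods it carries a
#'   `pairwise` table of adjusted p-values.
#' @export
compare_groups <- function(values, groups,
                           method = c("anova_tukey", "welch_t", "kruskal")) {
  method <- match.arg(method)
  groups <- droplevels(as.factor(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  ms <- tapply(values, groups, mean)
  ss <- tapply(values, groups, sd)
  ns <- tapply(values, groups, length)
  if (method == "welch_t") {
    if (nlevels(groups) != 2) stop("welch_t needs exactly two groups")
    lv <- levels(groups)
    return(welch_t(values[groups == lv[1]], values[groups == lv[2]]))
  }
  if (method == "anova_tukey") {
    fit <- aov(values ~ groups)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$groups
    res <- list(means = ms, sds = ss, ns = ns,
                statistic = an[["F value"]][1], df = an[["Df"]],
                p_value = an[["Pr(>F)"]][1],
                pairwise = data.frame(contrast = rownames(tk),
                                      diff = tk[, "diff"],
                                      p_adj = tk[, "p adj"],
                                      row.names = NULL),
                method = "anova_tukey")
  } else {
    kw <- kruskal.test(values, groups)
    pw <- pairwise.wilcox.test(values, groups, p.adjust.method = "holm",
                               exact = FALSE)
    res <- list(means = ms, sds = ss, ns = ns,
                statistic = unname(kw$statistic), df = unname(kw$parameter),
                p_value = kw$p.value, pairwise = pw$p.value,
                method = "kruskal")
  }
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

# Rank-based AUC with ties counted 1/2 (equals the trapezoidal area under
# the empirical ROC and the Mann-Whitney statistic).
auc_rank <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC analysis with Youden-optimal cutoff
#'
#' Builds the empirical ROC of a score against a binary label with the
#' orientation "higher score = positive". Candidate cutoffs are the
#' midpoints between adjacent distinct scores plus `-Inf` and `+Inf`; at a
#' cutoff `c`, sensitivity is `P(score >= c | positive)` and specificity is
#' `P(score < c | negative)`. The AUC is the trapezoidal area (identical to
#' the Mann-Whitney pair statistic with ties counted 1/2). The reported
#' cutoff maximizes the Youden index `J = sensitivity + specificity - 1`,
#' ties broken toward the smallest cutoff. The AUC confidence interval is a
#' seeded stratified percentile bootstrap.
#'
#' @param scores numeric scores (e.g. AA-FAI in HU).
#' @param labels binary labels (logical, or coercible 0/1); `TRUE`/1 is the
#'   positive class.
#' @param ci compute the bootstrap confidence interval.
#' @param boot number of bootstrap replicates.
#' @param conf confidence level.
#' @param seed seed for the bootstrap.
#' @return A `roc_result`: list with `auc`, `auc_ci`, `cutoff`,
#'   `sensitivity`, `specificity` (at the cutoff), `n_pos`, `n_neg`,
#'   `curve` (data frame of cutoff/sensitivity/specificity) and
#'   `positive_orientation`.
#' @export
#' @examples
#' roc_analysis(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE), ci = FALSE)
roc_analysis <- function(scores, labels, ci = TRUE, boot = 2000,
                         conf = 0.95, seed = 1L) {
  positive <- as.logical(labels)
  if (anyNA(scores) || anyNA(positive)) {
    keep <- !is.na(scores) & !is.na(positive)
    scores <- scores[keep]; positive <- positive[keep]
  }
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")

  s_sorted <- sort(unique(scores))
  cand <- c(-Inf, if (length(s_sorted) > 1)
    (head(s_sorted, -1) + s_sorted[-1]) / 2, Inf)
  pos_scores <- scores[positive]; neg_scores <- scores[!positive]
  sens <- vapply(cand, function(c) mean(pos_scores >= c), 0)
  spec <- vapply(cand, function(c) mean(neg_scores < c), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))[1] # candidates ascend, so first max = smallest cutoff
  auc <- auc_rank(scores, positive)

  auc_ci <- c(NA_real_, NA_real_)
  if (ci) {
    bs <- with_seed(seed, {
      vapply(seq_len(boot), function(b) {
        p <- sample(pos_scores, n_pos, replace = TRUE)
        n <- sample(neg_scores, n_neg, replace = TRUE)
        auc_rank(c(p, n), c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
      }, 0)
    })
    alpha <- (1 - conf) / 2
    auc_ci <- unname(quantile(bs, c(alpha, 1 - alpha)))
  }
  structure(list(auc = auc, auc_ci = auc_ci, cutoff = cand[best],
                 sensitivity = sens[best], specificity = spec[best],
                 n_pos = n_pos, n_neg = n_neg,
                 curve = data.frame(cutoff = cand, sensitivity = sens,
                                    specificity = spec),
                 positive_orientation = "higher score = positive"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%.3f-%.3f), cutoff %.3g: sens %.2f, spec %.2f (%d pos / %d neg)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$cutoff, x$sensitivity,
              x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Simulate the study ROC over replicate cohorts
#'
#' Repeatedly draws a cohort from the per-group Gaussian model (by default
#' the printed study summaries, see [study_groups()]), computes the
#' empirical ROC of AA-FAI for the requested contrast, and summarizes AUC,
#' Youden-optimal cutoff, and sensitivity/specificity at a supplied fixed
#' threshold across replicates.
#'
#' @param contrast `"HCTD_vs_non"` (MFS and LDS together positive) or
#'   `"MFS_vs_non"` (LDS excluded).
#' @param replicates number of replicate cohorts.
#' @param seed master seed; each replicate uses a derived child seed.
#' @param at_cutoff fixed threshold (HU) at which per-replicate sensitivity
#'   (`P(FAI >= cutoff | positive)`) and specificity
#'   (`P(FAI < cutoff | negative)`) are recorded.
#' @param groups group summary table as in [cohort_spec()].
#' @return List with `replicates` (data frame: `auc`, `cutoff`,
#'   `sens_at`, `spec_at` per replicate) and `summary` (means and SDs).
#' @export
reproduce_study_roc <- function(contrast = c("HCTD_vs_non", "MFS_vs_non"),
                                replicates = 500, seed = 1L,
                                at_cutoff = -55.3, groups = study_groups()) {
  contrast <- match.arg(contrast)
  g <- if (contrast == "MFS_vs_non") groups[groups$label != "LDS", ] else groups
  pos_labels <- setdiff(g$label, "non_HCTD")
  rows <- lapply(seq_len(replicates), function(i) {
    cohort <- simulate_fai_cohort(cohort_spec(groups = g,
                                              seed = child_seed(seed, i)))
    pos <- cohort$group %in% pos_labels
    roc <- roc_analysis(cohort$aa_fai, pos, ci = FALSE)
    data.frame(auc = roc$auc, cutoff = roc$cutoff,
               sens_at = mean(cohort$aa_fai[pos] >= at_cutoff),
               spec_at = mean(cohort$aa_fai[!pos] < at_cutoff))
  })
  reps <- do.call(rbind, rows)
  list(replicates = reps,
       summary = list(
         contrast = contrast, n_replicates = replicates,
         mean_auc = mean(reps$auc), sd_auc = sd(reps$auc),
         mean_cutoff = mean(reps$cutoff), sd_cutoff = sd(reps$cutoff),
         mean_sens = mean(reps$sens_at), mean_spec = mean(reps$spec_at),
         at_cutoff = at_cutoff))
}
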