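# Normality-gated group comparisons with Bonferroni correction.

#' Normality gate for a sample
#'
#' Shapiro-Wilk decides (p >= alpha means "normal"); the Lilliefors
#' (Kolmogorov-Smirnov with estimated parameters) result is reported
#' alongside. When the two disagree, Shapiro-Wilk governs. Degenerate
#' (constant) samples are returned as non-normal with a note.
#'
#' @param sample Numeric vector, n >= 3.
#' @param alpha Significance level for the gate.
#' @return List: `decision` (`"normal"`/`"non_normal"`), `shapiro_p`,
#'   `ks_p`, `note`.
#' @export
normality_gate <- function(sample, alpha = 0.05) {
  if (length(sample) < 3L) stop("normality assessment needs n >= 3")
  if (stats::sd(sample) == 0)
    return(list(decision = "non_normal", shapiro_p = NA_real_,
                ks_p = NA_real_, note = "constant sample (degenerate)"))
  sw <- stats::shapiro.test(sample)
  ks <- tryCatch(nortest::lillie.test(sample)$p.value,
                 error = function(e) NA_real_)
  list(decision = if (sw$p.value >= alpha) "normal" else "non_normal",
       shapiro_p = sw$p.value, ks_p = ks,
       note = "Shapiro-Wilk governs; KS (Lilliefors) reported alongside")
}

comparison_result <- function(test_name, statistic, p_value, adjusted_p,
                              group_stats, n, normality_p, decision_path,
                              pairwise = NULL) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, adjusted_p = adjusted_p,
                 group_stats = group_stats, n = n,
                 normality_p = normality_p, decision_path = decision_path,
                 pairwise = pairwise),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  cat(" ", x$decision_path, "\n")
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Bonferroni-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Two-group comparison with normality gating
#'
#' Both samples normal by [normality_gate()]: Student's two-tailed t-test
#' (paired variant when `paired`). Any sample non-normal: Mann-Whitney
#' (Wilcoxon rank-sum), or Wilcoxon signed-rank when paired. Paired data
#' with all-zero differences are reported as "no difference" with p = 1
#' rather than erroring.
#'
#' @param a,b Numeric samples (paired: equal length).
#' @param paired Logical.
#' @param alpha Gate significance level.
#' @return A `comparison_result` recording the test run, the decision
#'   path, group means/medians, per-group n and normality p-values.
#' @export
compare_two <- function(a, b, paired = FALSE, alpha = 0.05) {
  if (!length(a) || !length(b)) stop("empty sample")
  if (paired && length(a) != length(b))
    stop("paired samples must have equal length")
  ga <- normality_gate(a, alpha); gb <- normality_gate(b, alpha)
  normal <- ga$decision == "normal" && gb$decision == "normal"
  gs <- data.frame(group = c("a", "b"), mean = c(mean(a), mean(b)),
                   median = c(stats::median(a), stats::median(b)),
                   sd = c(stats::sd(a), stats::sd(b)))
  nn <- c(a = length(a), b = length(b))
  np <- c(a = ga$shapiro_p, b = gb$shapiro_p)
  if (paired && all(a - b == 0)) {
    return(comparison_result(
      if (normal) "paired t-test" else "Wilcoxon signed-rank",
      0, 1, 1, gs, nn, np,
      "paired samples identical: no difference (p = 1)"))
  }
  if (normal) {
    tt <- stats::t.test(a, b, paired = paired, var.equal = TRUE,
                        alternative = "two.sided")
    comparison_result(
      if (paired) "paired t-test" else "Student's t-test",
      unname(tt$statistic), tt$p.value, tt$p.value, gs, nn, np,
      "both samples normal (Shapiro-Wilk) -> parametric branch")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                              exact = FALSE))
    comparison_result(
      if (paired) "Wilcoxon signed-rank" else "Mann-Whitney",
      unname(wt$statistic), wt$p.value, wt$p.value, gs, nn, np,
      "at least one sample non-normal (Shapiro-Wilk) -> non-parametric branch")
  }
}

#' Multi-group comparison with normality gating
#'
#' All groups normal: one-way ANOVA with Bonferroni-adjusted pairwise
#' t-tests; otherwise Kruskal-Wallis with Bonferroni-adjusted pairwise
#' Mann-Whitney tests. Any non-normal group switches the whole
#' comparison to the non-parametric branch.
#'
#' @param groups Named list of >= 3 numeric samples.
#' @param alpha Gate significance level.
#' @return A `comparison_result` whose `pairwise` table carries the raw
#'   and Bonferroni-adjusted p-value (`min(1, m * p)`, m = number of
#'   pairs) for every pair.
#' @export
compare_multi <- function(groups, alpha = 0.05) {
  if (length(groups) < 3L) stop("compare_multi needs at least 3 groups")
  if (any(!lengths(groups))) stop("empty group")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  gates <- lapply(groups, normality_gate, alpha = alpha)
  normal <- all(vapply(gates, function(g) g$decision, "") == "normal")
  vals <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  gs <- data.frame(group = names(groups),
                   mean = vapply(groups, mean, 0),
                   median = vapply(groups, stats::median, 0),
                   sd = vapply(groups, stats::sd, 0))
  nn <- lengths(groups)
  np <- vapply(gates, function(g) g$shapiro_p, 0)
  prs <- utils::combn(names(groups), 2)
  m <- ncol(prs)
  pair_p <- vapply(seq_len(m), function(i) {
    x <- groups[[prs[1, i]]]; y <- groups[[prs[2, i]]]
    if (normal) stats::t.test(x, y, var.equal = TRUE)$p.value
    else suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))$p.value
  }, 0)
  pw <- data.frame(group_1 = prs[1, ], group_2 = prs[2, ], p = pair_p,
                   adjusted_p = pmin(1, m * pair_p))
  if (normal) {
    fit <- stats::aov(vals ~ grp)
    sm <- summary(fit)[[1]]
    comparison_result("one-way ANOVA", sm$`F value`[1], sm$`Pr(>F)`[1],
                      sm$`Pr(>F)`[1], gs, nn, np,
                      "all groups normal -> ANOVA + Bonferroni pairwise t",
                      pairwise = pw)
  } else {
    kw <- stats::kruskal.test(vals, grp)
    comparison_result("Kruskal-Wallis", unname(kw$statistic), kw$p.value,
                      kw$p.value, gs, nn, np,
                      "non-normal group(s) -> Kruskal-Wallis + Bonferroni pairwise Mann-Whitney",
                      pairwise = pw)
  }
}
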