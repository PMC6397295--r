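#' Differential module activity between two conditions
#'
#' Tests every module for a shift in activity between two sample groups with
#' the two-sided Wilcoxon rank-sum (Mann-Whitney) test: exact enumeration
#' when both groups have at most 8 samples and there are no ties, otherwise
#' the normal approximation with tie and continuity correction. P-values are
#' adjusted across modules by Benjamini-Hochberg FDR.
#'
#' @param act modules x samples activity matrix (see [activity_matrix()]).
#' @param design named character vector, sample -> class label.
#' @param group1,group2 the two class labels to compare; direction is
#'   reported for `group2` relative to `group1`.
#' @param alpha FDR significance threshold (default 0.05).
#' @param direction_stat `"mean"` (default) or `"median"`: the group summary
#'   whose difference defines the up/down call.
#' @return a data.frame sorted by `fdr_p`, one row per module, with columns
#'   `module_id`, `mean_group1`, `mean_group2`, `statistic` (rank-sum W of
#'   group2 vs group1), `p_value`, `fdr_p`, `direction` (`"up"`/`"down"`),
#'   `zero_diff` (TRUE when the group summaries are exactly equal; such ties
#'   are reported as "up"), `significant` (`fdr_p < alpha`).
#' @export
compare_conditions <- function(act, design, group1, group2, alpha = 0.05,
                               direction_stat = c("mean", "median")) {
  direction_stat <- match.arg(direction_stat)
  stopifnot(is.matrix(act))
  design <- design[names(design) %in% colnames(act)]
  for (g in c(group1, group2))
    if (!g %in% design)
      stop(sprintf("unknown group label '%s' (not present among samples of the activity matrix)", g))
  s1 <- names(design)[design == group1]
  s2 <- names(design)[design == group2]
  if (length(s1) < 2L || length(s2) < 2L)
    stop(sprintf("each group needs >=2 samples (got %d in '%s', %d in '%s')",
                 length(s1), group1, length(s2), group2))

  rows <- lapply(rownames(act), function(m) {
    x1 <- act[m, s1]
    x2 <- act[m, s2]
    exact <- length(x1) <= 8L && length(x2) <= 8L &&
      !anyDuplicated(c(x1, x2))
    wt <- suppressWarnings(
      stats::wilcox.test(x2, x1, alternative = "two.sided",
                         exact = exact, correct = TRUE))
    sum1 <- if (direction_stat == "mean") mean(x1) else stats::median(x1)
    sum2 <- if (direction_stat == "mean") mean(x2) else stats::median(x2)
    data.frame(module_id = m,
               mean_group1 = mean(x1), mean_group2 = mean(x2),
               statistic = unname(wt$statistic),
               p_value = min(wt$p.value, 1),
               direction = if (sum2 >= sum1) "up" else "down",
               zero_diff = sum2 == sum1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr_p < alpha
  out <- out[order(out$fdr_p, out$p_value, out$module_id), ]
  rownames(out) <- NULL
  out[, c("module_id", "mean_group1", "mean_group2", "statistic",
          "p_value", "fdr_p", "direction", "zero_diff", "significant")]
}
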