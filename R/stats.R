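.groupSummary <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  ranks <- rank(values)  # midranks
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  data.frame(group = names(groups),
             n = sizes,
             mean = vapply(groups, mean, numeric(1)),
             meanRank = vapply(seq_along(groups), function(i)
               mean(ranks[idx == i]), numeric(1)),
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank test among k groups
#'
#' H statistic with midrank tie correction and the chi-square
#' approximation on k - 1 degrees of freedom, with per-group mean ranks
#' reported alongside.
#'
#' @param groups list of at least 2 non-empty numeric vectors (3 in the
#'   usual three-tissue comparison).
#' @return a [TestResult-class].
#' @examples
#' kruskalWallis(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
#' @export
kruskalWallis <- function(groups) {
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  if (length(groups) < 2L)
    stop("at least 2 non-empty groups are required", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups),
                       vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(values, labels)
  new("TestResult",
      statistic = unname(kt$statistic),
      pValue = min(1, unname(kt$p.value)),
      method = "Kruskal-Wallis rank sum test",
      groupSummaries = .groupSummary(groups))
}

#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided. Exact enumeration p-value when the combined sample size
#' is at most 20 and there are no ties; otherwise the normal
#' approximation with continuity and tie correction. Per-group mean
#' ranks in the pooled ranking are reported (the reporting style used
#' for lesion comparisons).
#'
#' @param a,b non-empty numeric vectors.
#' @param groupNames labels for the two groups.
#' @return a [TestResult-class].
#' @examples
#' pValue(wilcoxonRankSum(1:3, 4:6))  # 0.1
#' @export
wilcoxonRankSum <- function(a, b, groupNames = c("a", "b")) {
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  groups <- stats::setNames(list(a, b), groupNames)
  pv <- unname(wt$p.value)
  if (is.na(pv)) pv <- 1  # fully tied data carry no evidence
  new("TestResult",
      statistic = unname(wt$statistic),
      pValue = min(1, pv),
      method = paste0("Wilcoxon rank-sum test (",
                      if (exact) "exact" else "normal approximation",
                      ")"),
      groupSummaries = .groupSummary(groups))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; input order is preserved.
#'
#' @param pValues numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values, same order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(pValues) {
  if (any(is.na(pValues)) || any(pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pValues, method = "BH")
}

#' Gated pairwise comparisons after an omnibus test
#'
#' Runs the Kruskal-Wallis omnibus test; when its p-value passes the
#' gate (default 0.05), performs all pairwise two-sided Wilcoxon
#' rank-sum tests and adjusts their p-values for multiplicity
#' (Benjamini-Hochberg by default, Bonferroni available). A
#' non-significant omnibus emits no pairwise tests.
#'
#' @param groups named list of numeric vectors.
#' @param gate omnibus significance gate (default 0.05).
#' @param method "BH" (default) or "bonferroni".
#' @return list with `omnibus` (a [TestResult-class]), `pairwise`
#'   (data.frame group_a, group_b, statistic, p, p_adjusted; empty when
#'   gated out) and `gated` (logical, TRUE when pairwise tests ran).
#' @export
correctedPairwise <- function(groups, gate = 0.05,
                              method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  omnibus <- kruskalWallis(groups)
  empty <- data.frame(group_a = character(), group_b = character(),
                      statistic = numeric(), p = numeric(),
                      p_adjusted = numeric(), stringsAsFactors = FALSE)
  if (pValue(omnibus) >= gate)
    return(list(omnibus = omnibus, pairwise = empty, gated = FALSE))
  nm <- names(groups)
  pairs <- utils::combn(seq_along(groups), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    wt <- wilcoxonRankSum(groups[[i1]], groups[[i2]],
                          groupNames = nm[c(i1, i2)])
    data.frame(group_a = nm[i1], group_b = nm[i2],
               statistic = wt@statistic, p = pValue(wt),
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$p_adjusted <- if (method == "BH") bhAdjust(pw$p) else
    pmin(1, pw$p * nrow(pw))
  list(omnibus = omnibus, pairwise = pw, gated = TRUE)
}
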