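# Exact and multiple-comparison statistics: Fisher's exact test on 2x2
# tables (point-probability two-sided definition) and Tukey-Kramer all-pairs
# comparison of per-animal frequencies.

#' Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins and sums exact hypergeometric point
#' probabilities; no normal approximation. The one-sided p-value is the
#' smaller hypergeometric tail at the observed cell; the two-sided p-value
#' follows the point-probability (Fisher) definition: the sum of all point
#' probabilities not exceeding that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with \code{table}, \code{p_one_sided}, \code{p_two_sided},
#'   and \code{odds_ratio} (sample odds ratio; may be \code{Inf}).
#' @examples
#' fisherExact2x2(matrix(c(38, 111, 2, 26), nrow = 2, byrow = TRUE))
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("expected a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers")
  if (sum(table) == 0) {
    warning("all-zero table: no information, p = 1")
    return(list(table = table, p_one_sided = 1, p_two_sided = 1,
                odds_ratio = NaN))
  }
  x <- table[1L, 1L]
  m <- sum(table[, 1L])            # first-column margin
  n <- sum(table[, 2L])
  k <- sum(table[1L, ])            # first-row margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  ptail <- min(phyper(x, m, n, k), phyper(x - 1L, m, n, k,
                                          lower.tail = FALSE))
  dx <- dhyper(x, m, n, k)
  support <- lo:hi
  d <- dhyper(support, m, n, k)
  p2 <- sum(d[d <= dx * (1 + 1e-7)])
  orat <- (table[1L, 1L] * table[2L, 2L]) /
          (table[1L, 2L] * table[2L, 1L])
  list(table = table, p_one_sided = min(1, ptail),
       p_two_sided = min(1, p2), odds_ratio = orat)
}

#' Tukey-Kramer all-pairs comparison of group means
#'
#' Classical one-way ANOVA pooled within-group variance with
#' studentized-range p-values for every unordered pair of groups; the
#' Tukey-Kramer standard error handles unbalanced group sizes. Applied in
#' this package to raw per-animal frequencies (no transformation); pass
#' log-transformed values explicitly if a log scale is wanted.
#'
#' @param valuesByGroup Named list of numeric vectors, one per group, each
#'   of length >= 2.
#' @return List with \code{comparisons} (data.frame: \code{groupA},
#'   \code{groupB}, \code{mean_diff}, \code{q_statistic},
#'   \code{p_adjusted}, \code{significant_at_0.05},
#'   \code{significant_at_0.01}), \code{pooled_within_variance} and
#'   \code{df_error}.
#' @examples
#' tukeyHsd(list(a = c(4, 5, 6), b = c(9, 10, 11)))$comparisons
#' @export
tukeyHsd <- function(valuesByGroup) {
  k <- length(valuesByGroup)
  if (k < 2L) stop("need at least two groups")
  if (is.null(names(valuesByGroup)) || any(names(valuesByGroup) == ""))
    names(valuesByGroup) <- paste0("group", seq_len(k))
  ni <- lengths(valuesByGroup)
  if (any(ni < 2L))
    stop("every group needs at least two values for a pooled variance")
  mi <- vapply(valuesByGroup, mean, 0)
  vi <- vapply(valuesByGroup, function(v) sum((v - mean(v))^2), 0)
  df <- sum(ni) - k
  s2 <- sum(vi) / df
  idx <- utils::combn(k, 2L)
  diff <- mi[idx[1L, ]] - mi[idx[2L, ]]
  se <- sqrt(s2 / 2 * (1 / ni[idx[1L, ]] + 1 / ni[idx[2L, ]]))
  q <- ifelse(se > 0, abs(diff) / se, ifelse(diff == 0, 0, Inf))
  p <- ifelse(is.infinite(q), 0,
              ptukey(q, nmeans = k, df = df, lower.tail = FALSE))
  p[q == 0] <- 1
  comp <- data.frame(groupA = names(valuesByGroup)[idx[1L, ]],
                     groupB = names(valuesByGroup)[idx[2L, ]],
                     mean_diff = unname(diff), q_statistic = unname(q),
                     p_adjusted = unname(p),
                     significant_at_0.05 = unname(p < 0.05),
                     significant_at_0.01 = unname(p < 0.01),
                     stringsAsFactors = FALSE)
  list(comparisons = comp, pooled_within_variance = s2, df_error = df)
}

#' Tukey comparison of per-animal frequencies across treatment groups
#'
#' Convenience wrapper: computes the chosen per-animal frequency with
#' [groupSummary()] and compares all group pairs with [tukeyHsd()].
#'
#' @inheritParams groupSummary
#' @return See [tukeyHsd()].
#' @export
compareGroups <- function(x, category = NULL, independent = FALSE) {
  per <- groupSummary(x, category, independent)$per_animal
  tukeyHsd(split(per$frequency, per$group_id))
}
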