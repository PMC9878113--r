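#' Unpaired two-tailed t-test
#'
#' Two-sided test on two independent samples, with Welch-Satterthwaite
#' degrees of freedom by default or the pooled-variance form. Degenerate
#' zero-variance inputs are resolved explicitly: equal means give `t = 0`,
#' `p = 1`; unequal means give the `p -> 0` limit with a flag.
#'
#' @param x,y Numeric vectors, each of length >= 2, finite.
#' @param variance_mode `"welch"` (default) or `"pooled"`.
#' @return A list with `t`, `p`, `df` and `degenerate` (TRUE when both
#'   variances were zero).
#' @export
welch_t_test <- function(x, y, variance_mode = c("welch", "pooled")) {
  variance_mode <- match.arg(variance_mode)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, p = 1, df = NA_real_, degenerate = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = NA_real_,
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, alternative = "two.sided",
                      var.equal = variance_mode == "pooled")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: the adjusted value of the i-th
#' order statistic is `min over j >= i of m * p_(j) / j`, capped at 1, and
#' results are returned in the input order. Thin wrapper over
#' [stats::p.adjust()] providing the package's module surface.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Call differential expression between two sample groups
#'
#' The study's screening rule: per-feature unpaired two-tailed t-test on log2
#' values, Benjamini-Hochberg adjustment across all tested features of the
#' platform and comparison, fold change as `2^(mean_a - mean_b)` (a geometric
#' mean ratio, consistent with testing on the log2 scale), and the dual
#' threshold: adjusted p below `alpha` together with fold change at least
#' `fc_threshold` ("Higher") or at most `1/fc_threshold` ("Lower").
#'
#' @param x An [expr_matrix()] on the log2 scale.
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   size >= 2. Fold changes are a-over-b.
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param variance_mode Passed to [welch_t_test()].
#' @return Data.frame with one row per feature: `feature_id`, `mean_log2_a`,
#'   `mean_log2_b`, `log2fc`, `fold_change`, `p_raw`, `p_adj`, `direction`
#'   (one of `"Lower"`, `"Higher"`, `"NotSignificant"`).
#' @export
call_differential <- function(x, group_a, group_b, fc_threshold = 1.5,
                              alpha = 0.05,
                              variance_mode = c("welch", "pooled")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "log2")
    stop("call_differential expects a log2-scale matrix", call. = FALSE)
  if (length(intersect(group_a, group_b)))
    stop("consistency error: overlapping groups", call. = FALSE)
  miss <- setdiff(c(group_a, group_b), colnames(x$values))
  if (length(miss))
    stop("unknown samples: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  va <- x$values[, group_a, drop = FALSE]
  vb <- x$values[, group_b, drop = FALSE]
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  p_raw <- vapply(seq_len(nrow(va)), function(i)
    welch_t_test(va[i, ], vb[i, ], variance_mode)$p, numeric(1))
  p_adj <- benjamini_hochberg(p_raw)
  log2fc <- mean_a - mean_b
  fc <- 2^log2fc
  direction <- rep("NotSignificant", length(fc))
  direction[p_adj < alpha & fc >= fc_threshold] <- "Higher"
  direction[p_adj < alpha & fc <= 1 / fc_threshold] <- "Lower"
  data.frame(feature_id = rownames(x$values), mean_log2_a = mean_a,
             mean_log2_b = mean_b, log2fc = log2fc, fold_change = fc,
             p_raw = p_raw, p_adj = p_adj, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a volcano-plot table
#'
#' One row per record: feature id, log2 fold change, `-log10` adjusted p
#' (capped for zero p-values) and direction call, ready for plotting.
#'
#' @param records Output of [call_differential()].
#' @param cap Ceiling for `-log10(p_adj)` when `p_adj` is 0 (default 300).
#' @return Data.frame with columns `feature_id`, `log2fc`,
#'   `neg_log10_p_adj`, `direction`.
#' @export
export_volcano <- function(records, cap = 300) {
  if (nrow(records) == 0)
    return(data.frame(feature_id = character(0), log2fc = numeric(0),
                      neg_log10_p_adj = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  nl <- -log10(records$p_adj)
  nl[!is.finite(nl)] <- cap
  nl <- pmin(nl, cap)
  data.frame(feature_id = records$feature_id, log2fc = records$log2fc,
             neg_log10_p_adj = nl, direction = records$direction,
             stringsAsFactors = FALSE)
}

#' Count fixture rows passing the screening thresholds
#'
#' Re-applies the dual screening rule to a printed table whose fold changes
#' are rounded to 2 decimals: adjusted p below `alpha` and fold change at
#' least `fc_threshold` or at most `round(1/fc_threshold, 2)` (the rounded
#' image of the reciprocal bound, 0.67 for the default 1.5).
#'
#' @param table A data.frame from [load_fixture_table()].
#' @param fc_threshold,alpha Screening thresholds.
#' @return Integer count of qualifying rows.
#' @export
count_qualifying <- function(table, fc_threshold = 1.5, alpha = 0.05) {
  lower_bound <- round(1 / fc_threshold, 2)
  sum(table$adjusted_p < alpha &
        (table$fold_change >= fc_threshold |
           table$fold_change <= lower_bound))
}
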