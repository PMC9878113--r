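#' Filter features by per-group detection rate
#'
#' Implements the 50% detection-rate rule: a feature is retained when it is
#' detected in at least `min_rate` of the samples of at least one group
#' (`mode = "any_group"`, the default) or of every group
#' (`mode = "all_groups"`). Both readings of the rule are exposed because the
#' original wording is ambiguous.
#'
#' @param x An [expr_matrix()].
#' @param annotation Sample annotation data.frame with `sample_id` and
#'   `group`; every sample of `x` must be annotated.
#' @param min_rate Minimum detection fraction, in (0, 1] (default 0.5).
#' @param mode `"any_group"` or `"all_groups"`.
#' @return A list with `matrix` (the filtered [expr_matrix()]) and `report`,
#'   a list with `kept_features`, `dropped_features` and `detection_rates`
#'   (feature x group matrix of detection fractions).
#' @export
detection_filter <- function(x, annotation, min_rate = 0.5,
                             mode = c("any_group", "all_groups")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "expr_matrix"), min_rate > 0, min_rate <= 1)
  annotation <- validate_annotation(annotation)
  samples <- colnames(x$values)
  missing <- setdiff(samples, annotation$sample_id)
  if (length(missing))
    stop("consistency error: samples missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  grp <- annotation$group[match(samples, annotation$sample_id)]
  groups <- sort(unique(grp))
  rates <- vapply(groups, function(g)
    rowMeans(x$detected[, grp == g, drop = FALSE]),
    numeric(nrow(x$values)))
  rates <- matrix(rates, nrow = nrow(x$values),
                  dimnames = list(rownames(x$values), groups))
  keep <- if (mode == "any_group")
    apply(rates >= min_rate, 1, any)
  else
    apply(rates >= min_rate, 1, all)
  kept <- rownames(x$values)[keep]
  dropped <- rownames(x$values)[!keep]
  out <- subset_expr(x, features = kept)
  list(matrix = out,
       report = list(kept_features = kept, dropped_features = dropped,
                     detection_rates = rates, min_rate = min_rate,
                     mode = mode))
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share one reference distribution: the
#' vector of row-wise means of the per-column sorted values. Ties within a
#' column receive the mean of the reference values over the tied ranks.
#' Undetected cells keep their measured intensity (detection calls are used
#' only for filtering). Delegates the numerics to
#' [limma::normalizeQuantiles()], whose tie convention is exactly this one.
#'
#' @param x An [expr_matrix()] on the raw scale.
#' @return The normalized [expr_matrix()], still on the raw scale.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "raw")
    stop("quantile_normalize expects a raw-scale matrix", call. = FALSE)
  if (nrow(x$values) == 1) {
    warning("single-feature matrix: quantile normalization is a no-op")
    return(x)
  }
  if (anyNA(x$values))
    stop("missing values are not allowed; filter features first", call. = FALSE)
  norm <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(norm) <- dimnames(x$values)
  expr_matrix(norm, x$detected, scale = "raw", platform = x$platform)
}

#' Log2-transform a raw-scale expression matrix
#'
#' @param x An [expr_matrix()] on the raw scale (values >= 0).
#' @param offset Non-negative constant added before taking logs (default 1,
#'   so zeros map to zero).
#' @return The [expr_matrix()] on the log2 scale.
#' @export
log2_transform <- function(x, offset = 1.0) {
  stopifnot(inherits(x, "expr_matrix"), offset >= 0)
  if (x$scale != "raw")
    stop("matrix is already on the log2 scale", call. = FALSE)
  if (any(x$values < 0, na.rm = TRUE))
    stop("domain error: negative intensities", call. = FALSE)
  if (offset == 0 && any(x$values == 0, na.rm = TRUE))
    stop("domain error: zero intensities need a positive offset", call. = FALSE)
  expr_matrix(log2(x$values + offset), x$detected, scale = "log2",
              platform = x$platform)
}

#' Average-linkage hierarchical clustering of samples or features
#'
#' Agglomerative UPGMA clustering under Euclidean distance on the log2
#' matrix, the procedure behind the study's QC dendrograms and heatmap
#' orderings. Items are ordered lexicographically by id before clustering so
#' merge order under tied distances is deterministic.
#'
#' @param x An [expr_matrix()] on the log2 scale.
#' @param axis Cluster `"samples"` (columns, default) or `"features"` (rows).
#' @return A list of class `upgma_dendrogram` with `merge` (standard hclust
#'   merge matrix), `height`, `labels`, `order` and the underlying `hclust`
#'   object.
#' @export
hierarchical_cluster <- function(x, axis = c("samples", "features")) {
  axis <- match.arg(axis)
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "log2")
    stop("hierarchical_cluster expects a log2-scale matrix", call. = FALSE)
  m <- if (axis == "samples") t(x$values) else x$values
  if (nrow(m) < 2) {
    warning("single item: returning a trivial one-leaf tree")
    return(structure(list(merge = matrix(integer(0), 0, 2), height = numeric(0),
                          labels = rownames(m), order = 1L, hclust = NULL),
                     class = "upgma_dendrogram"))
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 order = hc$order, hclust = hc),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("<upgma_dendrogram> %d leaves, %d merges, max height %.4g\n",
              length(x$labels), length(x$height),
              if (length(x$height)) max(x$height) else 0))
  invisible(x)
}
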