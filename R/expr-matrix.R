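#' Construct an expression matrix with detection calls
#'
#' The central container of the package: a feature-by-sample matrix of
#' microarray intensities together with per-cell detection calls, the scale
#' the values live on (`"raw"` linear intensities or `"log2"`), and the
#' platform (`"miRNA"` or `"mRNA"`).
#'
#' @param values Numeric feature x sample matrix. Row names are feature ids,
#'   column names sample ids; both must be unique and non-empty.
#' @param detected Logical matrix of the same shape flagging whether each
#'   feature was called detected in each sample. Defaults to all `TRUE`.
#' @param scale Either `"raw"` (non-negative linear intensities) or `"log2"`.
#' @param platform Either `"miRNA"` or `"mRNA"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `detected`, `scale` and `platform`.
#' @export
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("f", 1:3), c("s1", "s2")))
#' em <- expr_matrix(m, platform = "miRNA")
#' dim(em)
expr_matrix <- function(values, detected = NULL, scale = c("raw", "log2"),
                        platform = c("miRNA", "mRNA")) {
  scale <- match.arg(scale)
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids", call. = FALSE)
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  }
  if (!is.logical(detected) || !identical(dim(detected), dim(values)))
    stop("`detected` must be a logical matrix of the same shape as `values`",
         call. = FALSE)
  dimnames(detected) <- dimnames(values)
  if (scale == "raw" && any(!is.finite(values) | values < 0))
    stop("raw-scale values must be finite and >= 0", call. = FALSE)
  structure(list(values = values, detected = detected,
                 scale = scale, platform = platform),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' Feature and sample identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s platform, %s scale: %d features x %d samples\n",
              x$platform, x$scale, nrow(x$values), ncol(x$values)))
  cat(sprintf("  detected calls: %.1f%% TRUE\n", 100 * mean(x$detected)))
  invisible(x)
}

#' Subset an expression matrix by features and/or samples
#'
#' @param x An `expr_matrix`.
#' @param features,samples Character vectors of ids (or indices) to keep;
#'   `NULL` keeps everything on that axis.
#' @return The subsetted `expr_matrix`.
#' @export
subset_expr <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(features)) features <- rownames(x$values)
  if (is.null(samples)) samples <- colnames(x$values)
  if (is.character(features)) {
    missing <- setdiff(features, rownames(x$values))
    if (length(missing))
      stop("unknown features: ", paste(utils::head(missing, 5), collapse = ", "),
           call. = FALSE)
  }
  if (is.character(samples)) {
    missing <- setdiff(samples, colnames(x$values))
    if (length(missing))
      stop("unknown samples: ", paste(utils::head(missing, 5), collapse = ", "),
           call. = FALSE)
  }
  expr_matrix(x$values[features, samples, drop = FALSE],
              x$detected[features, samples, drop = FALSE],
              scale = x$scale, platform = x$platform)
}
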