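#' Spearman rank correlation with a t-approximation p-value
#'
#' Rho is computed from mid-ranks (ties receive the average rank); the
#' two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' with `|rho| = 1` mapped to the `p -> 0` limit. Constant input yields an
#' undefined correlation, returned as a non-evaluable sentinel.
#'
#' @param x,y Numeric vectors of equal length >= 4, finite.
#' @return A list with `rho`, `p`, `n` and `evaluable`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 4) stop("need at least 4 paired observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, evaluable = FALSE))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, evaluable = TRUE)
}

#' Build the inverse miRNA-mRNA correlation network
#'
#' For every cross pair of a differentially expressed miRNA and mRNA with
#' opposite direction calls and a 3'UTR binding site on record, the Spearman
#' correlation is computed across the stated samples; a pair becomes an edge
#' iff `rho <= -rho_threshold` and `p < alpha`. With
#' `permissive_sign = TRUE`, pairs with `|rho| >= rho_threshold` of either
#' sign are admitted instead (a sensitivity mode; the default requires the
#' inverse direction that repression predicts). Correlation p-values are not
#' multiplicity-adjusted by default; `adjust = TRUE` applies
#' Benjamini-Hochberg across all gated candidate pairs.
#'
#' @param mirna,mrna [expr_matrix()] objects on the log2 scale.
#' @param de_mirna,de_mrna Data.frames from [call_differential()]; rows with
#'   direction `"Lower"` or `"Higher"` define the node candidates.
#' @param sites Binding-site data.frame (see [read_binding_sites()]); mRNA
#'   feature ids are matched against `gene_id`.
#' @param samples Sample ids to correlate over (default: all samples shared
#'   by both matrices).
#' @param rho_threshold Correlation-magnitude threshold (default 0.5).
#' @param alpha Correlation p cutoff (default 0.05).
#' @param permissive_sign Admit either correlation sign (default FALSE).
#' @param adjust Apply BH to candidate-pair p-values (default FALSE).
#' @param probe_to_gene Optional data.frame with columns `probe_id`,
#'   `gene_id` mapping mRNA feature ids to gene symbols for the binding-site
#'   lookup; by default the feature id is taken to be the gene symbol.
#' @return A list with `edges` (data.frame: `mirna`, `mrna`, `rho`, `p`,
#'   `mirna_direction`, `mrna_direction`, `has_site`, `n_samples`) and
#'   `summary` (see [summarize_network()]).
#' @export
build_network <- function(mirna, mrna, de_mirna, de_mrna, sites,
                          samples = NULL, rho_threshold = 0.5, alpha = 0.05,
                          permissive_sign = FALSE, adjust = FALSE,
                          probe_to_gene = NULL) {
  stopifnot(inherits(mirna, "expr_matrix"), inherits(mrna, "expr_matrix"))
  if (mirna$scale != "log2" || mrna$scale != "log2")
    stop("build_network expects log2-scale matrices", call. = FALSE)
  if (is.null(samples))
    samples <- intersect(colnames(mirna$values), colnames(mrna$values))
  miss <- setdiff(samples, intersect(colnames(mirna$values),
                                     colnames(mrna$values)))
  if (length(miss))
    stop("samples absent from a matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  empty <- data.frame(mirna = character(0), mrna = character(0),
                      rho = numeric(0), p = numeric(0),
                      mirna_direction = character(0),
                      mrna_direction = character(0),
                      has_site = logical(0), n_samples = integer(0),
                      stringsAsFactors = FALSE)
  de_mi <- de_mirna[de_mirna$direction %in% c("Lower", "Higher"), ]
  de_mr <- de_mrna[de_mrna$direction %in% c("Lower", "Higher"), ]
  if (nrow(de_mi) == 0 || nrow(de_mr) == 0)
    return(list(edges = empty, summary = summarize_network(empty)))

  site_key <- unique(paste(sites$mirna_id, sites$gene_id, sep = "\r"))
  cand <- expand.grid(mi = de_mi$feature_id, mr = de_mr$feature_id,
                      stringsAsFactors = FALSE)
  cand$dir_mi <- de_mi$direction[match(cand$mi, de_mi$feature_id)]
  cand$dir_mr <- de_mr$direction[match(cand$mr, de_mr$feature_id)]
  cand <- cand[cand$dir_mi != cand$dir_mr, ]
  gene_of <- if (is.null(probe_to_gene)) cand$mr else
    probe_to_gene$gene_id[match(cand$mr, probe_to_gene$probe_id)]
  cand <- cand[!is.na(gene_of) &
                 paste(cand$mi, gene_of, sep = "\r") %in% site_key, ]
  cand <- cand[cand$mi %in% rownames(mirna$values) &
                 cand$mr %in% rownames(mrna$values), ]
  if (nrow(cand) == 0)
    return(list(edges = empty, summary = summarize_network(empty)))

  res <- lapply(seq_len(nrow(cand)), function(k) {
    spearman_cor(mirna$values[cand$mi[k], samples],
                 mrna$values[cand$mr[k], samples])
  })
  rho <- vapply(res, `[[`, numeric(1), "rho")
  p <- vapply(res, `[[`, numeric(1), "p")
  if (adjust) {
    ok <- !is.na(p)
    p[ok] <- benjamini_hochberg(p[ok])
  }
  keep <- !is.na(rho) & p < alpha &
    if (permissive_sign) abs(rho) >= rho_threshold else rho <= -rho_threshold
  edges <- data.frame(mirna = cand$mi[keep], mrna = cand$mr[keep],
                      rho = rho[keep], p = p[keep],
                      mirna_direction = cand$dir_mi[keep],
                      mrna_direction = cand$dir_mr[keep],
                      has_site = TRUE, n_samples = length(samples),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$mirna, edges$mrna), ]
  rownames(edges) <- NULL
  list(edges = edges, summary = summarize_network(edges))
}

#' Summarize a miRNA-mRNA network
#'
#' Tallies edges by direction pattern and counts distinct nodes by
#' regulation direction, both at pair level (edges) and gene level (distinct
#' node ids), without asserting the two views coincide.
#'
#' @param edges Edge data.frame as produced by [build_network()].
#' @return A list with `n_edges`, `n_edges_lowmi_highmr`,
#'   `n_edges_highmi_lowmr`, `n_mirna_lower`, `n_mirna_higher`,
#'   `n_mrna_lower`, `n_mrna_higher`, `n_mirna`, `n_mrna`.
#' @export
summarize_network <- function(edges) {
  lohi <- edges$mirna_direction == "Lower" & edges$mrna_direction == "Higher"
  hilo <- edges$mirna_direction == "Higher" & edges$mrna_direction == "Lower"
  list(
    n_edges = nrow(edges),
    n_edges_lowmi_highmr = sum(lohi),
    n_edges_highmi_lowmr = sum(hilo),
    n_mirna_lower = length(unique(edges$mirna[edges$mirna_direction == "Lower"])),
    n_mirna_higher = length(unique(edges$mirna[edges$mirna_direction == "Higher"])),
    n_mrna_lower = length(unique(edges$mrna[edges$mrna_direction == "Lower"])),
    n_mrna_higher = length(unique(edges$mrna[edges$mrna_direction == "Higher"])),
    n_mirna = length(unique(edges$mirna)),
    n_mrna = length(unique(edges$mrna)))
}

#' Re-validate every retained network edge against all four gates
#'
#' Independent post-hoc check that each edge has a binding site, a
#' significant p, a correlation at or beyond the threshold with negative
#' sign, and opposite direction calls.
#'
#' @param edges Edge data.frame.
#' @param sites Binding-site table.
#' @param rho_threshold,alpha Gate parameters used to build the network.
#' @return TRUE invisibly; stops with a message on the first violated gate.
#' @export
validate_edges <- function(edges, sites, rho_threshold = 0.5, alpha = 0.05) {
  if (nrow(edges) == 0) return(invisible(TRUE))
  site_key <- paste(sites$mirna_id, sites$gene_id)
  if (!all(paste(edges$mirna, edges$mrna) %in% site_key))
    stop("edge without a binding site", call. = FALSE)
  if (!all(edges$p < alpha)) stop("edge with p >= alpha", call. = FALSE)
  if (!all(edges$rho <= -rho_threshold))
    stop("edge violating the inverse-correlation gate", call. = FALSE)
  if (!all(edges$mirna_direction != edges$mrna_direction))
    stop("edge with same-direction regulation", call. = FALSE)
  invisible(TRUE)
}
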