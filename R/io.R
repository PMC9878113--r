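#' Read an expression matrix from a tab-delimited file
#'
#' Expects a header row of sample ids, a first column of feature ids, and
#' optionally one `<sample>.detected` logical column per sample carrying the
#' platform's detection calls. When detection columns are absent every cell is
#' treated as detected.
#'
#' @param path Path to a TSV file.
#' @param platform `"miRNA"` or `"mRNA"`.
#' @param scale Scale of the stored values, `"raw"` (default) or `"log2"`.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, platform = c("miRNA", "mRNA"),
                                   scale = c("raw", "log2")) {
  platform <- match.arg(platform)
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = character())
  if (ncol(df) < 2) stop("expression TSV needs a feature column plus samples",
                         call. = FALSE)
  fid <- df[[1]]
  if (anyDuplicated(fid))
    stop("schema error: duplicate feature ids in ", path, call. = FALSE)
  cols <- colnames(df)[-1]
  is_det <- grepl("\\.detected$", cols)
  det_cols <- cols[is_det]
  val_cols <- cols[!is_det]   # keep duplicates so the schema check sees them
  if (anyDuplicated(val_cols))
    stop("schema error: duplicate sample ids in header of ", path, call. = FALSE)
  vals <- matrix(NA_real_, length(fid), length(val_cols),
                 dimnames = list(fid, val_cols))
  for (s in val_cols) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    bad <- which(is.na(v) & !(df[[s]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("parse error: non-numeric cell at row %d (feature %s), column %s",
                   bad[1], fid[bad[1]], s), call. = FALSE)
    vals[, s] <- v
  }
  det <- matrix(TRUE, length(fid), length(val_cols),
                dimnames = list(fid, val_cols))
  for (dcol in det_cols) {
    s <- sub("\\.detected$", "", dcol)
    if (!s %in% val_cols)
      stop("schema error: detection column ", dcol, " has no matching sample",
           call. = FALSE)
    det[, s] <- as.logical(df[[dcol]])
  }
  expr_matrix(vals, det, scale = scale, platform = platform)
}

#' Write an expression matrix to a tab-delimited file
#'
#' Inverse of [read_expression_matrix()]: values are written with full
#' precision (`%.17g`) so a write/read round trip is bitwise exact. Detection
#' columns are emitted only when any cell is undetected.
#'
#' @param x An [expr_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature_id = rownames(x$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (s in colnames(x$values)) df[[s]] <- sprintf("%.17g", x$values[, s])
  if (!all(x$detected)) {
    for (s in colnames(x$values))
      df[[paste0(s, ".detected")]] <- x$detected[, s]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample annotation table
#'
#' Columns: `sample_id`, `group` (one of `TGA_RV`, `TGA_LV`, `control`), and
#' optionally `overt_hf`, `death` (logical) and the clinical markers
#' `ntprobnp` (pg/ml), `hstnt` (pg/ml), `egfr` (ml/min). Missing marker values
#' are empty cells (controls routinely lack these labs), never zeros.
#'
#' @param path TSV path.
#' @return A data.frame with one row per sample.
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_annotation(df)
}

validate_annotation <- function(df) {
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("annotation needs sample_id and group columns", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("schema error: duplicate sample ids in annotation", call. = FALSE)
  bad <- setdiff(unique(df$group), c("TGA_RV", "TGA_LV", "control"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (col in c("overt_hf", "death"))
    if (col %in% colnames(df)) df[[col]] <- as.logical(df[[col]])
  for (col in c("ntprobnp", "hstnt", "egfr"))
    if (col %in% colnames(df)) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write a sample annotation table
#' @param annotation Data.frame as returned by [read_sample_annotation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a miRNA to gene 3'UTR binding-site table
#'
#' One row per predicted site: `mirna_id`, `gene_id`, `region` (always `UTR3`
#' in this version), `site_start` (>= 0) and `site_end` (> `site_start`).
#' Such tables are produced by target-prediction engines (e.g. TargetScan)
#' and consumed here as data.
#'
#' @param path TSV path.
#' @return A data.frame of validated binding sites.
#' @export
read_binding_sites <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_binding_sites(df)
}

validate_binding_sites <- function(df) {
  need <- c("mirna_id", "gene_id", "region", "site_start", "site_end")
  if (!all(need %in% colnames(df)))
    stop("binding-site table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$region != "UTR3"))
    stop("only UTR3 regions are supported", call. = FALSE)
  if (any(df$site_start < 0) || any(df$site_end <= df$site_start))
    stop("invalid site coordinates", call. = FALSE)
  df
}

#' Write a binding-site table
#' @param sites Data.frame of binding sites.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_binding_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Packaged fixture files transcribing the printed differential-expression
# tables (miRNA: pooled TGA vs control, TGA-LV vs TGA-RV, TGA-RV vs control;
# mRNA: pooled TGA vs control, TGA-RV vs control).
.fixture_files <- c(
  T2A = "table2a_mirna_tga_vs_control.tsv",
  T2B = "table2b_mirna_tgalv_vs_tgarv.tsv",
  T2C = "table2c_mirna_tgarv_vs_control.tsv",
  T3A = "table3a_mrna_tga_vs_control.tsv",
  T3B = "table3b_mrna_tgarv_vs_control.tsv"
)

.fixture_comparisons <- c(
  T2A = "TGA vs control (miRNA)",
  T2B = "TGA-LV vs TGA-RV (miRNA)",
  T2C = "TGA-RV vs control (miRNA)",
  T3A = "TGA vs control (mRNA)",
  T3B = "TGA-RV vs control (mRNA)"
)

#' Load a packaged printed differential-expression table
#'
#' The package ships the study's printed significance tables verbatim:
#' `T2A` (39 miRNAs, pooled TGA vs control), `T2B` (51 miRNAs, TGA-LV vs
#' TGA-RV), `T2C` (101 miRNAs, TGA-RV vs control), `T3A` (36 mRNAs, pooled
#' TGA vs control) and `T3B` (164 mRNAs, TGA-RV vs control). Fold changes are
#' stored exactly as printed (2 decimals), adjusted p-values to 4 decimals.
#'
#' @param name One of `"T2A"`, `"T2B"`, `"T2C"`, `"T3A"`, `"T3B"`.
#' @return A data.frame with columns `feature_id`, `fold_change`,
#'   `adjusted_p`, `regulation`, carrying a `"comparison"` attribute.
#' @export
#' @examples
#' t2a <- load_fixture_table("T2A")
#' nrow(t2a)  # 39
load_fixture_table <- function(name) {
  if (length(name) != 1 || !name %in% names(.fixture_files))
    stop("unknown fixture table: ", name, " (expected one of ",
         paste(names(.fixture_files), collapse = ", "), ")", call. = FALSE)
  path <- system.file("extdata", .fixture_files[[name]], package = "tgamir",
                      mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$fold_change <- as.numeric(df$fold_change)
  df$adjusted_p <- as.numeric(df$adjusted_p)
  stopifnot(all(df$fold_change > 0),
            all((df$regulation == "Lower") == (df$fold_change < 1)))
  attr(df, "comparison") <- .fixture_comparisons[[name]]
  df
}

#' Write a miRNA-mRNA correlation network to TSV (and optionally GraphML)
#'
#' @param edges Data.frame of correlation edges with columns `mirna`, `mrna`,
#'   `rho`, `p`, `mirna_direction`, `mrna_direction`, `has_site`.
#' @param path Output TSV path.
#' @param graphml Optional path for a GraphML export of the bipartite network
#'   (requires the igraph package).
#' @return Invisibly, `path`.
#' @export
write_network <- function(edges, path, graphml = NULL) {
  cols <- c("mirna", "mrna", "rho", "p", "mirna_direction", "mrna_direction",
            "has_site")
  if (nrow(edges) == 0) {
    edges <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
  }
  if (!all(cols %in% colnames(edges)))
    stop("edge table needs columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  out <- edges[, cols, drop = FALSE]
  if (nrow(out)) {
    out$rho <- sprintf("%.17g", as.numeric(out$rho))
    out$p <- sprintf("%.17g", as.numeric(out$p))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml)) {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop("GraphML export needs the igraph package", call. = FALSE)
    if (nrow(edges)) {
      g <- igraph::graph_from_data_frame(
        edges[, c("mirna", "mrna", "rho", "p")], directed = TRUE)
      igraph::V(g)$type <- igraph::V(g)$name %in% edges$mrna
    } else {
      g <- igraph::make_empty_graph()
    }
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge table written by [write_network()]
#' @param path TSV path.
#' @return Data.frame of edges.
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df)) {
    df$rho <- as.numeric(df$rho)
    df$p <- as.numeric(df$p)
    df$has_site <- as.logical(df$has_site)
  }
  df
}
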