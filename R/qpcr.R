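#' Compute per-sample delta-Ct values with a Ct gate
#'
#' Relative quantification against an endogenous reference (RNU6B by
#' convention): `dCt = Ct_assay - Ct_reference` per sample. Lower dCt means
#' higher abundance. Sample-assay measurements whose Ct exceeds the gate are
#' dropped for that assay; samples whose reference fails the gate or is
#' missing are excluded entirely with a warning.
#'
#' @param ct_table Data.frame with columns `sample_id`, `assay_id`, `ct`.
#' @param reference_id Reference assay id (default `"RNU6B"`).
#' @param gate Maximum usable Ct (default 35).
#' @return Data.frame with columns `sample_id`, `assay_id`, `dct`, plus an
#'   attribute `"dropped"` logging excluded measurements.
#' @export
compute_delta_ct <- function(ct_table, reference_id = "RNU6B", gate = 35) {
  need <- c("sample_id", "assay_id", "ct")
  if (!all(need %in% colnames(ct_table)))
    stop("ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ref <- ct_table[ct_table$assay_id == reference_id, ]
  if (nrow(ref) == 0)
    stop("reference assay ", reference_id, " not found", call. = FALSE)
  ref_ok <- ref[ref$ct <= gate, ]
  lost_samples <- setdiff(unique(ct_table$sample_id), ref_ok$sample_id)
  if (length(lost_samples))
    warning("excluding samples with failing or missing reference: ",
            paste(lost_samples, collapse = ", "))
  tgt <- ct_table[ct_table$assay_id != reference_id, ]
  usable <- tgt$ct <= gate & tgt$sample_id %in% ref_ok$sample_id
  dropped <- tgt[!usable, c("sample_id", "assay_id", "ct")]
  tgt <- tgt[usable, ]
  ref_ct <- ref_ok$ct[match(tgt$sample_id, ref_ok$sample_id)]
  out <- data.frame(sample_id = tgt$sample_id, assay_id = tgt$assay_id,
                    dct = tgt$ct - ref_ct, stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Compare group delta-Ct values per assay
#'
#' Unpaired two-tailed t-test on delta-Ct between two sample groups for every
#' assay in the panel, with Benjamini-Hochberg adjustment across the panel.
#' The additive delta-Ct scale is the unit of testing; the fold change is
#' derived afterwards as `2^(-ddct)` where `ddct = mean_dct_a - mean_dct_b`
#' (lower delta-Ct means higher abundance, so a negative ddct is an increase
#' in group a).
#'
#' @param dct_table Output of [compute_delta_ct()].
#' @param group_a,group_b Disjoint character vectors of sample ids.
#' @param alpha Significance cutoff on the adjusted p (default 0.05).
#' @param variance_mode Passed to [welch_t_test()].
#' @return Data.frame with one row per assay: `assay_id`, `n_a`, `n_b`,
#'   `mean_dct_a`, `mean_dct_b`, `ddct`, `fold_change`, `p_raw`, `p_adj`,
#'   `evaluable`.
#' @export
compare_groups_dct <- function(dct_table, group_a, group_b, alpha = 0.05,
                               variance_mode = c("welch", "pooled")) {
  variance_mode <- match.arg(variance_mode)
  if (length(intersect(group_a, group_b)))
    stop("consistency error: overlapping groups", call. = FALSE)
  assays <- sort(unique(dct_table$assay_id))
  rows <- lapply(assays, function(a) {
    da <- dct_table$dct[dct_table$assay_id == a &
                          dct_table$sample_id %in% group_a]
    db <- dct_table$dct[dct_table$assay_id == a &
                          dct_table$sample_id %in% group_b]
    if (length(da) < 2 || length(db) < 2) {
      return(data.frame(assay_id = a, n_a = length(da), n_b = length(db),
                        mean_dct_a = NA_real_, mean_dct_b = NA_real_,
                        ddct = NA_real_, fold_change = NA_real_,
                        p_raw = NA_real_, p_adj = NA_real_,
                        evaluable = FALSE, stringsAsFactors = FALSE))
    }
    ht <- welch_t_test(da, db, variance_mode)
    ddct <- mean(da) - mean(db)
    data.frame(assay_id = a, n_a = length(da), n_b = length(db),
               mean_dct_a = mean(da), mean_dct_b = mean(db), ddct = ddct,
               fold_change = 2^(-ddct), p_raw = ht$p, p_adj = NA_real_,
               evaluable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- out$evaluable
  out$p_adj[ok] <- benjamini_hochberg(out$p_raw[ok])
  attr(out, "alpha") <- alpha
  out
}

#' Classify qPCR concordance with the microarray direction calls
#'
#' For each assay with a matching array differential-expression record,
#' classifies the validation outcome: `significant_same_direction` when the
#' adjusted qPCR p is below `alpha` and the qPCR fold change points the same
#' way as the array call; `same_direction_ns` when directions agree without
#' significance; `inverse` when they disagree; `not_evaluable` when the assay
#' is absent from the array table or the qPCR comparison was not evaluable.
#'
#' @param dct_results Output of [compare_groups_dct()].
#' @param de_records Output of [call_differential()] (array results); only
#'   rows with direction `"Lower"` or `"Higher"` are matched.
#' @param alpha Significance cutoff (default: the alpha recorded on
#'   `dct_results`, else 0.05).
#' @return `dct_results` with added columns `array_direction` and
#'   `concordance`.
#' @export
concordance_with_array <- function(dct_results, de_records, alpha = NULL) {
  if (is.null(alpha)) alpha <- attr(dct_results, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  de <- de_records[de_records$direction %in% c("Lower", "Higher"), ]
  idx <- match(dct_results$assay_id, de$feature_id)
  array_dir <- de$direction[idx]
  qpcr_dir <- ifelse(dct_results$fold_change > 1, "Higher",
                     ifelse(dct_results$fold_change < 1, "Lower", NA))
  conc <- rep("not_evaluable", nrow(dct_results))
  ok <- dct_results$evaluable & !is.na(array_dir) & !is.na(qpcr_dir)
  same <- ok & qpcr_dir == array_dir
  conc[same & dct_results$p_adj < alpha] <- "significant_same_direction"
  conc[same & dct_results$p_adj >= alpha] <- "same_direction_ns"
  conc[ok & qpcr_dir != array_dir] <- "inverse"
  dct_results$array_direction <- array_dir
  dct_results$concordance <- conc
  dct_results
}
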