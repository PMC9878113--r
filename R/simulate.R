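#' Simulation configuration for synthetic study bundles
#'
#' Describes a synthetic three-arm cohort (TGA-RV, TGA-LV, control) mirroring
#' the study design of 16 samples per group, with planted differential
#' expression, repressive miRNA-to-mRNA couplings, intensity-dependent
#' detection dropout, and heart-failure strata. Feature counts default to a
#' scaled-down cohort (300 miRNA probes, 1000 mRNA features) so complete
#' pipelines run in seconds; the real platforms carry ~2,549 and ~50,599
#' features and can be requested explicitly.
#'
#' @param n_per_group Samples per group (default 16).
#' @param n_mirna,n_mrna Feature counts per platform.
#' @param frac_de_mirna,frac_de_mrna Fraction of features with a planted
#'   group effect.
#' @param effect_log2fc Minimum planted absolute log2 fold change; effects are
#'   drawn uniformly between this and `effect_log2fc_max`.
#' @param effect_log2fc_max Upper end of the planted-effect range.
#' @param shared_frac Probability that a planted effect is shared between the
#'   TGA-RV and TGA-LV contrasts (otherwise it is RV-specific, reflecting the
#'   RV-dominant signal in this disease setting).
#' @param n_regulatory_pairs Number of planted repressive miRNA-mRNA pairs.
#' @param coupling_strength Target absolute Spearman correlation of planted
#'   pairs, in (0, 0.99].
#' @param dropout_rate Overall fraction of cells flagged undetected;
#'   dropout is logistic in log2 intensity, so low-intensity cells are
#'   enriched for missing detection calls.
#' @param noise_sd_log2 Within-group standard deviation on the log2 scale.
#' @param decoy_site_factor Binding sites are also planted on this multiple of
#'   uncoupled miRNA-mRNA pairs, so the site filter does real work.
#' @param baseline_mean,baseline_sd Mean and SD of per-feature baseline log2
#'   intensities (a log-normal regime on the raw scale).
#' @param n_overt_hf,n_death Number of TGA samples flagged with overt heart
#'   failure / death (default 4 each, as in the emulated cohort).
#' @param stratum_effect_log2fc Planted log2 effect of each stratum on its
#'   single informative miRNA.
#' @param seed Integer seed; identical configs give bitwise-identical bundles.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 16, n_mirna = 300, n_mrna = 1000,
                       frac_de_mirna = 0.10, frac_de_mrna = 0.05,
                       effect_log2fc = 0.585, effect_log2fc_max = 2.0,
                       shared_frac = 0.5, n_regulatory_pairs = 30,
                       coupling_strength = 0.7, dropout_rate = 0.10,
                       noise_sd_log2 = 0.5, decoy_site_factor = 5,
                       baseline_mean = 8, baseline_sd = 2,
                       n_overt_hf = 4, n_death = 4,
                       stratum_effect_log2fc = 0.63, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_per_group >= 2, n_mirna >= 2, n_mrna >= 2,
            frac_de_mirna >= 0, frac_de_mirna < 1,
            frac_de_mrna >= 0, frac_de_mrna < 1,
            effect_log2fc > 0, effect_log2fc_max >= effect_log2fc,
            shared_frac >= 0, shared_frac <= 1,
            n_regulatory_pairs >= 0,
            n_regulatory_pairs <= n_mirna * n_mrna,
            dropout_rate >= 0, dropout_rate < 1,
            noise_sd_log2 > 0, decoy_site_factor >= 0)
  if (coupling_strength < 0 || coupling_strength > 0.99)
    stop("config error: coupling_strength must lie in [0, 0.99]; ",
         "near-perfect coupling is not attainable with noisy measurements",
         call. = FALSE)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

.group_labels <- function(n) {
  data.frame(
    sample_id = c(sprintf("C%02d", seq_len(n)), sprintf("LV%02d", seq_len(n)),
                  sprintf("RV%02d", seq_len(n))),
    group = rep(c("control", "TGA_LV", "TGA_RV"), each = n),
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study bundle
#'
#' Produces a miRNA matrix, an mRNA matrix, sample annotation, a 3'UTR
#' binding-site table and the planted ground truth. Baseline log2 intensities
#' are drawn per feature; planted differentially expressed features receive
#' additive group-specific log2 shifts; each planted regulatory pair couples
#' the target mRNA to its miRNA as
#' `mRNA = baseline - beta * (miRNA - baseline_miRNA) + extra noise`,
#' with `beta` sized so the coupled mRNA is itself differentially expressed
#' and the extra-noise SD solved so the expected pooled Spearman correlation
#' is `-coupling_strength`. Detection flags are dropped with a logistic
#' probability in log2 intensity. Matrices are returned on the raw scale so
#' the full preprocessing chain (filter, quantile-normalize, log2) applies.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_bundle` with elements `mirna` and `mrna`
#'   ([expr_matrix()] objects), `annotation`, `sites` and `truth` (a list
#'   with `de_mirna`, `de_mrna`, `regulatory_pairs`,
#'   `hf_informative_markers`).
#' @export
generate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_per_group
  ann <- .group_labels(n)
  n_samp <- nrow(ann)
  is_rv <- ann$group == "TGA_RV"
  is_lv <- ann$group == "TGA_LV"

  mirna_ids <- sprintf("miR-sim-%04d", seq_len(config$n_mirna))
  mrna_ids <- sprintf("GENE%05d", seq_len(config$n_mrna))

  draw_effects <- function(ids, frac) {
    n_de <- round(frac * length(ids))
    de_ids <- sample(ids, n_de)
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    mag <- stats::runif(n_de, config$effect_log2fc, config$effect_log2fc_max)
    shared <- stats::runif(n_de) < config$shared_frac
    eff_rv <- sgn * mag
    eff_lv <- ifelse(shared, eff_rv, 0)
    data.frame(feature_id = de_ids, effect_rv = eff_rv, effect_lv = eff_lv,
               stringsAsFactors = FALSE)
  }

  build_matrix <- function(ids, de, extra_shift = NULL) {
    mu <- stats::rnorm(length(ids), config$baseline_mean, config$baseline_sd)
    names(mu) <- ids
    shift <- matrix(0, length(ids), n_samp, dimnames = list(ids, ann$sample_id))
    if (nrow(de)) {
      shift[de$feature_id, is_rv] <- de$effect_rv
      shift[de$feature_id, is_lv] <- de$effect_lv
    }
    noise <- matrix(stats::rnorm(length(ids) * n_samp, 0, config$noise_sd_log2),
                    length(ids), n_samp)
    list(log2 = mu + shift + noise, mu = mu, shift = shift)
  }

  de_mirna <- draw_effects(mirna_ids, config$frac_de_mirna)
  mir <- build_matrix(mirna_ids, de_mirna)

  # mRNA effects planted on features that are NOT reserved as coupled targets
  n_pairs <- config$n_regulatory_pairs
  coupled_mrna <- if (n_pairs) utils::tail(mrna_ids, n_pairs) else character(0)
  free_mrna <- setdiff(mrna_ids, coupled_mrna)
  de_mrna_own <- draw_effects(free_mrna, config$frac_de_mrna)
  mrn <- build_matrix(mrna_ids, de_mrna_own)

  # Plant repressive couplings: pick miRNAs with an RV-contrast effect so the
  # coupled target inherits an opposite-direction, DE-sized shift.
  pairs <- NULL
  if (n_pairs && config$coupling_strength == 0)
    stop("config error: planted regulatory pairs require coupling_strength > 0",
         call. = FALSE)
  if (n_pairs) {
    cand <- de_mirna$feature_id[de_mirna$effect_rv != 0]
    if (length(cand) == 0)
      stop("config error: planted pairs need at least one DE miRNA",
           call. = FALSE)
    pair_mirna <- cand[((seq_len(n_pairs) - 1L) %% length(cand)) + 1L]
    target_eff <- stats::runif(n_pairs, max(config$effect_log2fc, 1.0),
                               config$effect_log2fc_max + 0.5)
    rho_target <- -config$coupling_strength
    pairs <- data.frame(mirna_id = pair_mirna, mrna_id = coupled_mrna,
                        planted_rho = rho_target,
                        beta = NA_real_, stringsAsFactors = FALSE)
    for (k in seq_len(n_pairs)) {
      mi <- pair_mirna[k]; tg <- coupled_mrna[k]
      m_dev <- mir$log2[mi, ] - mir$mu[mi]        # group shift + noise
      beta <- target_eff[k] / abs(de_mirna$effect_rv[de_mirna$feature_id == mi])
      # Calibrate the extra-noise SD so the EXPECTED pooled Spearman equals
      # the coupling target: the pooled values are a mixture of group-shifted
      # normals, so no closed form applies; estimate the rank correlation by
      # Monte Carlo over noise replicates and bisect on the noise scale.
      rk_m <- rank(m_dev)
      zcal <- matrix(stats::rnorm(30 * n_samp), nrow = 30)
      mean_rho <- function(sg) mean(apply(zcal, 1, function(z)
        stats::cor(rk_m, rank(-beta * m_dev + sg * z))))
      # mean_rho rises from -1 (sg = 0) toward 0; bisect to the target
      hi <- beta * stats::sd(m_dev)
      while (mean_rho(hi) < rho_target) hi <- hi * 2
      lo <- 0
      for (it in 1:14) {
        mid <- (lo + hi) / 2
        if (mean_rho(mid) < rho_target) lo <- mid else hi <- mid
      }
      sd_extra <- (lo + hi) / 2
      extra <- stats::rnorm(n_samp, 0, sd_extra)
      mrn$log2[tg, ] <- mrn$mu[tg] - beta * m_dev + extra
      mrn$shift[tg, ] <- -beta * mir$shift[mi, ]
      pairs$beta[k] <- beta
    }
  }

  # Full mRNA DE ground truth (own effects + coupling-inherited effects)
  de_mrna <- de_mrna_own
  if (n_pairs) {
    inherited <- data.frame(
      feature_id = coupled_mrna,
      effect_rv = mrn$shift[coupled_mrna, which(is_rv)[1]],
      effect_lv = mrn$shift[coupled_mrna, which(is_lv)[1]],
      stringsAsFactors = FALSE)
    de_mrna <- rbind(de_mrna, inherited)
  }

  # HF strata: flags live on TGA samples; each stratum has one informative
  # miRNA, planted on a feature without a group effect.
  tga_samples <- ann$sample_id[ann$group != "control"]
  rv_first <- c(ann$sample_id[is_rv], ann$sample_id[is_lv])
  ann$overt_hf <- ann$group != "control" &
    ann$sample_id %in% rv_first[seq_len(min(config$n_overt_hf, 2 * n))]
  ann$overt_hf[ann$group == "control"] <- NA
  death_pick <- sample(tga_samples, min(config$n_death, 2 * n))
  ann$death <- ann$group != "control" & ann$sample_id %in% death_pick
  ann$death[ann$group == "control"] <- NA

  non_de <- setdiff(mirna_ids, de_mirna$feature_id)
  hf_mirna <- non_de[1]; death_mirna <- non_de[2]
  mir$log2[hf_mirna, ann$sample_id[!is.na(ann$overt_hf) & ann$overt_hf]] <-
    mir$log2[hf_mirna, ann$sample_id[!is.na(ann$overt_hf) & ann$overt_hf]] +
    config$stratum_effect_log2fc
  mir$log2[death_mirna, ann$sample_id[!is.na(ann$death) & ann$death]] <-
    mir$log2[death_mirna, ann$sample_id[!is.na(ann$death) & ann$death]] +
    config$stratum_effect_log2fc

  # Clinical markers: present only for TGA samples (controls lack these labs);
  # weakly discriminative between RV and LV, as for real HF markers.
  ann$ntprobnp <- ifelse(ann$group == "control", NA,
                         exp(stats::rnorm(n_samp, log(150) +
                                            0.35 * is_rv, 0.6)))
  ann$hstnt <- ifelse(ann$group == "control", NA,
                      exp(stats::rnorm(n_samp, log(4) + 0.25 * is_rv, 0.5)))
  ann$egfr <- ifelse(ann$group == "control", NA,
                     stats::rnorm(n_samp, 105 - 5 * is_rv, 15))

  # Binding sites: every planted pair gets a site, plus decoys on uncoupled
  # pairs (sampled without collision with planted pairs).
  sites <- data.frame(mirna_id = character(0), gene_id = character(0),
                      region = character(0), site_start = integer(0),
                      site_end = integer(0), stringsAsFactors = FALSE)
  mk_sites <- function(mi, ge) {
    st <- sample.int(2000L, length(mi), replace = TRUE)
    data.frame(mirna_id = mi, gene_id = ge, region = "UTR3",
               site_start = st, site_end = st + 7L, stringsAsFactors = FALSE)
  }
  if (n_pairs) sites <- mk_sites(pairs$mirna_id, pairs$mrna_id)
  n_decoy <- round(config$decoy_site_factor * max(n_pairs, 1))
  if (n_decoy > 0) {
    planted_key <- if (n_pairs) paste(pairs$mirna_id, pairs$mrna_id) else character(0)
    got <- 0L; tries <- 0L
    dm <- character(0); dg <- character(0)
    while (got < n_decoy && tries < 50L) {
      mi <- sample(mirna_ids, n_decoy - got, replace = TRUE)
      ge <- sample(mrna_ids, n_decoy - got, replace = TRUE)
      keep <- !(paste(mi, ge) %in% c(planted_key, paste(dm, dg)))
      dm <- c(dm, mi[keep]); dg <- c(dg, ge[keep])
      got <- length(dm); tries <- tries + 1L
    }
    sites <- rbind(sites, mk_sites(dm, dg))
  }

  # Intensity-dependent detection dropout (logistic in log2 intensity,
  # midpoint at the dropout-rate quantile).
  apply_dropout <- function(x) {
    if (config$dropout_rate <= 0)
      return(matrix(TRUE, nrow(x), ncol(x), dimnames = dimnames(x)))
    x0 <- stats::quantile(x, config$dropout_rate, names = FALSE)
    p_drop <- stats::plogis((x0 - x) / 0.7)
    det <- matrix(stats::runif(length(x)) >= p_drop, nrow(x), ncol(x),
                  dimnames = dimnames(x))
    det
  }
  dimnames(mir$log2) <- list(mirna_ids, ann$sample_id)
  dimnames(mrn$log2) <- list(mrna_ids, ann$sample_id)
  det_mi <- apply_dropout(mir$log2)
  det_mr <- apply_dropout(mrn$log2)

  bundle <- list(
    mirna = expr_matrix(2^mir$log2, det_mi, scale = "raw", platform = "miRNA"),
    mrna = expr_matrix(2^mrn$log2, det_mr, scale = "raw", platform = "mRNA"),
    annotation = ann,
    sites = sites,
    truth = list(
      de_mirna = de_mirna,
      de_mrna = de_mrna,
      regulatory_pairs = pairs,
      hf_informative_markers = data.frame(
        feature_id = c(hf_mirna, death_mirna),
        stratum = c("overt_hf", "death"),
        effect_log2fc = config$stratum_effect_log2fc,
        stringsAsFactors = FALSE)),
    config = config)
  class(bundle) <- "sim_bundle"
  bundle
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(paste0("<sim_bundle> %d miRNAs x %d samples; %d mRNAs; ",
                     "%d planted DE miRNAs, %d planted DE mRNAs, %d pairs\n"),
              nrow(x$mirna$values), ncol(x$mirna$values), nrow(x$mrna$values),
              nrow(x$truth$de_mirna), nrow(x$truth$de_mrna),
              if (is.null(x$truth$regulatory_pairs)) 0L
              else nrow(x$truth$regulatory_pairs)))
  invisible(x)
}

#' Write a synthetic bundle to a directory of TSV files
#'
#' Emits `mirna_matrix.tsv`, `mrna_matrix.tsv`, `metadata.tsv`, `sites.tsv`
#' and `ground_truth.tsv`.
#'
#' @param bundle A bundle from [generate_bundle()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(bundle$mirna, file.path(dir, "mirna_matrix.tsv"))
  write_expression_matrix(bundle$mrna, file.path(dir, "mrna_matrix.tsv"))
  write_sample_annotation(bundle$annotation, file.path(dir, "metadata.tsv"))
  write_binding_sites(bundle$sites, file.path(dir, "sites.tsv"))
  gt <- rbind(
    data.frame(kind = "de_mirna", id1 = bundle$truth$de_mirna$feature_id,
               id2 = "", value = bundle$truth$de_mirna$effect_rv),
    data.frame(kind = "de_mrna", id1 = bundle$truth$de_mrna$feature_id,
               id2 = "", value = bundle$truth$de_mrna$effect_rv),
    if (!is.null(bundle$truth$regulatory_pairs))
      data.frame(kind = "pair", id1 = bundle$truth$regulatory_pairs$mirna_id,
                 id2 = bundle$truth$regulatory_pairs$mrna_id,
                 value = bundle$truth$regulatory_pairs$planted_rho))
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a qPCR cycle-threshold table from a bundle
#'
#' Emulates single-assay RT-qPCR on selected miRNAs under the affine model
#' `Ct = a - b * log2(expression) + noise`, together with a group-invariant
#' reference assay (RNU6B-like) used for delta-Ct normalization downstream. A
#' configurable fraction of case-assay Ct values is pushed past the gate to
#' exercise the Ct <= 35 rule.
#'
#' @param bundle A [generate_bundle()] result.
#' @param assays Character vector of miRNA feature ids to assay.
#' @param reference_id Name of the reference assay (must not be a planted
#'   differentially expressed feature; default `"RNU6B"`, synthesized with a
#'   group-invariant mean when absent from the matrix).
#' @param a,b Intercept and slope of the affine Ct model (defaults 36 and 1).
#' @param ct_noise_sd Gaussian Ct noise SD in cycles (default 0.25; set 0 for
#'   exact arithmetic checks).
#' @param gate_fail_frac Fraction of non-reference Ct values forced past the
#'   gate (default 0.05).
#' @param gate Ct gate (default 35).
#' @return Data.frame with columns `sample_id`, `assay_id`, `ct`,
#'   `passes_gate`.
#' @export
generate_ct_table <- function(bundle, assays, reference_id = "RNU6B",
                              a = 36, b = 1, ct_noise_sd = 0.25,
                              gate_fail_frac = 0.05, gate = 35) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (!all(assays %in% rownames(bundle$mirna$values)))
    stop("assays must be miRNA features of the bundle", call. = FALSE)
  if (reference_id %in% bundle$truth$de_mirna$feature_id)
    stop("config error: reference assay must not be a planted DE feature",
         call. = FALSE)
  set.seed((bundle$config$seed + 77003L) %% .Machine$integer.max)
  samples <- colnames(bundle$mirna$values)
  log2_expr <- log2(bundle$mirna$values[assays, samples, drop = FALSE])
  ct <- a - b * log2_expr +
    matrix(stats::rnorm(length(log2_expr), 0, ct_noise_sd),
           nrow(log2_expr), ncol(log2_expr))
  if (reference_id %in% rownames(bundle$mirna$values)) {
    ref_ct <- a - b * log2(bundle$mirna$values[reference_id, samples]) +
      stats::rnorm(length(samples), 0, ct_noise_sd)
  } else {
    ref_expr <- 10 + stats::rnorm(length(samples), 0, ct_noise_sd / max(b, 1e-9))
    ref_ct <- a - b * ref_expr
  }
  tab <- rbind(
    data.frame(sample_id = rep(samples, each = length(assays)),
               assay_id = rep(assays, length(samples)),
               ct = as.vector(ct), stringsAsFactors = FALSE),
    data.frame(sample_id = samples, assay_id = reference_id, ct = ref_ct,
               stringsAsFactors = FALSE))
  if (gate_fail_frac > 0) {
    idx <- which(tab$assay_id != reference_id)
    n_fail <- round(gate_fail_frac * length(idx))
    if (n_fail > 0) {
      pick <- sample(idx, n_fail)
      tab$ct[pick] <- gate + stats::runif(n_fail, 0.5, 3)
    }
  }
  tab$passes_gate <- tab$ct <= gate
  tab
}
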