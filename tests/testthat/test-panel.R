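test_that("AUC handles separation, the worked example, and ties", {
  expect_equal(auc_from_scores(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)
  expect_equal(auc_from_scores(c(3, 1, 2, 4), c(0, 1, 0, 1)), 0.5)
  expect_equal(auc_from_scores(rep(5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc_from_scores(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals exhaustive pair enumeration and satisfies symmetry laws", {
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(4:200, 1)
    scores <- sample(round(rnorm(n), 1))  # ties present
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    a <- auc_from_scores(scores, labels)
    expect_equal(a, oracle_auc(scores, labels), tolerance = 1e-12)
    # complement law and monotone-transform invariance
    expect_equal(auc_from_scores(-scores, labels), 1 - a, tolerance = 1e-12)
    expect_equal(auc_from_scores(exp(scores), labels), a, tolerance = 1e-12)
  }
})

test_that("logistic panels: constant predictor, separating predictor, synergy", {
  labels <- rep(c(0, 1), each = 8)
  const <- suppressWarnings(
    fit_logistic_panel(data.frame(v = rep(1, 16)), labels))
  expect_equal(const$auc, 0.5)

  sep <- fit_logistic_panel(data.frame(v = c(1:8, 101:108)), labels)
  expect_equal(sep$auc, 1)
  expect_true(sep$separated)  # flagged and refitted with a small ridge

  # additive two-variable panel outperforms each single variable
  set.seed(3)
  n <- 60
  lab <- rbinom(n, 1, 0.5)
  v1 <- lab + rnorm(n, 0, 1.5)
  v2 <- lab + rnorm(n, 0, 1.5)
  a1 <- fit_logistic_panel(data.frame(v1), lab)$auc
  a2 <- fit_logistic_panel(data.frame(v2), lab)$auc
  a12 <- fit_logistic_panel(data.frame(v1, v2), lab)$auc
  expect_gt(a12, a1)
  expect_gt(a12, a2)
})

test_that("panel significance: null equals full gives p = 1; planted effects are detected", {
  set.seed(8)
  n <- 31
  lab <- rep(c(0, 1), length.out = n)
  x <- lab * 2 + rnorm(n, 0, 0.8)
  fit <- fit_logistic_panel(data.frame(x), lab)
  expect_equal(panel_significance(fit, fit_null = NULL, mode = "lr"),
               panel_significance(fit))
  expect_lt(panel_significance(fit, mode = "lr"), 0.01)
  expect_lt(panel_significance(fit, mode = "deviance_f"), 0.01)
  # identical nested models: zero deviance difference
  noise <- rnorm(n)
  f1 <- fit_logistic_panel(data.frame(noise), lab)
  expect_equal(panel_significance(f1, f1), 1)
  expect_error(panel_significance(f1, fit_logistic_panel(
    data.frame(noise, x), lab)), "nested")
})

test_that("marker panels rank a planted discriminative miRNA first under BH", {
  b <- generate_bundle(sim_config(n_mirna = 60, n_mrna = 50, seed = 19,
                                  effect_log2fc = 1.5, shared_frac = 0,
                                  n_regulatory_pairs = 0))
  mi <- toy_matrix(log2(b$mirna$values), scale = "log2")
  # RV-specific planted features discriminate TGA_RV from TGA_LV
  tr <- b$truth$de_mirna
  rv_specific <- tr$feature_id[tr$effect_lv == 0][1]
  nulls <- setdiff(rownames(mi$values),
                   c(tr$feature_id,
                     b$truth$hf_informative_markers$feature_id))[1:9]
  res <- evaluate_marker_panels(mi, b$annotation, "ntprobnp",
                                c(rv_specific, nulls))
  expect_identical(res$panel[1], "ntprobnp")
  combo <- res[-1, ]
  best <- combo$panel[which.min(combo$p_adj)]
  expect_identical(best, paste("ntprobnp", rv_specific, sep = " + "))
  expect_gt(combo$auc[combo$panel == best], res$auc[1])
  # marker rows use only TGA samples (controls lack the labs)
  expect_identical(unique(res$n_pos + res$n_neg), 32L)
})

test_that("a pure-noise variable barely moves a large-sample panel AUC", {
  set.seed(44)
  n <- 500
  lab <- rbinom(n, 1, 0.5)
  signal <- lab + rnorm(n, 0, 1)
  noise <- rnorm(n)
  a_sig <- fit_logistic_panel(data.frame(signal), lab)$auc
  a_both <- fit_logistic_panel(data.frame(signal, noise), lab)$auc
  expect_lt(abs(a_both - a_sig), 0.1)
})

test_that("stratum screens find the planted heart-failure miRNA by minimum raw p", {
  # group effects switched off so the stratum shift is the only signal
  b <- generate_bundle(sim_config(n_mirna = 60, n_mrna = 50, seed = 23,
                                  frac_de_mirna = 0, frac_de_mrna = 0,
                                  n_regulatory_pairs = 0,
                                  noise_sd_log2 = 0.2,
                                  stratum_effect_log2fc = 1.0))
  mi <- toy_matrix(log2(b$mirna$values), scale = "log2")
  res <- stratum_screen(mi, b$annotation, "overt_hf")
  planted <- b$truth$hf_informative_markers
  hf_mir <- planted$feature_id[planted$stratum == "overt_hf"]
  expect_identical(res$feature_id[which.min(res$p_raw)], hf_mir)
  expect_identical(unique(res$stratum), "overt_hf")

  # permuting the stratum labels destroys the call
  ann_perm <- b$annotation
  tga <- !is.na(ann_perm$overt_hf)
  set.seed(1)
  ann_perm$overt_hf[tga] <- sample(ann_perm$overt_hf[tga])
  res_p <- suppressWarnings(stratum_screen(mi, ann_perm, "overt_hf"))
  expect_gt(res_p$p_raw[res_p$feature_id == hf_mir], min(res$p_raw))

  ann_empty <- b$annotation
  ann_empty$overt_hf[tga] <- FALSE
  expect_error(suppressWarnings(stratum_screen(mi, ann_empty, "overt_hf")),
               "empty stratum")

  # tiny strata trigger the small-class warning
  b2 <- generate_bundle(sim_config(n_mirna = 20, n_mrna = 20, seed = 2,
                                   frac_de_mirna = 0, frac_de_mrna = 0,
                                   n_regulatory_pairs = 0, n_overt_hf = 2))
  mi2 <- toy_matrix(log2(b2$mirna$values), scale = "log2")
  expect_warning(stratum_screen(mi2, b2$annotation, "overt_hf"),
                 "fewer than 3")
})
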