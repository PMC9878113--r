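small_cfg <- function(...) {
  args <- utils::modifyList(list(n_mirna = 60, n_mrna = 120,
                                 n_regulatory_pairs = 6), list(...))
  do.call(sim_config, args)
}

test_that("identical seeds give bitwise-identical bundles", {
  b1 <- generate_bundle(small_cfg(seed = 11))
  b2 <- generate_bundle(small_cfg(seed = 11))
  expect_identical(b1$mirna$values, b2$mirna$values)
  expect_identical(b1$mrna$values, b2$mrna$values)
  expect_identical(b1$annotation, b2$annotation)
  expect_identical(b1$sites, b2$sites)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_bundle(small_cfg(seed = 12))
  expect_false(identical(b1$mirna$values, b3$mirna$values))
})

test_that("bundle structure matches the three-arm design and ground truth is coherent", {
  cfg <- small_cfg(seed = 3)
  b <- generate_bundle(cfg)
  expect_identical(table(b$annotation$group),
                   table(factor(rep(c("TGA_LV", "TGA_RV", "control"), each = 16))))
  expect_identical(dim(b$mirna$values), c(60L, 48L))
  expect_identical(dim(b$mrna$values), c(120L, 48L))
  # every planted pair has a binding-site row and a negative planted rho
  pr <- b$truth$regulatory_pairs
  expect_true(all(paste(pr$mirna_id, pr$mrna_id) %in%
                    paste(b$sites$mirna_id, b$sites$gene_id)))
  expect_true(all(pr$planted_rho < 0))
  # decoy sites exist beyond the planted ones
  expect_gt(nrow(b$sites), nrow(pr))
  # controls carry no marker labs
  ctrl <- b$annotation$group == "control"
  expect_true(all(is.na(b$annotation$ntprobnp[ctrl])))
  expect_true(all(!is.na(b$annotation$ntprobnp[!ctrl])))
})

test_that("uncoupled bundles show no miRNA-mRNA correlation structure", {
  b <- generate_bundle(small_cfg(seed = 5, n_regulatory_pairs = 0,
                                 frac_de_mirna = 0, frac_de_mrna = 0))
  set.seed(1)
  rho <- replicate(200, {
    mi <- sample(rownames(b$mirna$values), 1)
    mr <- sample(rownames(b$mrna$values), 1)
    spearman_cor(log2(b$mirna$values[mi, ]), log2(b$mrna$values[mr, ]))$rho
  })
  expect_lt(mean(abs(rho)), 0.2)
})

test_that("strong coupling with low noise yields strongly negative planted correlations", {
  b <- generate_bundle(small_cfg(seed = 9, coupling_strength = 0.9,
                                 noise_sd_log2 = 0.1, n_regulatory_pairs = 20,
                                 effect_log2fc = 1.0))
  pr <- b$truth$regulatory_pairs
  rho <- vapply(seq_len(nrow(pr)), function(k)
    spearman_cor(log2(b$mirna$values[pr$mirna_id[k], ]),
                 log2(b$mrna$values[pr$mrna_id[k], ]))$rho, numeric(1))
  expect_gte(mean(rho <= -0.8), 0.9)
})

test_that("planted correlations track the coupling target across noise levels", {
  for (noise in c(1.0, 0.5, 0.1)) {
    b <- generate_bundle(small_cfg(seed = 21, noise_sd_log2 = noise,
                                   n_regulatory_pairs = 20,
                                   effect_log2fc = 1.0))
    pr <- b$truth$regulatory_pairs
    rho <- vapply(seq_len(nrow(pr)), function(k)
      spearman_cor(log2(b$mirna$values[pr$mirna_id[k], ]),
                   log2(b$mrna$values[pr$mrna_id[k], ]))$rho, numeric(1))
    expect_lt(abs(mean(rho) - (-0.7)), 0.12)
  }
})

test_that("detection dropout is enriched in low-intensity cells", {
  b <- generate_bundle(small_cfg(seed = 13, dropout_rate = 0.2))
  x <- log2(b$mirna$values)
  det <- b$mirna$detected
  expect_lt(mean(x[!det]), mean(x[det]))
  expect_gt(mean(!det), 0.05)
  b0 <- generate_bundle(small_cfg(seed = 13, dropout_rate = 0))
  expect_true(all(b0$mirna$detected))
})

test_that("config validation rejects infeasible settings", {
  expect_error(sim_config(coupling_strength = 0.995), "coupling_strength")
  expect_error(sim_config(dropout_rate = 1), "dropout_rate")
  expect_error(sim_config(n_regulatory_pairs = 1e9), "n_regulatory_pairs")
  expect_error(generate_bundle(small_cfg(coupling_strength = 0)),
               "coupling_strength > 0")
})

test_that("noiseless Ct model is an exact affine map of log2 expression", {
  b <- generate_bundle(small_cfg(seed = 2))
  assays <- rownames(b$mirna$values)[1:3]
  ct <- generate_ct_table(b, assays, a = 36, b = 1, ct_noise_sd = 0,
                          gate_fail_frac = 0)
  tgt <- ct[ct$assay_id %in% assays, ]
  expected <- 36 - log2(b$mirna$values[cbind(tgt$assay_id, tgt$sample_id)])
  expect_equal(tgt$ct, unname(expected), tolerance = 1e-12)
  # reference is group-invariant by construction
  ref <- ct[ct$assay_id == "RNU6B", ]
  grp <- b$annotation$group[match(ref$sample_id, b$annotation$sample_id)]
  means <- tapply(ref$ct, grp, mean)
  expect_lt(max(means) - min(means), 1e-9)
})

test_that("Ct table gating fraction and DE-reference guard behave", {
  b <- generate_bundle(small_cfg(seed = 2))
  assays <- rownames(b$mirna$values)[1:5]
  ct <- generate_ct_table(b, assays, gate_fail_frac = 0.2)
  non_ref <- ct[ct$assay_id != "RNU6B", ]
  expect_gt(mean(!non_ref$passes_gate), 0.1)
  expect_identical(ct$passes_gate, ct$ct <= 35)
  de_feature <- b$truth$de_mirna$feature_id[1]
  expect_error(generate_ct_table(b, assays, reference_id = de_feature),
               "reference")
  expect_error(generate_ct_table(b, "not-a-mirna"), "miRNA features")
})

test_that("bundle serialization via write_bundle round-trips the matrices", {
  b <- generate_bundle(small_cfg(seed = 4))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back <- read_expression_matrix(file.path(dir, "mirna_matrix.tsv"), "miRNA")
  expect_identical(back$values, b$mirna$values)
  expect_identical(back$detected, b$mirna$detected)
  ann <- read_sample_annotation(file.path(dir, "metadata.tsv"))
  expect_identical(ann$group, b$annotation$group)
})
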