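test_that("spearman handles monotone, anti-monotone and the worked single-swap example", {
  x <- 1:6
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -(2^x))$rho, -1)
  expect_equal(spearman_cor(x, x^3)$p, 0)
  # n = 5 with one adjacent swap: d^2 sum = 2, rho = 1 - 12/120 = 0.9
  sw <- spearman_cor(c(1, 2, 3, 4, 5), c(1, 2, 3, 5, 4))
  expect_equal(sw$rho, 0.9)
  expect_equal(sw$p, 2 * pt(-0.9 * sqrt(3 / (1 - 0.81)), df = 3),
               tolerance = 1e-12)
  const <- spearman_cor(rep(1, 5), 1:5)
  expect_false(const$evaluable)
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
})

test_that("spearman matches the rank-then-Pearson oracle with and without ties", {
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (rep %% 2 == 0) {      # force ties
      x <- round(x, 1)
      y <- round(y, 1)
    }
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_cor(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
})

make_net_inputs <- function() {
  # 8 samples; miR-up inversely tracks gene-dn, miR-dn inversely tracks gene-up
  s <- paste0("s", 1:8)
  base <- seq(0, 7)
  mirna <- rbind(`miR-up` = 8 + base * 0.5, `miR-dn` = 12 - base * 0.5)
  mrna <- rbind(`gene-dn` = 10 - base * 0.45, `gene-up` = 6 + base * 0.45)
  colnames(mirna) <- s; colnames(mrna) <- s
  de_mi <- data.frame(feature_id = c("miR-up", "miR-dn"),
                      direction = c("Higher", "Lower"))
  de_mr <- data.frame(feature_id = c("gene-dn", "gene-up"),
                      direction = c("Lower", "Higher"))
  sites <- data.frame(mirna_id = c("miR-up", "miR-dn"),
                      gene_id = c("gene-dn", "gene-up"),
                      region = "UTR3", site_start = 1L, site_end = 8L)
  list(mi = toy_matrix(mirna, scale = "log2"),
       mr = toy_matrix(mrna, platform = "mRNA", scale = "log2"),
       de_mi = de_mi, de_mr = de_mr, sites = sites)
}

test_that("network gates: binding site, inverse direction, correlation sign", {
  inp <- make_net_inputs()
  net <- build_network(inp$mi, inp$mr, inp$de_mi, inp$de_mr, inp$sites)
  expect_identical(net$summary$n_edges, 2L)
  expect_true(all(net$edges$rho <= -0.5))
  validate_edges(net$edges, inp$sites)

  # no sites -> no edges regardless of correlations
  empty_sites <- inp$sites[0, ]
  net0 <- build_network(inp$mi, inp$mr, inp$de_mi, inp$de_mr, empty_sites)
  expect_identical(net0$summary$n_edges, 0L)

  # same-direction pair excluded even with perfect anti-correlation and a site
  de_same <- inp$de_mr
  de_same$direction <- c("Higher", "Lower")  # now both pairs same-direction
  net1 <- build_network(inp$mi, inp$mr, inp$de_mi, de_same, inp$sites)
  expect_identical(net1$summary$n_edges, 0L)

  # positive correlation with a site and opposite directions: rejected by
  # default, admitted in permissive mode
  mr2 <- inp$mr
  mr2$values["gene-dn", ] <- 4 + seq(0, 7) * 0.45  # now rises with miR-up
  net2 <- build_network(inp$mi, mr2, inp$de_mi, inp$de_mr, inp$sites)
  expect_identical(nrow(net2$edges[net2$edges$mrna == "gene-dn", ]), 0L)
  net3 <- build_network(inp$mi, mr2, inp$de_mi, inp$de_mr, inp$sites,
                        permissive_sign = TRUE)
  expect_identical(nrow(net3$edges[net3$edges$mrna == "gene-dn", ]), 1L)

  # empty DE list -> empty network, no error
  net4 <- build_network(inp$mi, inp$mr, inp$de_mi[0, ], inp$de_mr, inp$sites)
  expect_identical(net4$summary$n_edges, 0L)

  # probe ids resolve through an explicit probe-to-gene map
  mr_probe <- inp$mr
  rownames(mr_probe$values) <- c("probeA", "probeB")
  rownames(mr_probe$detected) <- c("probeA", "probeB")
  de_probe <- inp$de_mr
  de_probe$feature_id <- c("probeA", "probeB")
  map <- data.frame(probe_id = c("probeA", "probeB"),
                    gene_id = c("gene-dn", "gene-up"))
  net5 <- build_network(inp$mi, mr_probe, inp$de_mi, de_probe, inp$sites,
                        probe_to_gene = map)
  expect_identical(net5$summary$n_edges, 2L)
  expect_setequal(net5$edges$mrna, c("probeA", "probeB"))
  # without the map the probe ids match no site
  net6 <- build_network(inp$mi, mr_probe, inp$de_mi, de_probe, inp$sites)
  expect_identical(net6$summary$n_edges, 0L)
})

test_that("edge sets are invariant to sample and feature ordering, and monotone in rho threshold", {
  inp <- make_net_inputs()
  ref <- build_network(inp$mi, inp$mr, inp$de_mi, inp$de_mr, inp$sites)
  perm_s <- rev(colnames(inp$mi$values))
  mi_p <- subset_expr(inp$mi, samples = perm_s)
  mr_p <- subset_expr(inp$mr, samples = perm_s)
  out <- build_network(mi_p, mr_p, inp$de_mi[2:1, ], inp$de_mr[2:1, ],
                       inp$sites)
  expect_equal(out$edges, ref$edges)

  loose <- build_network(inp$mi, inp$mr, inp$de_mi, inp$de_mr, inp$sites,
                         rho_threshold = 0.2)
  expect_true(all(paste(ref$edges$mirna, ref$edges$mrna) %in%
                    paste(loose$edges$mirna, loose$edges$mrna)))
})

test_that("network summary tallies pattern counts that sum to the edge total", {
  expect_identical(summarize_network(data.frame(
    mirna = character(0), mrna = character(0),
    mirna_direction = character(0), mrna_direction = character(0)))$n_edges,
    0L)
  edges <- data.frame(
    mirna = c("m1", "m1"), mrna = c("g1", "g2"),
    mirna_direction = c("Higher", "Higher"),
    mrna_direction = c("Lower", "Lower"))
  s <- summarize_network(edges)
  expect_identical(s$n_edges, 2L)
  expect_identical(s$n_mirna, 1L)
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    e <- data.frame(
      mirna = sample(paste0("m", 1:5), n, TRUE),
      mrna = sample(paste0("g", 1:8), n, TRUE),
      mirna_direction = sample(c("Lower", "Higher"), n, TRUE))
    e$mrna_direction <- ifelse(e$mirna_direction == "Lower", "Higher", "Lower")
    s <- summarize_network(e)
    expect_identical(s$n_edges_lowmi_highmr + s$n_edges_highmi_lowmr,
                     s$n_edges)
  }
})

test_that("planted regulatory pairs are recovered through the full integration chain", {
  recovered <- 0L; eligible <- 0L; decoy_edges <- 0L; total_edges <- 0L
  for (seed in 1:4) {
    b <- generate_bundle(sim_config(n_mirna = 80, n_mrna = 200, seed = seed,
                                    effect_log2fc = 1.5,
                                    n_regulatory_pairs = 10))
    mi <- toy_matrix(log2(b$mirna$values), scale = "log2")
    mr <- toy_matrix(log2(b$mrna$values), platform = "mRNA", scale = "log2")
    rv <- b$annotation$sample_id[b$annotation$group == "TGA_RV"]
    ctl <- b$annotation$sample_id[b$annotation$group == "control"]
    de_mi <- call_differential(mi, rv, ctl)
    de_mr <- call_differential(mr, rv, ctl)
    net <- build_network(mi, mr, de_mi, de_mr, b$sites)
    validate_edges(net$edges, b$sites)
    pr <- b$truth$regulatory_pairs
    dir_of <- function(de, id) de$direction[match(id, de$feature_id)]
    both_de <- dir_of(de_mi, pr$mirna_id) %in% c("Lower", "Higher") &
      dir_of(de_mr, pr$mrna_id) %in% c("Lower", "Higher")
    key <- paste(pr$mirna_id, pr$mrna_id)
    edge_key <- paste(net$edges$mirna, net$edges$mrna)
    eligible <- eligible + sum(both_de)
    recovered <- recovered + sum(key[both_de] %in% edge_key)
    decoy_edges <- decoy_edges + sum(!edge_key %in% key)
    total_edges <- total_edges + length(edge_key)
  }
  expect_gt(eligible, 0)
  expect_gte(recovered / eligible, 0.8)
  expect_lte(decoy_edges / max(total_edges, 1), 0.05)
})
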