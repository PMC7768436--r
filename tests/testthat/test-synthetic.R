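test_that("proteomics generator is reproducible and honors its spec", {
  spec <- synthetic_spec(n_features = 400, seed = 11)
  g1 <- generate_proteomics(spec)
  g2 <- generate_proteomics(spec)
  expect_identical(abundance_values(g1$matrix), abundance_values(g2$matrix))
  expect_identical(g1$truth, g2$truth)

  expect_equal(nrow(g1$matrix), 400)
  expect_equal(length(sample_ids(g1$matrix)), 19)
  expect_equal(sum(g1$design$group == "poor"), 10)
  expect_equal(sum(g1$design$group == "good"), 9)
  # contaminants are flagged and never affected
  expect_false(any(g1$truth$affected & (g1$truth$bovine | g1$truth$reverse)))

  none <- generate_proteomics(synthetic_spec(n_features = 100,
                                             frac_affected = 0, seed = 3))
  expect_equal(sum(none$truth$affected), 0)
})

test_that("planted effects have the requested empirical size", {
  spec <- synthetic_spec(n_features = 5000, effect_log2 = 1.5,
                         within_group_sd = 0.5, missing_rate = 0, seed = 1)
  g <- generate_proteomics(spec)
  m <- log2(abundance_values(g$matrix))
  good <- g$design$sample_id[g$design$group == "good"]
  poor <- g$design$sample_id[g$design$group == "poor"]
  diff <- rowMeans(m[, good]) - rowMeans(m[, poor])
  aff <- g$truth$affected
  signed <- diff[aff] * sign(g$truth$effect_log2[aff])
  expect_equal(mean(signed), 1.5, tolerance = 0.05 / 1.5)
})

test_that("missingness is intensity-dependent at the configured rate", {
  spec <- synthetic_spec(n_features = 3000, missing_rate = 0.15, seed = 5)
  g <- generate_proteomics(spec)
  m <- abundance_values(g$matrix)
  expect_equal(mean(is.na(m)), 0.15, tolerance = 0.02)
  # dropout concentrates at low intensities: missing rows sit lower
  row_na <- rowMeans(is.na(m))
  row_mu <- rowMeans(log2(m), na.rm = TRUE)
  partial <- row_na > 0.3 & row_na < 1
  expect_lt(mean(row_mu[partial]), mean(row_mu[row_na == 0]))
})

test_that("panel generator builds housekeeping structure correctly", {
  g <- generate_mrna_panel(panel_spec(seed = 7))
  g2 <- generate_mrna_panel(panel_spec(seed = 7))
  expect_identical(abundance_values(g$matrix), abundance_values(g2$matrix))

  expect_equal(nrow(g$matrix), 549)
  expect_equal(length(sample_ids(g$matrix)), 25)
  expect_equal(sum(g$matrix$housekeeping), 15)
  expect_false(any(is.na(abundance_values(g$matrix))))
  # housekeeping genes never carry a planted effect
  expect_false(any(g$truth$affected & g$truth$housekeeping))
  # the constructed low-signal gene sits below the default exclusion threshold
  m <- abundance_values(g$matrix)
  low <- g$truth$feature_id[g$truth$low_signal_hk]
  threshold <- 0.05 * median(apply(m, 2, median))
  expect_lt(median(m[low, ]), threshold)
})

test_that("gene-set generator plants enrichment and decoys behave uniformly", {
  g <- generate_proteomics(synthetic_spec(n_features = 1000,
                                          frac_affected = 0.1, seed = 2))
  universe <- g$matrix$feature_id
  gs <- generate_gene_sets(g$truth, universe, n_decoy_sets = 200,
                           set_size = 20, enrichment_ratio = 0.6, seed = 9)
  gs2 <- generate_gene_sets(g$truth, universe, n_decoy_sets = 200,
                            set_size = 20, enrichment_ratio = 0.6, seed = 9)
  expect_identical(as_tibble_strip(gs), as_tibble_strip(gs2))

  affected <- g$truth$feature_id[g$truth$affected]
  planted_overlap <- length(intersect(gs$genes[[1]], affected))
  expect_gt(planted_overlap, 20 * length(affected) / length(universe))
  # decoy overlap with the affected features matches the uniform expectation
  decoy_overlap <- vapply(gs$genes[-1],
                          function(s) length(intersect(s, affected)), 0L)
  expected <- 20 * length(affected) / length(universe)
  expect_equal(mean(decoy_overlap), expected, tolerance = 0.25)
  # out-of-universe symbols present to exercise pruning
  expect_true(any(!gs$genes[[2]] %in% universe))
})

test_that("network generator wires a connected cluster and isolates the rest", {
  seeds <- sprintf("SEED%02d", 1:10)
  net <- generate_network(seeds, n_background = 50, seed = 4)
  net2 <- generate_network(seeds, n_background = 50, seed = 4)
  expect_identical(as.data.frame(net), as.data.frame(net2))

  cl <- attr(net, "cluster_seeds")
  iso <- attr(net, "isolated_seeds")
  sub <- direct_subnetwork(cl, net)
  expect_setequal(sub$members$node, cl)
  expect_equal(length(unique(sub$members$component)), 1)
  # isolated seeds have no edge to any other seed
  seed_edges <- net[net$from %in% seeds & net$to %in% seeds, ]
  expect_false(any(iso %in% c(seed_edges$from, seed_edges$to)))
})
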