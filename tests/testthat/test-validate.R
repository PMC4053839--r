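test_that("a site carries every state it shows in any cell type", {
  sites <- data.frame(site_id = c("a", "b"), chrom = "chr1",
                      pos = c(100L, 900L), stringsAsFactors = FALSE)
  ann <- data.frame(chrom = "chr1", start = c(50L, 50L, 850L),
                    end = c(150L, 150L, 950L),
                    label = c("state4", "state1", "state2"),
                    cell_type = c("c1", "c2", "c1"),
                    stringsAsFactors = FALSE)
  sets <- list(real = c("a", "b"), shuffled = list(c("b"), character(0)))
  res <- chromatin_state_enrichment(sets, sites, ann)
  expect_equal(res$real_count[res$category == "state4"], 1)
  expect_equal(res$real_count[res$category == "state1"], 1)  # same site
  expect_equal(res$real_count[res$category == "state2"], 1)
  # never-observed-in-shuffles state has fold NA
  expect_true(is.na(res$fold[res$category == "state4"]))
})

test_that("planted state4 enrichment has the top fold among states", {
  sim <- generate_panel(panel_config(n_cell_types = 25L, n_genes = 50L,
                                     n_background_sites = 500L,
                                     enhancer_pair_rho = -0.9, noise_sd = 5,
                                     chrom_length = 5e6, seed = 44))
  ann <- generate_annotations(sim, seed = 3, enrichment_odds = 10)
  vms <- select_vms(sim$meth)$panel
  pairs <- enumerate_candidate_pairs(sim$genes, vms)
  sets <- shuffled_high_sites(published_model(), pairs, vms, sim$expr,
                              sim$genes, threshold = 0.9, n_shuffles = 6L,
                              seed = 5)
  res <- chromatin_state_enrichment(sets, vms$sites, ann$states)
  res <- res[!is.na(res$fold), ]
  expect_equal(res$category[which.max(res$fold)], "state4")
  expect_lt(res$p_value[res$category == "state4"], 0.05)
})

test_that("TF binding is higher at unmethylated high-scoring sites", {
  sim <- generate_panel(panel_config(n_cell_types = 25L, n_genes = 50L,
                                     n_background_sites = 500L,
                                     enhancer_pair_rho = -0.9, noise_sd = 5,
                                     chrom_length = 5e6, seed = 44))
  ann <- generate_annotations(sim, seed = 3, tf_max_mean = 10)
  vms <- select_vms(sim$meth)$panel
  pairs <- enumerate_candidate_pairs(sim$genes, vms)
  sets <- shuffled_high_sites(published_model(), pairs, vms, sim$expr,
                              sim$genes, threshold = 0.85, n_shuffles = 6L,
                              seed = 5)
  site_meth <- setNames(rowMeans(vms$values, na.rm = TRUE),
                        vms$sites$site_id)
  res <- tf_binding_comparison(sets, vms$sites, ann$tf_peaks, site_meth,
                               unmeth_cut = 45, meth_cut = 55)
  expect_gt(res$group_means[["unmethylated"]],
            res$group_means[["methylated"]])
  expect_lt(res$wilcoxon_p, 0.05)
  expect_error(
    tf_binding_comparison(sets, vms$sites, ann$tf_peaks, site_meth,
                          unmeth_cut = -1, meth_cut = 55),
    "no unmethylated")
})

test_that("distinct factors are counted once per site", {
  sites <- data.frame(site_id = "a", chrom = "chr1", pos = 100L,
                      stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = c(50L, 90L, 95L),
                      end = c(150L, 120L, 130L),
                      label = c("TF1", "TF1", "TF2"), cell_type = "c1",
                      stringsAsFactors = FALSE)
  expect_equal(unname(methpair:::tf_counts_per_site(sites, peaks)), 2)
})

test_that("5C agreement degenerates and scales as expected", {
  rec <- data.frame(site_id = "e1", gene_id = letters[1:4],
                    reads = rep(7, 4), predicted = c(TRUE, FALSE, FALSE,
                                                     FALSE),
                    score = c(0.9, 0.9, 0.1, 0.1))
  expect_message(res <- fivec_agreement(rec), "skipped")
  expect_equal(res$agree_fraction_high, 0)  # strict > mean
  expect_equal(res$agree_fraction_low, 0)

  # exact Wilcoxon oracle: {300, 310} vs {85, 90, 95} -> p = 2/choose(5,2)
  rec2 <- data.frame(site_id = "e1", gene_id = letters[1:5],
                     reads = c(300, 310, 90, 85, 95),
                     predicted = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                     score = c(0.9, 0.9, 0.2, 0.2, 0.2))
  res2 <- suppressMessages(fivec_agreement(rec2))
  expect_equal(res2$predicted_vs_other_p, 2 / choose(5, 2))

  # invariance to rescaling all reads
  rec3 <- rec2; rec3$reads <- rec3$reads * 7
  res3 <- suppressMessages(fivec_agreement(rec3))
  expect_equal(res3$agree_fraction_high, res2$agree_fraction_high)
  expect_equal(res3$predicted_vs_other_p, res2$predicted_vs_other_p)
})

test_that("planted 5C signal separates high- from low-score strata", {
  sim <- generate_panel(panel_config(n_cell_types = 12L, n_genes = 100L,
                                     n_enhancer_pairs = 300L,
                                     n_background_sites = 10L, seed = 19))
  ann <- generate_annotations(sim, seed = 2, fivec_ratio = 3)
  # score of each record's (gene, enhancer) pair: true pairs high
  truth_key <- pair_key(sim$truth$true_enhancer_pairs$gene_id,
                        sim$truth$true_enhancer_pairs$site_id)
  rec <- ann$fivec
  rec$score <- ifelse(pair_key(rec$gene_id, rec$site_id) %in% truth_key,
                      0.95, 0.3)
  res <- fivec_agreement(rec, high_threshold = 0.85)
  expect_gt(res$agree_fraction_high, res$agree_fraction_low)
  expect_lt(res$binomial_p, 0.01)
  expect_lt(res$predicted_vs_other_p, 1e-6)
})

test_that("replication test recovers planted pairs and is seeded", {
  sim <- generate_panel(panel_config(n_cell_types = 25L, n_genes = 60L,
                                     n_background_sites = 200L,
                                     enhancer_pair_rho = -0.9,
                                     noise_sd = 5, seed = 55))
  # an independent panel generated with the same truth structure:
  # same genes/sites, new noise -> same seed family, different draw
  sim2 <- generate_panel(panel_config(n_cell_types = 25L, n_genes = 60L,
                                      n_background_sites = 200L,
                                      enhancer_pair_rho = -0.9,
                                      noise_sd = 5, seed = 55))
  prior <- sim$truth$true_enhancer_pairs[, c("gene_id", "site_id")]
  res <- replication_test(prior, published_model(), sim2$meth, sim2$expr,
                          threshold = 0.9, n_null = 100L, seed = 4)
  expect_gt(res$observed, res$expected_mean)
  expect_lt(res$p_two_sided, 0.05)
  res2 <- replication_test(prior, published_model(), sim2$meth, sim2$expr,
                           threshold = 0.9, n_null = 100L, seed = 4)
  expect_identical(res[c("observed", "expected_mean", "expected_sd")],
                   res2[c("observed", "expected_mean", "expected_sd")])
  expect_error(replication_test(prior[1:5, ], published_model(),
                                sim2$meth, sim2$expr), "fewer than 10")
})
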