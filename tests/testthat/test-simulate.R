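test_that("the generator is reproducible and respects type invariants", {
  cfg <- panel_config(n_cell_types = 12L, n_genes = 25L,
                      n_background_sites = 100L, seed = 31)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$meth$values, b$meth$values)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)
  v <- a$meth$values
  expect_true(all(is.na(v) | (v >= 0 & v <= 100)))
  expect_true(all(is.finite(a$expr)))
  expect_true(all(a$truth$true_promoter_pairs$site_id %in%
                    a$meth$sites$site_id))
  expect_true(all(a$truth$true_enhancer_pairs$gene_id %in%
                    a$genes$gene_id))
  expect_error(panel_config(n_cell_types = 5), "n_cell_types")
  expect_error(panel_config(promoter_pair_rho = 0.5), "rho")
})

test_that("promoter and enhancer sites land in their genomic windows", {
  sim <- generate_panel(panel_config(n_cell_types = 12L, n_genes = 40L,
                                     n_background_sites = 50L, seed = 8))
  g <- sim$genes
  pp <- sim$truth$true_promoter_pairs
  gi <- match(pp$gene_id, g$gene_id)
  si <- match(pp$site_id, sim$meth$sites$site_id)
  d <- (sim$meth$sites$pos[si] - g$tss[gi]) * ifelse(g$strand[gi] == "+",
                                                     1, -1)
  expect_true(all(d >= -500 & d <= 2000))
  ep <- sim$truth$true_enhancer_pairs
  gi <- match(ep$gene_id, g$gene_id)
  si <- match(ep$site_id, sim$meth$sites$site_id)
  expect_true(all(sim$meth$sites$chrom[si] == g$chrom[gi]))
  dd <- abs(sim$meth$sites$pos[si] - g$tss[gi])
  expect_true(all(dd >= 1e4 & dd <= 1e6))
})

test_that("the noiseless rho = -1 limit gives exact Pearson -1", {
  sim <- generate_panel(panel_config(n_cell_types = 15L, n_genes = 20L,
                                     n_background_sites = 10L,
                                     promoter_pair_rho = -1, noise_sd = 0,
                                     missing_rate = 0, seed = 2))
  pp <- sim$truth$true_promoter_pairs
  for (i in seq_len(nrow(pp))) {
    m <- sim$meth$values[pp$site_id[i], ]
    e <- sim$expr[pp$gene_id[i], ]
    expect_equal(cor(m, e), -1, tolerance = 1e-12)
  }
})

test_that("realized pair correlations hit the configured rho", {
  sim <- generate_panel(panel_config(n_cell_types = 50L, n_genes = 200L,
                                     n_background_sites = 100L,
                                     promoter_pair_rho = -0.8, seed = 17))
  pp <- sim$truth$true_promoter_pairs
  r <- vapply(seq_len(nrow(pp)), function(i)
    cor(sim$meth$values[pp$site_id[i], ], sim$expr[pp$gene_id[i], ],
        use = "pairwise.complete.obs"), numeric(1))
  expect_equal(mean(r), -0.8, tolerance = 0.05)
  # background sites carry no expression relationship
  bg <- sample(sim$truth$background_sites, 50)
  rb <- vapply(seq_along(bg), function(i)
    cor(sim$meth$values[bg[i], ], sim$expr[i, ],
        use = "pairwise.complete.obs"), numeric(1))
  expect_lt(abs(mean(rb)), 0.1)
})

test_that("cancer drift is the identity at strength 0 and bends extremes in", {
  sim <- generate_panel(panel_config(n_cell_types = 12L, n_genes = 30L,
                                     n_background_sites = 100L, seed = 4))
  null <- generate_cancer_pair(sim, cancer_config(drift_strength = 0,
                                                  n_hypo_enhancers = 0L,
                                                  n_hyper_enhancers = 0L))
  expect_identical(null$cancer$meth$values, sim$meth$values)
  expect_identical(null$cancer$expr, sim$expr)
  # unmethylated sites gain, methylated sites lose
  expect_equal(cancer_drift(0, 0.6), 30)
  expect_equal(cancer_drift(100, 0.6), 70)
  expect_equal(cancer_drift(50, 0.6), 50)
  cp <- generate_cancer_pair(sim, cancer_config(drift_strength = 0.6,
                                                n_hypo_enhancers = 0L,
                                                n_hyper_enhancers = 0L))
  low <- !is.na(sim$meth$values) & sim$meth$values < 50
  expect_true(all(cp$cancer$meth$values[low] > sim$meth$values[low]))
  high <- !is.na(sim$meth$values) & sim$meth$values > 50
  expect_true(all(cp$cancer$meth$values[high] < sim$meth$values[high]))
})

test_that("targeted enhancers couple methylation loss to expression gain", {
  sim <- generate_panel(panel_config(n_cell_types = 12L, n_genes = 30L,
                                     n_background_sites = 50L, seed = 6))
  cp <- generate_cancer_pair(sim, cancer_config(
    drift_strength = 0, n_hypo_enhancers = 5L, n_hyper_enhancers = 0L,
    enhancer_effect = 2, targeted_delta = 50, expr_noise_sd = 0, seed = 3))
  expect_equal(cp$targets$d_expr, -2 * cp$targets$d_meth / 100)
  expect_true(all(cp$targets$d_meth < 0))
  for (k in seq_len(nrow(cp$targets))) {
    g <- cp$targets$gene_id[k]
    expect_equal(unname(cp$cancer$expr[g, ] - cp$normal$expr[g, ]),
                 rep(cp$targets$d_expr[k], ncol(sim$expr)))
  }
  expect_error(generate_cancer_pair(sim, cancer_config(
    n_hypo_enhancers = 100L, n_hyper_enhancers = 0L)), "exceeds")
})

test_that("annotation generator plants state4 enrichment only when asked", {
  sim <- generate_panel(panel_config(n_cell_types = 12L, n_genes = 100L,
                                     n_background_sites = 800L, seed = 12))
  is_enh <- sim$meth$sites$site_id %in%
    sim$truth$true_enhancer_pairs$site_id
  f4 <- function(ann, ids) {
    covered <- ann$states$label == "state4"
    key <- paste(ann$states$chrom, ann$states$start)
    site_key <- paste(sim$meth$sites$chrom, sim$meth$sites$pos)
    hit <- site_key %in% key[covered]
    mean(hit[match(ids, sim$meth$sites$site_id)])
  }
  enh_ids <- sim$meth$sites$site_id[is_enh]
  bg_ids <- sim$meth$sites$site_id[!is_enh]
  null_ann <- generate_annotations(sim, seed = 5, enrichment_odds = 1)
  expect_lt(abs(f4(null_ann, enh_ids) - f4(null_ann, bg_ids)), 0.12)
  rich_ann <- generate_annotations(sim, seed = 5, enrichment_odds = 10)
  expect_gt(f4(rich_ann, enh_ids), f4(rich_ann, bg_ids) + 0.2)
})

test_that("5C reads of true pairs exceed non-pairs by the configured ratio", {
  sim <- generate_panel(panel_config(n_cell_types = 12L, n_genes = 120L,
                                     n_enhancer_pairs = 1000L,
                                     n_background_sites = 10L, seed = 19))
  ann <- generate_annotations(sim, seed = 2, fivec_ratio = 3,
                              fivec_false_mean = 90)
  ratio <- mean(ann$fivec$reads[ann$fivec$predicted]) /
    mean(ann$fivec$reads[!ann$fivec$predicted])
  expect_equal(ratio, 3, tolerance = 0.1)
})
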