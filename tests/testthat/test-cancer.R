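test_that("delta table of identical panels is identically zero", {
  sim <- generate_panel(panel_config(n_cell_types = 12L, n_genes = 20L,
                                     n_background_sites = 50L, seed = 3))
  panel <- list(meth = sim$meth, expr = sim$expr)
  pairs <- sim$truth$true_enhancer_pairs[, c("gene_id", "site_id")]
  tab <- delta_table(panel, panel, pairs, sim$genes)
  expect_true(all(tab$d_meth == 0))
  expect_true(all(tab$d_expr == 0))
  expect_setequal(unique(tab$class),
                  c("enhancer", "promoter_of_enhancer_gene",
                    "all_promoters"))
})

test_that("a 0%-to-100% site reports d_meth = +100", {
  norm <- toy_panel(matrix(0, 1, 10), pos = 1e6L)
  canc <- toy_panel(matrix(100, 1, 10), pos = 1e6L)
  genes <- gene_models(data.frame(gene_id = "g1", chrom = "chr1",
                                  strand = "+", tss = 1.001e6,
                                  tes = 1.05e6, stringsAsFactors = FALSE))
  e <- matrix(5, 1, 10, dimnames = list("g1", colnames(norm$values)))
  tab <- delta_table(list(meth = norm, expr = e),
                     list(meth = canc, expr = e),
                     data.frame(gene_id = "g1", site_id = "s001"),
                     genes, classes = "enhancer")
  expect_equal(tab$d_meth, 100)
  expect_equal(tab$d_expr, 0)
})

test_that("delta correlation recovers an exact linear relationship", {
  tab <- data.frame(class = "enhancer", d_meth = seq(-80, 80, by = 10))
  tab$d_expr <- -0.02 * tab$d_meth
  res <- delta_correlation(tab, "enhancer")
  expect_equal(res$pearson_r, -1)
  expect_equal(res$slope, -0.02)
  expect_equal(res$intercept, 0)
  flat <- data.frame(class = "x", d_meth = rep(1, 5), d_expr = rnorm(5))
  expect_error(delta_correlation(flat), "zero variance")
})

test_that("quadrant z test matches the pooled two-proportion formula", {
  mk <- function(k, n) data.frame(
    d_meth = c(rep(-30, k), rep(0, n - k)),
    d_expr = c(rep(0.5, k), rep(0, n - k)))
  same <- quadrant_proportion_test(mk(40, 100), mk(40, 100))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  res <- quadrant_proportion_test(mk(40, 100), mk(10, 100))
  p1 <- 0.4; p2 <- 0.1; pp <- 50 / 200
  z_hand <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  expect_equal(res$z, z_hand)
  expect_equal(res$p_value, 2 * pnorm(-abs(z_hand)))

  expect_error(quadrant_proportion_test(mk(0, 10), mk(0, 10),
                                        d_meth_cut = 99, d_expr_cut = 99),
               "no rows")
})

test_that("gene-set overlap p-values behave at both extremes", {
  disj <- list(paste0("g", 1:50), paste0("g", 51:100))
  res <- geneset_overlap_pvalue(disj, universe_size = 1000, n_null = 500,
                                seed = 2)
  expect_equal(res$observed_overlap, 0)
  expect_gt(res$p, 0.5)
  same <- list(paste0("g", 1:20), paste0("g", 1:20))
  res2 <- geneset_overlap_pvalue(same, universe_size = 1000, n_null = 500,
                                 seed = 2)
  expect_equal(res2$observed_overlap, 20)
  expect_equal(res2$p, 1 / 501)
  # hypergeometric mean k1 k2 / N
  res3 <- geneset_overlap_pvalue(list(paste0("g", 1:100),
                                      paste0("g", 1:100)),
                                 universe_size = 1000, n_null = 2000,
                                 seed = 5)
  expect_equal(res3$expected, 10, tolerance = 0.15)
  expect_error(geneset_overlap_pvalue(same, universe_size = 10), "larger")
})

test_that("shift curves are flat at identity and match the drift closed form", {
  sim <- generate_panel(panel_config(n_cell_types = 15L, n_genes = 40L,
                                     n_background_sites = 400L, seed = 21))
  flat <- methylation_shift_curve(sim$meth, sim$meth)
  expect_true(all(flat$mean_shift == 0))

  cp <- generate_cancer_pair(sim, cancer_config(drift_strength = 0.6,
                                                n_hypo_enhancers = 0L,
                                                n_hyper_enhancers = 0L))
  curve <- methylation_shift_curve(cp$normal$meth, cp$cancer$meth)
  # per-site shift is exactly 0.6 * (50 - m), so each bin mean matches
  expect_equal(curve$mean_shift, 0.6 * (50 - curve$mean_normal),
               tolerance = 1e-10)
  # mass balance: count-weighted bin means equal the overall mean shift
  overall <- mean(rowMeans(cp$cancer$meth$values, na.rm = TRUE) -
                    rowMeans(cp$normal$meth$values, na.rm = TRUE))
  expect_equal(sum(curve$mean_shift * curve$n_sites) / sum(curve$n_sites),
               overall, tolerance = 1e-10)
})

test_that("targeted enhancers depart from the global drift curve", {
  sim <- generate_panel(panel_config(n_cell_types = 15L, n_genes = 100L,
                                     n_background_sites = 500L, seed = 33))
  cp <- generate_cancer_pair(sim, cancer_config(drift_strength = 0.4,
                                                n_hypo_enhancers = 50L,
                                                n_hyper_enhancers = 0L,
                                                seed = 7))
  masks <- list(all = rep(TRUE, nrow(sim$meth$values)),
                targeted = cp$targets$site_id)
  curves <- methylation_shift_curve(cp$normal$meth, cp$cancer$meth, masks)
  tgt <- curves[curves$class == "targeted", ]
  # hypomethylated targets sit below the global drift at every bin
  expect_true(all(tgt$mean_shift < 0.4 * (50 - tgt$mean_normal)))
})

test_that("regression on targeted enhancers recovers the planted effect", {
  sim <- generate_panel(panel_config(n_cell_types = 20L, n_genes = 220L,
                                     n_enhancer_pairs = 220L,
                                     n_background_sites = 50L, seed = 61))
  cp <- generate_cancer_pair(sim, cancer_config(drift_strength = 0,
                                                n_hypo_enhancers = 100L,
                                                n_hyper_enhancers = 100L,
                                                enhancer_effect = 2,
                                                expr_noise_sd = 0.2,
                                                seed = 5))
  tab <- delta_table(cp$normal, cp$cancer,
                     cp$targets[, c("gene_id", "site_id")], sim$genes,
                     classes = "enhancer")
  res <- delta_correlation(tab, "enhancer")
  expect_equal(res$slope, -0.02, tolerance = 0.15)
  expect_lt(res$pearson_r, -0.8)
})
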