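# Synthetic panel generator. Emulates the statistical structure the pairing
# analysis assumes: a panel of dozens of cell types; promoter CpGs whose
# methylation falls monotonically with their gene's expression; distal
# enhancer CpGs with graded (not binary) methylation tracking expression
# gradients; uncorrelated variable background CpGs; per-cell missingness and
# RRBS read-depth structure; and a paired normal/cancer panel with a global
# drift of methylation plus targeted enhancer hypo/hyper-methylation coupled
# to expression change.

#' Configuration for the synthetic panel generator
#'
#' Defaults mirror the study conditions of the analysis the package
#' implements: 52 cell types (an RRBS-scale panel), promoter and enhancer
#' methylation anti-correlated with expression at rho = -0.8, 10 percent
#' points of measurement noise, 5% missing cells, and negative-binomial RRBS
#' read depths averaging 30x.
#'
#' @param n_cell_types number of cell types (>= 10; correlations need
#'   support).
#' @param n_genes number of genes, one true promoter CpG each.
#' @param n_enhancer_pairs number of true distal enhancer pairs (genes
#'   sampled without replacement if <= `n_genes`, else with replacement).
#' @param n_background_sites variable CpGs uncorrelated with any gene.
#' @param promoter_pair_rho,enhancer_pair_rho target Pearson correlation
#'   between methylation and expression for true pairs, in \[-1, 0\].
#' @param noise_sd Gaussian measurement noise on methylation, percent
#'   points. Signal amplitude is calibrated against this noise so that the
#'   realized correlation approximates the configured rho.
#' @param bg_sd cell-to-cell spread of background sites, percent points
#'   (must exceed the VMS threshold for backgrounds to act as decoys).
#' @param missing_rate per-(site, cell) probability of a missing value.
#' @param rrbs_mean_depth,rrbs_size negative-binomial mean and size for
#'   read coverage.
#' @param chrom_count,chrom_length number and length (bp) of chromosomes.
#' @param expr_mean_range,expr_sd_range ranges for per-gene expression mean
#'   and cell-to-cell SD (log2 RMA-like units).
#' @param seed RNG seed; identical seeds give byte-identical panels.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_cell_types = 52L, n_genes = 200L,
                         n_enhancer_pairs = n_genes,
                         n_background_sites = 2000L,
                         promoter_pair_rho = -0.8,
                         enhancer_pair_rho = -0.8,
                         noise_sd = 10, bg_sd = 15,
                         missing_rate = 0.05,
                         rrbs_mean_depth = 30, rrbs_size = 5,
                         chrom_count = 10L, chrom_length = 40e6,
                         expr_mean_range = c(4, 12),
                         expr_sd_range = c(0.8, 2),
                         seed = 1L) {
  cfg <- list(n_cell_types = as.integer(n_cell_types),
              n_genes = as.integer(n_genes),
              n_enhancer_pairs = as.integer(n_enhancer_pairs),
              n_background_sites = as.integer(n_background_sites),
              promoter_pair_rho = promoter_pair_rho,
              enhancer_pair_rho = enhancer_pair_rho,
              noise_sd = noise_sd, bg_sd = bg_sd,
              missing_rate = missing_rate,
              rrbs_mean_depth = rrbs_mean_depth, rrbs_size = rrbs_size,
              chrom_count = as.integer(chrom_count),
              chrom_length = chrom_length,
              expr_mean_range = expr_mean_range,
              expr_sd_range = expr_sd_range,
              seed = as.integer(seed))
  if (cfg$n_cell_types < 10L)
    stop("n_cell_types must be >= 10")
  if (promoter_pair_rho < -1 || promoter_pair_rho > 0 ||
      enhancer_pair_rho < -1 || enhancer_pair_rho > 0)
    stop("pair rho must lie in [-1, 0]")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  if (noise_sd < 0 || rrbs_mean_depth <= 0)
    stop("noise_sd must be >= 0 and rrbs_mean_depth > 0")
  if (chrom_length < 2.5e6)
    stop("chromosomes too short to place a gene with a 1 Mb flank")
  class(cfg) <- "panel_config"
  cfg
}

# Anti-monotone methylation signal for one gene across cells.
# Linear map of standardized expression, amplitude a calibrated so that
# cor(signal + noise, expr) ~= rho for noise sd sigma:
#   |rho| = a / sqrt(a^2 + sigma^2)  =>  a = sigma * |rho| / sqrt(1 - rho^2).
# Amplitude is capped so values stay inside [0, 100] before noise; when the
# cap binds (or sigma = 0 with |rho| < 1) the noise is rescaled to a/k to
# preserve the target correlation. rho = -1 forces zero noise.
anti_monotone_meth <- function(expr, rho, noise_sd, center = 50) {
  z <- as.numeric(scale(expr))
  if (any(!is.finite(z))) z <- rep(0, length(expr))  # constant expression
  cap <- (min(center, 100 - center) - 5) / max(abs(z), 1e-9)
  if (rho == 0) {
    a <- 0; sd_n <- noise_sd
  } else if (rho <= -1) {
    a <- cap; sd_n <- 0
  } else {
    k <- abs(rho) / sqrt(1 - rho^2)
    a <- min(noise_sd * k, cap)
    if (a <= 0) a <- cap
    sd_n <- a / k
  }
  m <- center - a * z + stats::rnorm(length(z), 0, sd_n)
  pmin(pmax(m, 0), 100)
}

#' Generate a synthetic methylation/expression panel with known truth
#'
#' Builds a [meth_panel()], an expression matrix, gene models and a truth
#' table. True promoter CpGs sit in \[-500, +2000\] of their gene's TSS
#' (strand-aware) and true enhancer CpGs 10 kb to 1 Mb away on the same
#' chromosome; both carry methylation that is an anti-monotone linear
#' transform of the gene's expression plus Gaussian noise, calibrated to
#' the configured correlation. Background CpGs vary across cells
#' independently of all expression.
#'
#' @param config a [panel_config()].
#' @return List with elements `meth` ([meth_panel()]), `expr` (genes x
#'   cells matrix), `genes` ([gene_models()] data.frame), `truth` (list:
#'   `true_promoter_pairs`, `true_enhancer_pairs`, `background_sites`) and
#'   `config`.
#' @export
generate_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  C <- config$n_cell_types
  G <- config$n_genes
  cells <- sprintf("cell%02d", seq_len(C))
  chroms <- sprintf("chr%d", seq_len(config$chrom_count))

  gene_id <- sprintf("gene%04d", seq_len(G))
  chrom <- chroms[((seq_len(G) - 1L) %% config$chrom_count) + 1L]
  strand <- sample(c("+", "-"), G, replace = TRUE)
  lo <- 1.2e6; hi <- config$chrom_length - 1.2e6
  if (hi <= lo) stop("chromosome too small for requested placement")
  start <- floor(stats::runif(G, lo, hi))
  len <- floor(stats::runif(G, 2e3, 2e5))
  tss <- ifelse(strand == "+", start, start + len)
  tes <- ifelse(strand == "+", start + len, start)
  alt <- lapply(seq_len(G), function(i) {
    if (stats::runif(1) < 0.3)
      as.integer(tss[i] + sample(c(-1, 1), 1) * sample(10e3:80e3, 1))
    else integer(0)
  })
  genes <- gene_models(data.frame(gene_id = gene_id, chrom = chrom,
                                  strand = strand,
                                  tss = as.integer(tss),
                                  tes = as.integer(tes),
                                  stringsAsFactors = FALSE) |>
                         transform(alt_promoters = I(alt)))

  mu <- stats::runif(G, config$expr_mean_range[1], config$expr_mean_range[2])
  sdv <- stats::runif(G, config$expr_sd_range[1], config$expr_sd_range[2])
  expr <- t(vapply(seq_len(G),
                   function(i) mu[i] + stats::rnorm(C, 0, sdv[i]),
                   numeric(C)))
  dimnames(expr) <- list(gene_id, cells)

  # promoter CpGs, strand-aware window [-500, +2000] of the TSS
  prom_off <- sample(-500:2000, G, replace = TRUE)
  prom_pos <- as.integer(ifelse(strand == "+", tss + prom_off,
                                tss - prom_off))
  # baseline methylation varies by site (some regulatory CpGs sit low,
  # some high), bounded away from the scale limits so the anti-monotone
  # gradient has room
  prom_center <- stats::runif(G, 35, 65)
  prom_meth <- t(vapply(seq_len(G), function(i)
    anti_monotone_meth(expr[i, ], config$promoter_pair_rho, config$noise_sd,
                       prom_center[i]),
    numeric(C)))

  # distal enhancer CpGs, 10 kb - 1 Mb from the TSS, same chromosome
  nE <- config$n_enhancer_pairs
  enh_gene <- if (nE <= G) sample.int(G, nE) else
    sample.int(G, nE, replace = TRUE)
  enh_off <- sample(c(-1, 1), nE, replace = TRUE) *
    floor(stats::runif(nE, 1e4, 1e6))
  enh_pos <- as.integer(pmin(pmax(tss[enh_gene] + enh_off, 0),
                             config$chrom_length - 1))
  enh_center <- stats::runif(nE, 35, 65)
  enh_meth <- t(vapply(seq_len(nE), function(i)
    anti_monotone_meth(expr[enh_gene[i], ], config$enhancer_pair_rho,
                       config$noise_sd, enh_center[i]),
    numeric(C)))

  # variable background CpGs independent of all expression
  nB <- config$n_background_sites
  bg_chrom <- sample(chroms, nB, replace = TRUE)
  bg_pos <- as.integer(floor(stats::runif(nB, 0, config$chrom_length)))
  bg_mean <- stats::runif(nB, 5, 95)
  bg_meth <- matrix(pmin(pmax(
    bg_mean + stats::rnorm(nB * C, 0, config$bg_sd), 0), 100),
    nrow = nB, ncol = C)

  sites <- data.frame(
    site_id = c(sprintf("prom%04d", seq_len(G)),
                sprintf("enh%04d", seq_len(nE)),
                sprintf("bg%05d", seq_len(nB))),
    chrom = c(chrom, chrom[enh_gene], bg_chrom),
    pos = c(prom_pos, enh_pos, bg_pos),
    stringsAsFactors = FALSE)
  vals <- rbind(prom_meth, enh_meth, bg_meth)
  rownames(vals) <- sites$site_id
  colnames(vals) <- cells

  if (config$missing_rate > 0) {
    drop <- stats::runif(length(vals)) < config$missing_rate
    vals[drop] <- NA_real_
  }
  coverage <- matrix(stats::rnbinom(length(vals), mu = config$rrbs_mean_depth,
                                    size = config$rrbs_size),
                     nrow = nrow(vals), dimnames = dimnames(vals))

  truth <- list(
    true_promoter_pairs = data.frame(gene_id = gene_id,
                                     site_id = sites$site_id[seq_len(G)],
                                     stringsAsFactors = FALSE),
    true_enhancer_pairs = data.frame(
      gene_id = gene_id[enh_gene],
      site_id = sites$site_id[G + seq_len(nE)],
      correlation_strength = rep(config$enhancer_pair_rho, nE),
      stringsAsFactors = FALSE),
    background_sites = sites$site_id[G + nE + seq_len(nB)])

  list(meth = meth_panel(sites, vals, coverage), expr = expr,
       genes = genes, truth = truth, config = config)
}

#' Configuration for the paired normal/cancer generator
#'
#' @param drift_strength in \[0, 1\]: strength of the global methylation
#'   drift in cancer. The drift is the deterministic map
#'   `m -> m + drift_strength * (50 - m)`: sites unmethylated in the normal
#'   cells gain methylation and methylated sites lose it, reproducing the
#'   global normal-to-cancer trend. 0.6 gives a +30 point shift at 10%
#'   normal methylation.
#' @param n_hypo_enhancers,n_hyper_enhancers number of true enhancers given
#'   a targeted loss/gain of methylation on top of the drift.
#' @param enhancer_effect expression change (log2 units) per 100 percent
#'   points of targeted methylation change, applied with opposite sign.
#' @param targeted_delta magnitude of the targeted methylation shift
#'   (percent points).
#' @param expr_noise_sd Gaussian noise on the cancer expression of targeted
#'   genes (log2 units).
#' @param seed RNG seed.
#' @return A list of class `cancer_config`.
#' @export
cancer_config <- function(drift_strength = 0.6, n_hypo_enhancers = 20L,
                          n_hyper_enhancers = 20L, enhancer_effect = 2,
                          targeted_delta = 50, expr_noise_sd = 0.2,
                          seed = 1L) {
  if (drift_strength < 0 || drift_strength > 1)
    stop("drift_strength must lie in [0, 1]")
  structure(list(drift_strength = drift_strength,
                 n_hypo_enhancers = as.integer(n_hypo_enhancers),
                 n_hyper_enhancers = as.integer(n_hyper_enhancers),
                 enhancer_effect = enhancer_effect,
                 targeted_delta = targeted_delta,
                 expr_noise_sd = expr_noise_sd,
                 seed = as.integer(seed)),
            class = "cancer_config")
}

#' Global cancer methylation drift (closed form)
#'
#' The deterministic normal-to-cancer drift used by
#' [generate_cancer_pair()]: a linear odd function about 50% pulling values
#' toward the middle of the scale, so the expected shift-versus-normal
#' curve is `drift_strength * (50 - m)`. Because the map is a convex
#' combination of `m` and 50 it never leaves \[0, 100\].
#'
#' @param m methylation, percent.
#' @param drift_strength in \[0, 1\].
#' @return Drifted methylation values.
#' @export
cancer_drift <- function(m, drift_strength) {
  m + drift_strength * (50 - m)
}

#' Generate a paired normal/cancer panel
#'
#' The normal panel is the input simulation; the cancer panel applies the
#' global [cancer_drift()] to every site, then a targeted hypo- or
#' hyper-methylation shift at selected true enhancers. Genes whose enhancer
#' was targeted change expression by
#' `-enhancer_effect * (realized d_meth / 100)` (plus small noise), i.e.
#' enhancer hypomethylation upregulates the linked gene.
#'
#' @param sim output of [generate_panel()].
#' @param config a [cancer_config()].
#' @return List with `normal` and `cancer` (each `list(meth, expr)`),
#'   `targets` (data.frame: `site_id`, `gene_id`, `direction`,
#'   `d_meth` realized mean shift, `d_expr` applied expression change) and
#'   `drift_strength`.
#' @export
generate_cancer_pair <- function(sim, config = cancer_config()) {
  stopifnot(inherits(config, "cancer_config"))
  enh <- sim$truth$true_enhancer_pairs
  n_t <- config$n_hypo_enhancers + config$n_hyper_enhancers
  if (n_t > nrow(enh))
    stop("targeted enhancer count exceeds number of true enhancers")
  set.seed(config$seed)

  normal_m <- sim$meth$values
  cancer_m <- cancer_drift(normal_m, config$drift_strength)

  idx <- sample.int(nrow(enh), n_t)
  direction <- rep(c(-1, 1), c(config$n_hypo_enhancers,
                               config$n_hyper_enhancers))
  tgt_sites <- enh$site_id[idx]
  rows <- match(tgt_sites, rownames(cancer_m))
  for (k in seq_along(rows)) {
    cancer_m[rows[k], ] <- pmin(pmax(
      cancer_m[rows[k], ] + direction[k] * config$targeted_delta, 0), 100)
  }

  d_meth <- rowMeans(cancer_m[rows, , drop = FALSE], na.rm = TRUE) -
    rowMeans(normal_m[rows, , drop = FALSE], na.rm = TRUE)

  cancer_e <- sim$expr
  tgt_genes <- enh$gene_id[idx]
  d_expr <- -config$enhancer_effect * d_meth / 100
  for (k in seq_along(tgt_genes)) {
    g <- match(tgt_genes[k], rownames(cancer_e))
    cancer_e[g, ] <- cancer_e[g, ] + d_expr[k] +
      stats::rnorm(ncol(cancer_e), 0, config$expr_noise_sd)
  }

  targets <- data.frame(site_id = tgt_sites, gene_id = tgt_genes,
                        direction = ifelse(direction < 0, "hypo", "hyper"),
                        d_meth = as.numeric(d_meth),
                        d_expr = as.numeric(d_expr),
                        stringsAsFactors = FALSE)
  list(normal = list(meth = sim$meth, expr = sim$expr),
       cancer = list(meth = meth_panel(sim$meth$sites, cancer_m,
                                       sim$meth$coverage),
                     expr = cancer_e),
       targets = targets, drift_strength = config$drift_strength)
}

#' Generate synthetic chromatin-state, TF-peak and 5C annotations
#'
#' Chromatin states: each site gets one state label per annotated cell
#' type; true enhancer sites receive the enhancer state (`state4`) with the
#' configured odds multiplier (odds 1 = independent of truth). TF peaks:
#' the number of distinct factors bound at a site is Poisson with mean
#' decreasing linearly in the site's mean methylation. 5C: read counts for
#' true enhancer-gene pairs are drawn with `fivec_ratio`-fold higher mean
#' than enhancer-to-other-TSS records.
#'
#' @param sim output of [generate_panel()].
#' @param seed RNG seed.
#' @param n_states number of chromatin states (`state1` ... `stateK`).
#' @param enrichment_odds odds multiplier for `state4` at true enhancers.
#' @param n_cell_types_annotated how many panel cell types carry
#'   annotations.
#' @param n_tfs number of distinct transcription factors.
#' @param tf_max_mean Poisson mean of bound factors at 0% methylation
#'   (decays linearly to ~0 at 100%).
#' @param fivec_false_mean mean 5C reads for non-pair records.
#' @param fivec_ratio true:false mean-read ratio.
#' @param n_false_tss non-pair TSS records per enhancer.
#' @return List with `states` and `tf_peaks` (BED-style data.frames:
#'   `chrom`, `start`, `end`, `label`, `cell_type`) and `fivec`
#'   (data.frame: `site_id`, `gene_id`, `reads`, `predicted`).
#' @export
generate_annotations <- function(sim, seed = 1L, n_states = 7L,
                                 enrichment_odds = 10,
                                 n_cell_types_annotated = 3L,
                                 n_tfs = 20L, tf_max_mean = 8,
                                 fivec_false_mean = 90, fivec_ratio = 3,
                                 n_false_tss = 5L) {
  set.seed(seed)
  sites <- sim$meth$sites
  is_enh <- sites$site_id %in% sim$truth$true_enhancer_pairs$site_id
  states <- paste0("state", seq_len(n_states))
  ann_cells <- cell_types(sim$meth)[seq_len(min(n_cell_types_annotated,
                                                ncol(sim$meth$values)))]

  base <- rep(1, n_states)
  w_enh <- base; w_enh[4L] <- enrichment_odds
  state_rows <- do.call(rbind, lapply(ann_cells, function(ct) {
    lab <- ifelse(is_enh,
                  sample(states, nrow(sites), replace = TRUE,
                         prob = w_enh / sum(w_enh)),
                  sample(states, nrow(sites), replace = TRUE,
                         prob = base / sum(base)))
    data.frame(chrom = sites$chrom, start = sites$pos,
               end = sites$pos + 200L, label = lab, cell_type = ct,
               stringsAsFactors = FALSE)
  }))

  mean_meth <- rowMeans(sim$meth$values, na.rm = TRUE)
  mean_meth[!is.finite(mean_meth)] <- 50
  tf_names <- sprintf("TF%02d", seq_len(n_tfs))
  tf_rows <- do.call(rbind, lapply(ann_cells, function(ct) {
    lam <- tf_max_mean * (1 - mean_meth / 100)
    k <- pmin(stats::rpois(length(lam), lam), n_tfs)
    hit <- which(k > 0)
    if (!length(hit)) return(NULL)
    do.call(rbind, lapply(hit, function(i)
      data.frame(chrom = sites$chrom[i],
                 start = pmax(sites$pos[i] - 100L, 0L),
                 end = sites$pos[i] + 100L,
                 label = sample(tf_names, k[i]), cell_type = ct,
                 stringsAsFactors = FALSE)))
  }))

  enh <- sim$truth$true_enhancer_pairs
  genes <- sim$genes
  fivec <- do.call(rbind, lapply(seq_len(nrow(enh)), function(i) {
    g_true <- enh$gene_id[i]
    others <- setdiff(genes$gene_id[genes$chrom ==
                                      genes$chrom[match(g_true,
                                                        genes$gene_id)]],
                      g_true)
    g_false <- if (length(others))
      sample(others, min(n_false_tss, length(others))) else character(0)
    data.frame(site_id = enh$site_id[i],
               gene_id = c(g_true, g_false),
               reads = c(stats::rnbinom(1, mu = fivec_false_mean *
                                          fivec_ratio, size = 4),
                         stats::rnbinom(length(g_false),
                                        mu = fivec_false_mean, size = 4)),
               predicted = c(TRUE, rep(FALSE, length(g_false))),
               stringsAsFactors = FALSE)
  }))
  list(states = state_rows, tf_peaks = tf_rows, fivec = fivec)
}
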