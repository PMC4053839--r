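# Orthogonal validation statistics: chromatin-state enrichment, TF binding
# counts, 5C chromatin-interaction agreement, and replication of
# predictions in an independent panel.

#' High-scoring sites under real and expression-shuffled scoring
#'
#' Shared null machinery for the enrichment analyses: scores the candidate
#' pairs once on the real expression, then `n_shuffles` more times with
#' each gene's expression swapped to a cross-chromosome partner, returning
#' the high-scoring site sets of each run.
#'
#' @inheritParams interval_enrichment_permutation
#' @return List: `real` (character site ids scoring >= threshold) and
#'   `shuffled` (list of site-id vectors, one per shuffle).
#' @export
shuffled_high_sites <- function(model, pairs, meth, expr, genes,
                                threshold = 0.9, n_shuffles = 10L,
                                seed = 1L) {
  set.seed(seed)
  real <- count_high_pairs(model, pairs, meth, expr, threshold,
                           return_sites = TRUE)
  gene_ord <- rownames(expr)
  gm <- genes[match(gene_ord, genes$gene_id), , drop = FALSE]
  shuffled <- lapply(seq_len(n_shuffles), function(i) {
    p <- shuffle_expression_partners(gm)
    e2 <- expr[p, , drop = FALSE]
    rownames(e2) <- gene_ord
    count_high_pairs(model, pairs, meth, e2, threshold,
                     return_sites = TRUE)
  })
  list(real = real, shuffled = shuffled)
}

# States (labels) per site: a state is called when the site falls in an
# interval with that label in at least one cell type; a site may carry
# several states.
site_states <- function(sites, annotations) {
  res <- stats::setNames(vector("list", nrow(sites)), sites$site_id)
  for (ch in unique(sites$chrom)) {
    a <- annotations[annotations$chrom == ch, , drop = FALSE]
    si <- which(sites$chrom == ch)
    for (i in si) {
      hit <- a$start <= sites$pos[i] & sites$pos[i] < a$end
      res[[i]] <- unique(a$label[hit])
    }
  }
  res
}

#' Chromatin-state enrichment of high-scoring sites
#'
#' Per state: the number of high-scoring sites carrying that state (in at
#' least one annotated cell type; multi-state sites count in every state
#' they carry) versus the counts from the expression-shuffled runs. The
#' fold is real over the shuffled mean and the p-value the upper normal
#' tail of the shuffled counts.
#'
#' @param site_sets output of [shuffled_high_sites()].
#' @param sites site table of the panel (`site_id`, `chrom`, `pos`).
#' @param annotations chromatin-state intervals
#'   ([read_bed_annotations()] layout).
#' @return data.frame: `category`, `real_count`, `shuffled_mean`,
#'   `shuffled_sd`, `fold`, `p_value` (one row per state; `fold` is `NA`,
#'   flagged, when the shuffled mean is 0).
#' @export
chromatin_state_enrichment <- function(site_sets, sites, annotations) {
  st <- site_states(sites, annotations)
  states <- sort(unique(annotations$label))
  count_in <- function(ids) {
    got <- unlist(st[ids], use.names = FALSE)
    vapply(states, function(s) sum(got == s), numeric(1))
  }
  real <- count_in(site_sets$real)
  shuf <- vapply(site_sets$shuffled, count_in,
                 numeric(length(states)))
  if (is.null(dim(shuf))) shuf <- matrix(shuf, nrow = length(states))
  mu <- rowMeans(shuf)
  sdv <- apply(shuf, 1L, stats::sd)
  data.frame(category = states, real_count = real,
             shuffled_mean = mu, shuffled_sd = sdv,
             fold = ifelse(mu > 0, real / mu, NA_real_),
             p_value = ifelse(sdv > 0,
                              stats::pnorm(real, mu, sdv,
                                           lower.tail = FALSE),
                              as.numeric(real <= mu)),
             stringsAsFactors = FALSE)
}

# Distinct factors bound at each site, averaged across annotated cell
# types. Peaks hitting the same site twice for one factor count once.
tf_counts_per_site <- function(sites, tf_peaks) {
  cts <- unique(tf_peaks$cell_type)
  acc <- matrix(0, nrow(sites), length(cts))
  for (j in seq_along(cts)) {
    pk <- tf_peaks[tf_peaks$cell_type == cts[j], , drop = FALSE]
    for (ch in unique(sites$chrom)) {
      a <- pk[pk$chrom == ch, , drop = FALSE]
      si <- which(sites$chrom == ch)
      for (i in si) {
        hit <- a$start <= sites$pos[i] & sites$pos[i] < a$end
        acc[i, j] <- length(unique(a$label[hit]))
      }
    }
  }
  stats::setNames(rowMeans(acc), sites$site_id)
}

#' Transcription-factor binding at high-scoring sites
#'
#' Counts the number of distinct factors bound at each high-scoring site
#' (averaged across annotated cell types), compares the mean against the
#' expression-shuffled expectation, and contrasts unmethylated versus
#' methylated sites (mean methylation at or below `unmeth_cut` / at or
#' above `meth_cut`) with a Wilcoxon rank-sum test.
#'
#' @param site_sets output of [shuffled_high_sites()].
#' @param sites panel site table.
#' @param tf_peaks TF peak intervals (label = factor name, `cell_type`
#'   column).
#' @param site_meth named per-site mean methylation (percent).
#' @param unmeth_cut,meth_cut group cutoffs, percent (defaults 20/80).
#' @return List: `mean_count`, `shuffled_mean`, `fold`, `p_value` (upper
#'   normal tail), `group_means` (unmethylated/methylated),
#'   `wilcoxon_p`.
#' @export
tf_binding_comparison <- function(site_sets, sites, tf_peaks, site_meth,
                                  unmeth_cut = 20, meth_cut = 80) {
  counts <- tf_counts_per_site(sites, tf_peaks)
  real_mean <- mean(counts[site_sets$real])
  shuf_means <- vapply(site_sets$shuffled,
                       function(ids) mean(counts[ids]), numeric(1))
  mu <- mean(shuf_means); sdv <- stats::sd(shuf_means)

  m <- site_meth[site_sets$real]
  un <- counts[site_sets$real][!is.na(m) & m <= unmeth_cut]
  me <- counts[site_sets$real][!is.na(m) & m >= meth_cut]
  if (!length(un))
    stop("no unmethylated sites at cut <= ", unmeth_cut)
  if (!length(me))
    stop("no methylated sites at cut >= ", meth_cut)
  w <- stats::wilcox.test(un, me, exact = FALSE)

  list(mean_count = real_mean, shuffled_mean = mu,
       fold = if (mu > 0) real_mean / mu else NA_real_,
       p_value = if (!is.na(sdv) && sdv > 0)
         stats::pnorm(real_mean, mu, sdv, lower.tail = FALSE)
         else as.numeric(real_mean <= mu),
       group_means = c(unmethylated = mean(un), methylated = mean(me)),
       wilcoxon_p = w$p.value)
}

#' Agreement between methylation-based pairing and 5C interactions
#'
#' A record "agrees" when its interaction read count strictly exceeds the
#' global mean read count. Agreement fractions are computed separately for
#' high-score (`score >= high_threshold`) and lower-score records and
#' compared by a binomial test of the high-stratum successes against the
#' low-stratum proportion. Separately, reads of predicted enhancer-TSS
#' pairs are compared with the same enhancers' other-TSS records by a
#' Wilcoxon rank-sum test. Both statistics are invariant to rescaling all
#' reads by a positive constant.
#'
#' @param records data.frame: `site_id`, `gene_id`, `reads`, `predicted`
#'   (logical), `score` (of the enhancer-gene pair).
#' @param high_threshold score cutoff for the high stratum.
#' @return List: `mean_reads`, `agree_fraction_high`,
#'   `agree_fraction_low`, `binomial_p` (`NA`, with a message, if a
#'   stratum is empty), `predicted_vs_other_p`.
#' @export
fivec_agreement <- function(records, high_threshold = 0.85) {
  stopifnot(all(c("reads", "predicted", "score") %in% names(records)))
  mu <- mean(records$reads)
  agree <- records$reads > mu
  hi <- records$score >= high_threshold
  f_hi <- if (any(hi)) mean(agree[hi]) else NA_real_
  f_lo <- if (any(!hi)) mean(agree[!hi]) else NA_real_
  binom_p <- NA_real_
  if (any(hi) && any(!hi) && f_lo > 0 && f_lo < 1) {
    binom_p <- stats::binom.test(sum(agree[hi]), sum(hi),
                                 p = f_lo)$p.value
  } else {
    message("5C binomial comparison skipped: missing or degenerate stratum")
  }
  pv <- if (any(records$predicted) && any(!records$predicted))
    stats::wilcox.test(records$reads[records$predicted],
                       records$reads[!records$predicted],
                       exact = !anyDuplicated(records$reads))$p.value
    else NA_real_
  list(mean_reads = mu, agree_fraction_high = f_hi,
       agree_fraction_low = f_lo, binomial_p = binom_p,
       predicted_vs_other_p = pv)
}

#' Replication of predicted pairs in an independent panel
#'
#' Re-scores previously predicted (gene, CpG) pairs in a new panel and
#' counts how many score above `threshold`. The chance expectation comes
#' from re-scoring with the gene-expression assignment shuffled among the
#' genes (`n_null` rounds); the p-value is two-sided normal for the
#' observed count against the null mean and SD.
#'
#' @param prior_pairs data.frame with `gene_id`, `site_id` of pairs
#'   predicted in a reference panel (at least 10 must be assessable).
#' @param model a `pair_ranker`.
#' @param meth,expr the new panel and expression matrix.
#' @param threshold normalized score cutoff (strict `>`).
#' @param n_null shuffle rounds.
#' @param seed RNG seed.
#' @return List: `observed`, `expected_mean`, `expected_sd`,
#'   `p_two_sided`, `n_assessable`.
#' @export
replication_test <- function(prior_pairs, model, meth, expr,
                             threshold = 0.9, n_null = 1000L, seed = 1L) {
  ok <- prior_pairs$site_id %in% meth$sites$site_id &
    prior_pairs$gene_id %in% rownames(expr)
  pairs <- prior_pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 10L)
    stop("fewer than 10 prior pairs assessable in the new panel")
  set.seed(seed)
  si <- match(pairs$site_id, meth$sites$site_id)
  M <- meth$values[si, , drop = FALSE]
  gi <- match(pairs$gene_id, rownames(expr))
  score_once <- function(E_rows) {
    f <- feature_matrix(M, E_rows)
    sum(normalize_scores(raw_score(model, f)) > threshold)
  }
  observed <- score_once(expr[gi, , drop = FALSE])
  ng <- nrow(expr)
  null_counts <- vapply(seq_len(n_null), function(i) {
    p <- sample.int(ng)
    score_once(expr[p[gi], , drop = FALSE])
  }, numeric(1))
  mu <- mean(null_counts); sdv <- stats::sd(null_counts)
  # continuity-corrected two-sided tail: the counts are integers
  list(observed = observed, expected_mean = mu, expected_sd = sdv,
       p_two_sided = if (sdv > 0)
       2 * stats::pnorm(-max(abs(observed - mu) - 0.5, 0) / sdv) else
         as.numeric(observed != mu),
       n_assessable = nrow(pairs))
}
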