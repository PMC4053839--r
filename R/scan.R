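# Genome-wide application of the model: candidate pair enumeration over
# +-1 Mb gene intervals, promoter-proximal removal, distal region
# clustering, and enrichment against expression-shuffled intervals.

#' Gene intervals for the genome scan
#'
#' The scanning window of a gene: 1 Mb upstream of the transcription
#' start through the gene body to 1 Mb downstream of the transcription
#' end, stored as a plain coordinate range `[min(tss, tes) - 1 Mb,
#' max(tss, tes) + 1 Mb]` (floored at 0), which is strand-independent.
#'
#' @param genes [gene_models()] data.frame.
#' @param flank flank size in bp (default 1 Mb).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end` (closed
#'   interval; a site exactly `flank` away is inside).
#' @export
gene_intervals <- function(genes, flank = 1e6) {
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(pmin(genes$tss, genes$tes) - flank, 0),
             end = pmax(genes$tss, genes$tes) + flank,
             stringsAsFactors = FALSE)
}

#' Enumerate candidate (gene, CpG) pairs over gene intervals
#'
#' One candidate per (gene, VMS inside the gene's interval on the same
#' chromosome); interval membership is inclusive at both ends, so a site
#' exactly 1 Mb from the gene is a candidate. A site overlapping several
#' gene intervals pairs with each of those genes.
#'
#' @param genes [gene_models()] data.frame.
#' @param panel a VMS-filtered [meth_panel()].
#' @param flank interval flank in bp.
#' @return data.frame: `gene_id`, `site_id`, `chrom`, `pos`.
#' @export
enumerate_candidate_pairs <- function(genes, panel, flank = 1e6) {
  iv <- gene_intervals(genes, flank)
  out <- vector("list", nrow(iv))
  for (ch in unique(iv$chrom)) {
    si <- which(panel$sites$chrom == ch)
    if (!length(si)) next
    pos <- panel$sites$pos[si]
    o <- order(pos)
    si <- si[o]; pos <- pos[o]
    for (gi in which(iv$chrom == ch)) {
      lo <- findInterval(iv$start[gi] - 1L, pos) + 1L
      hi <- findInterval(iv$end[gi], pos)
      if (hi < lo) next
      sel <- si[lo:hi]
      out[[gi]] <- data.frame(gene_id = iv$gene_id[gi],
                              site_id = panel$sites$site_id[sel],
                              chrom = ch, pos = panel$sites$pos[sel],
                              stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(gene_id = character(), site_id = character(),
                      chrom = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Remove promoter-proximal pairs
#'
#' Drops pairs whose CpG lies within `exclusion` bp (closed: a site
#' exactly at the boundary is removed) of the associated gene's TSS or any
#' of its alternative promoters. Proximity to a *different* gene's
#' promoter does not disqualify a pair.
#'
#' @param pairs data.frame from [enumerate_candidate_pairs()] (needs
#'   `gene_id`, `pos`).
#' @param genes [gene_models()] with `alt_promoters`.
#' @param exclusion distance in bp (default 5 kb).
#' @return The filtered pair data.frame.
#' @export
filter_promoter_proximal <- function(pairs, genes, exclusion = 5000) {
  gi <- match(pairs$gene_id, genes$gene_id)
  if (anyNA(gi)) stop("pair gene(s) missing from gene models")
  near <- vapply(seq_len(nrow(pairs)), function(k) {
    proms <- c(genes$tss[gi[k]], genes$alt_promoters[[gi[k]]])
    any(abs(pairs$pos[k] - proms) <= exclusion)
  }, logical(1))
  pairs[!near, , drop = FALSE]
}

#' Cluster distal CpGs into enhancer regions
#'
#' Single-linkage merge of sites on the same chromosome whose neighbouring
#' distance is strictly below `gap` (sites 2,999 bp apart merge; 3,000 bp
#' apart do not); by transitivity a chain of close sites forms one region.
#' Every input site lands in exactly one region.
#'
#' @param sites data.frame with `chrom`, `pos` and optionally `site_id`.
#' @param gap merge threshold in bp (strict `<`).
#' @return data.frame: `region_id`, `chrom`, `start`, `end` (span of
#'   member positions), `n_sites`, `site_ids` (comma-joined, ordered by
#'   position).
#' @export
cluster_regions <- function(sites, gap = 3000) {
  if (is.null(sites$site_id))
    sites$site_id <- paste0(sites$chrom, ":", sites$pos)
  sites <- unique(sites[c("site_id", "chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  if (!nrow(sites))
    return(data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_sites = integer(), site_ids = character(),
                      stringsAsFactors = FALSE))
  new_chrom <- c(TRUE, sites$chrom[-1] != sites$chrom[-nrow(sites)])
  dist_ok <- c(Inf, diff(sites$pos)) < gap
  region <- cumsum(new_chrom | !dist_ok)
  agg <- lapply(split(seq_len(nrow(sites)), region), function(ix)
    data.frame(chrom = sites$chrom[ix[1]],
               start = min(sites$pos[ix]), end = max(sites$pos[ix]),
               n_sites = length(ix),
               site_ids = paste(sites$site_id[ix], collapse = ","),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- cbind(region_id = sprintf("region%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Shuffle expression with cross-chromosome partners
#'
#' Returns a permutation of the gene index in which (almost surely) every
#' gene receives the expression vector of a gene from another chromosome —
#' the null used by the enrichment permutation tests. Violating
#' assignments after a uniform draw are re-drawn among themselves; a final
#' lone violator is swapped with a random compatible gene.
#'
#' @param genes [gene_models()] data.frame.
#' @return Integer permutation of `seq_len(nrow(genes))`.
#' @export
shuffle_expression_partners <- function(genes) {
  n <- nrow(genes)
  p <- sample.int(n)
  for (iter in 1:50) {
    bad <- which(genes$chrom[p] == genes$chrom)
    if (length(bad) <= 1L) break
    p[bad] <- p[bad[sample.int(length(bad))]]
  }
  bad <- which(genes$chrom[p] == genes$chrom)
  for (b in bad) {
    ok <- which(genes$chrom != genes$chrom[b] &
                  genes$chrom[p] != genes$chrom[p[b]])
    if (length(ok)) {
      j <- ok[sample.int(length(ok), 1L)]
      p[c(b, j)] <- p[c(j, b)]
    }
  }
  p
}

# Re-score candidate pairs under one expression shuffle and count
# normalized scores >= threshold. Returns the count (and high site_ids
# when asked).
count_high_pairs <- function(model, pairs, meth, expr, threshold,
                             return_sites = FALSE) {
  s <- score_pairs(model, pairs, meth, expr)
  if (return_sites) unique(s$site_id[s$score >= threshold])
  else sum(s$score >= threshold)
}

#' Enrichment of high-scoring pairs in real versus shuffled intervals
#'
#' Counts candidate pairs with normalized score at or above `threshold`,
#' then repeats the scoring after replacing each gene's expression with
#' that of a cross-chromosome partner (`n_shuffles` independent rounds).
#' The fold is real over the shuffled mean; the p-value is the upper tail
#' of a normal distribution fitted to the shuffled counts.
#'
#' @param model a `pair_ranker`.
#' @param pairs candidate pairs ([enumerate_candidate_pairs()]).
#' @param meth a [meth_panel()].
#' @param expr genes x cell types expression matrix.
#' @param genes [gene_models()] data.frame.
#' @param threshold normalized score cutoff (default 0.9).
#' @param n_shuffles number of shuffle rounds (>= 2; the SD needs it).
#' @param seed RNG seed; the shuffle assignments are reproducible.
#' @return List: `real_count`, `shuffled_counts`, `fold`, `p_value`.
#' @export
interval_enrichment_permutation <- function(model, pairs, meth, expr,
                                            genes, threshold = 0.9,
                                            n_shuffles = 10L, seed = 1L) {
  if (n_shuffles < 2L)
    stop("n_shuffles must be >= 2 (the null SD is undefined below that)")
  set.seed(seed)
  real <- count_high_pairs(model, pairs, meth, expr, threshold)
  gene_ord <- rownames(expr)
  gm <- genes[match(gene_ord, genes$gene_id), , drop = FALSE]
  shuffled <- vapply(seq_len(n_shuffles), function(i) {
    p <- shuffle_expression_partners(gm)
    e2 <- expr[p, , drop = FALSE]
    rownames(e2) <- gene_ord
    count_high_pairs(model, pairs, meth, e2, threshold)
  }, numeric(1))
  mu <- mean(shuffled); s <- stats::sd(shuffled)
  # continuity-corrected upper tail: the counts are integers
  list(real_count = real, shuffled_counts = shuffled,
       fold = if (mu > 0) real / mu else NA_real_,
       p_value = if (s > 0)
         stats::pnorm(real - 0.5, mu, s, lower.tail = FALSE)
         else as.numeric(real <= mu))
}
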