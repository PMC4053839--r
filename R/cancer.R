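# Normal-versus-cancer contrasts: per-pair delta tables, correlation and
# regression of expression change on methylation change, quadrant
# proportion tests, gene-set overlaps, and the global methylation shift
# curves.

# Promoter-window site ids of a set of genes: sites within [-500, +2000]
# of the TSS, strand-aware.
promoter_window_sites <- function(genes, panel, window = c(-500, 2000)) {
  hits <- character(0)
  for (i in seq_len(nrow(genes))) {
    si <- which(panel$sites$chrom == genes$chrom[i])
    if (!length(si)) next
    d <- panel$sites$pos[si] - genes$tss[i]
    if (genes$strand[i] == "-") d <- -d
    hits <- c(hits, panel$sites$site_id[si[d >= window[1] &
                                             d <= window[2]]])
  }
  unique(hits)
}

#' Per-pair methylation/expression differences between normal and cancer
#'
#' Builds the contrast table behind the delta scatter plots: one row per
#' pair per site class with `d_meth = cancer - normal` (percent points;
#' +100 means 0% methylated in normal and 100% in cancer) and
#' `d_expr = cancer - normal` (log2 units), both averaged over the cell
#' types of each panel. Classes: `enhancer` (the supplied high-scoring
#' distal pairs), `promoter_of_enhancer_gene` (promoter-window sites of
#' the genes appearing in those pairs) and `all_promoters`
#' (promoter-window sites of every gene).
#'
#' @param normal,cancer lists with `meth` ([meth_panel()]) and `expr`
#'   matrix; panels must share sites and genes.
#' @param pairs data.frame of high-scoring distal pairs (`gene_id`,
#'   `site_id`).
#' @param genes [gene_models()] data.frame.
#' @param classes which classes to emit.
#' @return data.frame: `pair_id`, `class`, `gene_id`, `site_id`,
#'   `d_meth`, `d_expr`. Pairs unassessable in either panel are skipped;
#'   the number skipped is in `attr(, "n_skipped")`.
#' @export
delta_table <- function(normal, cancer, pairs, genes,
                        classes = c("enhancer",
                                    "promoter_of_enhancer_gene",
                                    "all_promoters")) {
  dm_site <- rowMeans(cancer$meth$values, na.rm = TRUE) -
    rowMeans(normal$meth$values, na.rm = TRUE)
  names(dm_site) <- normal$meth$sites$site_id
  de_gene <- rowMeans(cancer$expr) - rowMeans(normal$expr)

  rows <- list(); skipped <- 0L
  add_rows <- function(gene_id, site_id, cls) {
    ok <- site_id %in% names(dm_site) & gene_id %in% names(de_gene) &
      is.finite(dm_site[site_id])
    skipped <<- skipped + sum(!ok)
    if (!any(ok)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      pair_id = paste(gene_id[ok], site_id[ok], sep = "|"),
      class = cls, gene_id = gene_id[ok], site_id = site_id[ok],
      d_meth = as.numeric(dm_site[site_id[ok]]),
      d_expr = as.numeric(de_gene[gene_id[ok]]),
      stringsAsFactors = FALSE)
  }
  if ("enhancer" %in% classes)
    add_rows(pairs$gene_id, pairs$site_id, "enhancer")
  if ("promoter_of_enhancer_gene" %in% classes) {
    g <- genes[genes$gene_id %in% unique(pairs$gene_id), , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      ps <- promoter_window_sites(g[i, , drop = FALSE], normal$meth)
      if (length(ps))
        add_rows(rep(g$gene_id[i], length(ps)), ps,
                 "promoter_of_enhancer_gene")
    }
  }
  if ("all_promoters" %in% classes) {
    for (i in seq_len(nrow(genes))) {
      ps <- promoter_window_sites(genes[i, , drop = FALSE], normal$meth)
      if (length(ps))
        add_rows(rep(genes$gene_id[i], length(ps)), ps, "all_promoters")
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(), class = character(),
               gene_id = character(), site_id = character(),
               d_meth = numeric(), d_expr = numeric(),
               stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- skipped
  out
}

#' Correlation and regression of expression change on methylation change
#'
#' @param table a [delta_table()].
#' @param class which class of rows to use (default: all rows).
#' @return List: `pearson_r`, `slope`, `intercept`, `n` (ordinary least
#'   squares of `d_expr` on `d_meth`).
#' @export
delta_correlation <- function(table, class = NULL) {
  if (!is.null(class)) table <- table[table$class == class, , drop = FALSE]
  if (nrow(table) < 3L) stop("need at least 3 rows")
  if (stats::sd(table$d_meth) == 0)
    stop("zero variance in d_meth; correlation undefined")
  fit <- stats::lm(d_expr ~ d_meth, data = table)
  list(pearson_r = stats::cor(table$d_meth, table$d_expr),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = nrow(table))
}

#' Two-proportion z test of concordant-quadrant frequencies
#'
#' The concordant quadrants are hypomethylated-and-upregulated
#' (`d_meth <= -d_meth_cut` and `d_expr >= d_expr_cut`) and
#' hypermethylated-and-downregulated (`d_meth >= d_meth_cut` and
#' `d_expr <= -d_expr_cut`). The fraction of rows falling in them is
#' compared between the enhancer and promoter tables with the pooled
#' two-proportion z statistic, two-sided.
#'
#' @param enh,prom [delta_table()] rows for the two classes.
#' @param d_meth_cut percent-point cut (default 25).
#' @param d_expr_cut expression-unit cut (default 0.25).
#' @return List: `p_enh`, `p_prom`, `z`, `p_value`.
#' @export
quadrant_proportion_test <- function(enh, prom, d_meth_cut = 25,
                                     d_expr_cut = 0.25) {
  stopifnot(nrow(enh) > 0, nrow(prom) > 0)
  in_quad <- function(t)
    (t$d_meth <= -d_meth_cut & t$d_expr >= d_expr_cut) |
    (t$d_meth >= d_meth_cut & t$d_expr <= -d_expr_cut)
  k1 <- sum(in_quad(enh)); n1 <- nrow(enh)
  k2 <- sum(in_quad(prom)); n2 <- nrow(prom)
  if (k1 + k2 == 0L)
    stop("no rows pass the quadrant cuts in either class")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se > 0) (p1 - p2) / se else 0
  list(p_enh = p1, p_prom = p2, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Monte-Carlo p-value for multi-set gene overlap
#'
#' Observed overlap is the size of the intersection of all sets; the null
#' draws same-sized sets uniformly from a universe of `universe_size`
#' genes, and the p-value is the plus-one-corrected fraction of null
#' overlaps at least as large as observed.
#'
#' @param sets list of character vectors of gene ids.
#' @param universe_size size of the declared gene universe.
#' @param n_null Monte-Carlo rounds.
#' @param seed RNG seed.
#' @return List: `observed_overlap`, `expected`, `p`.
#' @export
geneset_overlap_pvalue <- function(sets, universe_size, n_null = 10000L,
                                   seed = 1L) {
  sizes <- lengths(sets)
  if (any(sizes > universe_size))
    stop("a set is larger than the universe")
  observed <- length(Reduce(intersect, sets))
  set.seed(seed)
  null <- vapply(seq_len(n_null), function(i) {
    length(Reduce(intersect, lapply(sizes, function(k)
      sample.int(universe_size, k))))
  }, numeric(1))
  list(observed_overlap = observed, expected = mean(null),
       p = (1 + sum(null >= observed)) / (n_null + 1))
}

#' Average methylation shift in cancer as a function of normal level
#'
#' Bins sites by their normal-cell methylation (equal-width bins over
#' \[0, 100\]) and reports the mean cancer-minus-normal shift per bin,
#' separately for each site class. The site-count-weighted mean of the
#' per-bin shifts equals the overall mean shift exactly.
#'
#' @param normal,cancer aligned [meth_panel()]s.
#' @param site_class_masks named list of logical vectors (or site-id
#'   character vectors) selecting each class; default one class of all
#'   sites.
#' @param n_bins number of bins over \[0, 100\].
#' @return data.frame: `class`, `bin_center`, `mean_normal`,
#'   `mean_shift`, `n_sites` (non-empty bins only; empty classes are
#'   dropped with a warning).
#' @export
methylation_shift_curve <- function(normal, cancer,
                                    site_class_masks =
                                      list(all = rep(TRUE,
                                                     nrow(normal$values))),
                                    n_bins = 20L) {
  stopifnot(identical(dim(normal$values), dim(cancer$values)))
  m0 <- rowMeans(normal$values, na.rm = TRUE)
  shift <- rowMeans(cancer$values, na.rm = TRUE) - m0
  breaks <- seq(0, 100, length.out = n_bins + 1L)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- list()
  for (cls in names(site_class_masks)) {
    sel <- site_class_masks[[cls]]
    if (is.character(sel)) sel <- normal$sites$site_id %in% sel
    sel <- sel & is.finite(m0) & is.finite(shift)
    if (!any(sel)) {
      warning("class '", cls, "' has no usable sites; curve omitted")
      next
    }
    b <- findInterval(m0[sel], breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
    for (k in sort(unique(b))) {
      ix <- which(b == k)
      out[[length(out) + 1L]] <- data.frame(
        class = cls, bin_center = centers[k],
        mean_normal = mean(m0[sel][ix]),
        mean_shift = mean(shift[sel][ix]),
        n_sites = length(ix), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
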