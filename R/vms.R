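# Variable methylation site (VMS) selection: iterative Thompson tau outlier
# rejection, a strict SD threshold, RRBS coverage filtering, and
# array/RRBS matrix merging.

#' Iterative (modified) Thompson tau outlier mask
#'
#' Flags outliers one at a time: at each step the value with the largest
#' absolute deviation from the current mean is flagged if that deviation
#' exceeds tau * SD, where tau is derived from the two-sided Student-t
#' critical value at `alpha` for the current sample size; mean and SD are
#' recomputed after each removal until no value exceeds the bound.
#'
#' @param values numeric vector (NAs allowed; never flagged).
#' @param alpha two-sided significance level of the rejection bound
#'   (default 0.001, i.e. 0.1%).
#' @return Logical vector, `TRUE` where the value is an outlier. Fewer
#'   than 3 non-missing values: nothing is flagged.
#' @export
thompson_tau_mask <- function(values, alpha = 0.001) {
  mask <- rep(FALSE, length(values))
  active <- which(!is.na(values))
  while (length(active) >= 3L) {
    n <- length(active)
    v <- values[active]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) break
    tcrit <- stats::qt(1 - alpha / 2, df = n - 2L)
    tau <- tcrit * (n - 1) / (sqrt(n) * sqrt(n - 2L + tcrit^2))
    dev <- abs(v - mean(v))
    i <- which.max(dev)
    if (dev[i] > tau * s) {
      mask[active[i]] <- TRUE
      active <- active[-i]
    } else break
  }
  mask
}

#' Select variable methylation sites
#'
#' A site is retained when its sample standard deviation across cell types,
#' computed after omitting Thompson-tau outliers and missing values,
#' strictly exceeds `sd_threshold` (boundary SD equal to the threshold is
#' dropped). Outlier cells are only excluded from the SD test; the returned
#' matrix keeps all values. Sites with fewer than 3 usable values are
#' untestable and dropped.
#'
#' @param panel a [meth_panel()].
#' @param sd_threshold percent-point SD threshold (strict `>`).
#' @param alpha Thompson tau significance (two-sided).
#' @return List: `panel` (filtered [meth_panel()]) and `decisions`
#'   (data.frame: `site_id`, `n_outliers`, `post_outlier_sd`, `retained`).
#' @export
select_vms <- function(panel, sd_threshold = 5, alpha = 0.001) {
  stopifnot(inherits(panel, "meth_panel"))
  n <- nrow(panel$values)
  post_sd <- numeric(n)
  n_out <- integer(n)
  for (i in seq_len(n)) {
    v <- panel$values[i, ]
    mask <- thompson_tau_mask(v, alpha)
    keep <- !is.na(v) & !mask
    n_out[i] <- sum(mask)
    post_sd[i] <- if (sum(keep) >= 3L) stats::sd(v[keep]) else NA_real_
  }
  retained <- !is.na(post_sd) & post_sd > sd_threshold
  decisions <- data.frame(site_id = panel$sites$site_id,
                          n_outliers = n_out, post_outlier_sd = post_sd,
                          retained = retained, stringsAsFactors = FALSE)
  list(panel = subset_sites(panel, retained), decisions = decisions)
}

#' Filter sites by RRBS read coverage
#'
#' Retains sites covered by at least `min_reads` reads in at least
#' `min_fraction` of the cell types (both comparisons inclusive). The
#' laxer 0.6 fraction is used for general analyses and 0.8 when preparing
#' the ranking-model training set. Panels without a coverage matrix
#' (array-type data) pass unchanged.
#'
#' @param panel a [meth_panel()].
#' @param min_reads minimum read depth (inclusive).
#' @param min_fraction minimum fraction of cell types at depth (inclusive).
#' @return The filtered [meth_panel()].
#' @export
coverage_filter <- function(panel, min_reads = 10, min_fraction = 0.6) {
  stopifnot(inherits(panel, "meth_panel"))
  if (is.null(panel$coverage)) return(panel)
  frac <- rowMeans(!is.na(panel$coverage) & panel$coverage >= min_reads)
  subset_sites(panel, frac >= min_fraction)
}

#' Merge RRBS and array methylation panels
#'
#' Replicate RRBS panels are averaged first (per site/cell, pairwise over
#' non-missing values); the combined RRBS matrix is then merged with the
#' array matrix, taking the mean where a (site, cell) value exists in both
#' and whichever exists otherwise. Sites are matched by (chrom, pos).
#' Coverage comes from the RRBS side (summed over replicates); array-only
#' sites have NA coverage.
#'
#' @param rrbs a [meth_panel()] or list of replicate [meth_panel()]s
#'   sharing sites and cell types.
#' @param array a [meth_panel()] (typically without coverage).
#' @return The merged [meth_panel()].
#' @export
merge_assay_matrices <- function(rrbs, array) {
  if (inherits(rrbs, "meth_panel")) rrbs <- list(rrbs)
  stopifnot(length(rrbs) >= 1L, inherits(array, "meth_panel"))
  cells <- cell_types(rrbs[[1]])
  for (p in rrbs) if (!identical(cell_types(p), cells))
    stop("conflicting cell-type headers between RRBS replicates")
  if (!identical(cell_types(array), cells))
    stop("conflicting cell-type headers between RRBS and array panels")
  for (p in rrbs[-1]) if (!identical(p$sites[c("chrom", "pos")],
                                     rrbs[[1]]$sites[c("chrom", "pos")]))
    stop("RRBS replicates must share sites")

  # replicate average (pairwise over non-missing)
  acc <- matrix(0, nrow(rrbs[[1]]$values), length(cells))
  cnt <- matrix(0L, nrow(acc), ncol(acc))
  cov <- matrix(0, nrow(acc), ncol(acc))
  has_cov <- FALSE
  for (p in rrbs) {
    ok <- !is.na(p$values)
    acc[ok] <- acc[ok] + p$values[ok]
    cnt <- cnt + ok
    if (!is.null(p$coverage)) { cov <- cov + p$coverage; has_cov <- TRUE }
  }
  rrbs_vals <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)

  key_r <- paste(rrbs[[1]]$sites$chrom, rrbs[[1]]$sites$pos)
  key_a <- paste(array$sites$chrom, array$sites$pos)
  all_key <- unique(c(key_r, key_a))
  ir <- match(all_key, key_r)
  ia <- match(all_key, key_a)

  vals <- matrix(NA_real_, length(all_key), length(cells))
  cv <- matrix(NA_real_, length(all_key), length(cells))
  for (j in seq_along(cells)) {
    r <- ifelse(is.na(ir), NA_real_, rrbs_vals[ir, j])
    a <- ifelse(is.na(ia), NA_real_, array$values[ia, j])
    vals[, j] <- ifelse(is.na(r), a, ifelse(is.na(a), r, (r + a) / 2))
    if (has_cov) cv[, j] <- ifelse(is.na(ir), NA_real_, cov[ir, j])
  }
  # the two assays carry independent id namespaces; the merged panel is
  # keyed by coordinate
  sites <- data.frame(
    site_id = sub(" ", ":", all_key),
    chrom = ifelse(!is.na(ir), rrbs[[1]]$sites$chrom[ir],
                   array$sites$chrom[ia]),
    pos = ifelse(!is.na(ir), rrbs[[1]]$sites$pos[ir],
                 array$sites$pos[ia]),
    stringsAsFactors = FALSE)
  rownames(vals) <- sites$site_id
  colnames(vals) <- cells
  if (has_cov) dimnames(cv) <- dimnames(vals)
  meth_panel(sites, vals, if (has_cov) cv)
}
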