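#' Methylation panel
#'
#' A methylation panel holds percent methylation (0-100) for a set of CpG
#' sites measured across a common panel of cell types, together with the
#' genomic coordinates of each site and, for sequencing-based (RRBS) assays,
#' an optional matrix of per-site/per-cell read coverage. Missing
#' measurements are `NA`; missingness is per (site, cell type).
#'
#' Coordinates are 0-based throughout the package; intervals are half-open
#' (BED convention).
#'
#' @param sites data.frame with columns `site_id`, `chrom`, `pos`
#'   (0-based integer position of the CpG).
#' @param values numeric matrix, sites x cell types, percent methylation in
#'   \[0, 100\] or `NA`. Row names must match `sites$site_id`; column names
#'   are the cell-type names.
#' @param coverage optional integer matrix of read depths with the same
#'   dimnames as `values`, or `NULL` for array-type data.
#' @return An object of class `meth_panel`.
#' @export
meth_panel <- function(sites, values, coverage = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("site_id", "chrom", "pos") %in% names(sites)))
  values <- as.matrix(values)
  if (nrow(values) != nrow(sites))
    stop("`values` must have one row per site")
  if (is.null(rownames(values))) rownames(values) <- sites$site_id
  if (nrow(values) > 0L &&
      !identical(rownames(values), as.character(sites$site_id)))
    stop("row names of `values` must match sites$site_id")
  if (anyDuplicated(sites$site_id))
    stop("duplicated site_id")
  if (any(sites$pos < 0))
    stop("site positions must be >= 0")
  bad <- which(!is.na(values) & (values < 0 | values > 100))
  if (length(bad))
    stop("methylation values outside [0, 100] at ", length(bad), " cells")
  if (!is.null(coverage)) {
    coverage <- as.matrix(coverage)
    if (!identical(dim(coverage), dim(values)))
      stop("`coverage` must have the same dimensions as `values`")
    if (any(!is.na(coverage) & coverage < 0))
      stop("coverage must be non-negative")
    rownames(coverage) <- rownames(values)
  }
  structure(list(sites = sites, values = values, coverage = coverage),
            class = "meth_panel")
}

#' @export
print.meth_panel <- function(x, ...) {
  cat("<meth_panel> ", nrow(x$values), " sites x ", ncol(x$values),
      " cell types", if (!is.null(x$coverage)) " (with coverage)", "\n",
      sep = "")
  cat("  chromosomes: ", paste(utils::head(unique(x$sites$chrom), 8),
                               collapse = ", "),
      if (length(unique(x$sites$chrom)) > 8) ", ...", "\n", sep = "")
  cat("  missing: ", sum(is.na(x$values)), " of ",
      length(x$values), " cells\n", sep = "")
  invisible(x)
}

#' @export
dim.meth_panel <- function(x) dim(x$values)

#' Subset a methylation panel by site
#'
#' @param panel a [meth_panel()].
#' @param keep logical or integer index over sites, or character site ids.
#' @return The subsetted `meth_panel`.
#' @export
subset_sites <- function(panel, keep) {
  stopifnot(inherits(panel, "meth_panel"))
  if (is.character(keep)) keep <- match(keep, panel$sites$site_id)
  meth_panel(panel$sites[keep, , drop = FALSE],
             panel$values[keep, , drop = FALSE],
             if (!is.null(panel$coverage))
               panel$coverage[keep, , drop = FALSE])
}

#' Cell-type names of a panel
#' @param panel a [meth_panel()] or expression matrix.
#' @return Character vector of cell-type names.
#' @export
cell_types <- function(panel) {
  if (inherits(panel, "meth_panel")) colnames(panel$values)
  else colnames(panel)
}

#' Gene model table
#'
#' Validates a gene-model data.frame: `gene_id`, `chrom`, `strand` (+/-),
#' `tss`, `tes` (0-based; `tss` is the transcription start regardless of
#' numeric order, so `tss > tes` on the minus strand), and `alt_promoters`,
#' a list-column of integer positions of alternative promoters (possibly
#' empty).
#'
#' @param genes data.frame as described.
#' @return The validated data.frame, with `alt_promoters` as a list-column.
#' @export
gene_models <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "strand", "tss", "tes") %in%
                  names(genes)))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  plus <- genes$strand == "+"
  if (any(genes$tss[plus] > genes$tes[plus]) ||
      any(genes$tss[!plus] < genes$tes[!plus]))
    stop("tss/tes inconsistent with strand")
  if (is.null(genes$alt_promoters))
    genes$alt_promoters <- replicate(nrow(genes), integer(0),
                                     simplify = FALSE)
  if (!is.list(genes$alt_promoters))
    stop("alt_promoters must be a list-column of integer positions")
  genes
}
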