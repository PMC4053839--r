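# Tabular and interval IO. One convention for the whole package:
# 0-based positions, half-open intervals (BED), percent methylation 0-100,
# "NA" for missing cells.

#' Read a methylation matrix from TSV
#'
#' Expected layout: header row naming the columns `chrom`, `pos`, then one
#' column per cell type; one row per CpG site; `NA` for missing values.
#' Positions are 0-based. A sibling coverage TSV (same layout, integer read
#' depths) may be supplied for RRBS-type data.
#'
#' @param path path to the methylation TSV.
#' @param coverage_path optional path to a coverage TSV with identical
#'   chrom/pos rows and cell-type columns.
#' @return A [meth_panel()].
#' @export
read_methylation_matrix <- function(path, coverage_path = NULL) {
  df <- read_tsv_checked(path, c("chrom", "pos"))
  cells <- setdiff(names(df), c("chrom", "pos"))
  if (length(cells) == 0L) stop("no cell-type columns in ", path)
  vals <- as.matrix(df[cells])
  if (!is.numeric(vals)) stop("non-numeric methylation values in ", path)
  bad <- which(!is.na(vals) & (vals < 0 | vals > 100), arr.ind = TRUE)
  if (nrow(bad))
    stop("methylation value out of [0,100] at line ", bad[1, 1] + 1L,
         " of ", path)
  sites <- data.frame(site_id = paste0(df$chrom, ":", df$pos),
                      chrom = df$chrom, pos = as.integer(df$pos),
                      stringsAsFactors = FALSE)
  rownames(vals) <- sites$site_id
  cov <- NULL
  if (!is.null(coverage_path)) {
    cdf <- read_tsv_checked(coverage_path, c("chrom", "pos"))
    if (!identical(cdf$chrom, df$chrom) || !identical(as.integer(cdf$pos),
                                                      sites$pos))
      stop("coverage rows do not match methylation rows")
    cov <- as.matrix(cdf[cells])
    rownames(cov) <- sites$site_id
  }
  meth_panel(sites, vals, cov)
}

#' Write a methylation panel to TSV
#'
#' Inverse of [read_methylation_matrix()]; `read(write(x))` reproduces the
#' panel exactly (including missing cells).
#'
#' @param panel a [meth_panel()].
#' @param path output TSV path.
#' @param coverage_path optional output path for the coverage matrix.
#' @return `path`, invisibly.
#' @export
write_methylation_matrix <- function(panel, path, coverage_path = NULL) {
  stopifnot(inherits(panel, "meth_panel"))
  df <- data.frame(chrom = panel$sites$chrom, pos = panel$sites$pos,
                   panel$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(coverage_path)) {
    if (is.null(panel$coverage)) stop("panel has no coverage matrix")
    cdf <- data.frame(chrom = panel$sites$chrom, pos = panel$sites$pos,
                      panel$coverage, check.names = FALSE)
    utils::write.table(cdf, coverage_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Layout: `gene_id` column, then one column per cell type, values in
#' log2 (RMA-like) units.
#'
#' @param path path to the TSV.
#' @return Numeric matrix, genes x cell types, row names = gene ids.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_checked(path, "gene_id")
  cells <- setdiff(names(df), "gene_id")
  m <- as.matrix(df[cells])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- df$gene_id
  m
}

#' Write an expression matrix to TSV
#' @param expr genes x cell types matrix with row names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from TSV
#'
#' Columns: `gene_id`, `chrom`, `strand`, `tss`, `tes`, and optionally
#' `alt_promoters` as a comma-separated list of positions (empty string for
#' none).
#'
#' @param path path to the TSV.
#' @return A validated [gene_models()] data.frame.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "chrom", "strand", "tss", "tes"))
  if ("alt_promoters" %in% names(df)) {
    ap <- as.character(df$alt_promoters)
    ap[is.na(ap)] <- ""
    df$alt_promoters <- lapply(strsplit(ap, ","), function(x)
      as.integer(x[nzchar(x)]))
  }
  gene_models(df)
}

#' Write gene models to TSV
#' @param genes a [gene_models()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  genes <- gene_models(genes)
  out <- genes[c("gene_id", "chrom", "strand", "tss", "tes")]
  out$alt_promoters <- vapply(genes$alt_promoters, paste, "", collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read interval annotations from BED
#'
#' BED is 0-based half-open. The name field (column 4) carries the label
#' (chromatin-state name or TF name); the cell type sits in a configurable
#' column (default 5). Intervals are returned sorted within chromosome.
#'
#' @param path path to the BED file.
#' @param cell_type_col 1-based column index holding the cell type, or `NA`
#'   if the file has none (cell_type is then `""`).
#' @return data.frame with columns `chrom`, `start`, `end`, `label`,
#'   `cell_type`.
#' @export
read_bed_annotations <- function(path, cell_type_col = 5L) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = paste0("V", 1:12), fill = TRUE)[
                            , 1:max(4L, cell_type_col, na.rm = TRUE),
                            drop = FALSE]
  if (nrow(df) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      cell_type = character(), stringsAsFactors = FALSE))
  out <- data.frame(chrom = df$V1, start = as.integer(df$V2),
                    end = as.integer(df$V3), label = as.character(df$V4),
                    cell_type = if (!is.na(cell_type_col) &&
                                    ncol(df) >= cell_type_col)
                      as.character(df[[cell_type_col]]) else "",
                    stringsAsFactors = FALSE)
  out$cell_type[is.na(out$cell_type)] <- ""
  if (any(is.na(out$start)) || any(is.na(out$end)))
    stop("malformed BED coordinates in ", path)
  if (any(out$start >= out$end))
    stop("BED interval with start >= end at line ",
         which(out$start >= out$end)[1], " of ", path)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Write interval annotations to BED
#' @param annotations data.frame as returned by [read_bed_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_annotations <- function(annotations, path) {
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(annotations)))
  if (any(annotations$start >= annotations$end))
    stop("interval with start >= end")
  out <- annotations[c("chrom", "start", "end", "label")]
  out$cell_type <- if ("cell_type" %in% names(annotations))
    annotations$cell_type else ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a scored pair table to CSV
#'
#' Emits one row per (CpG, gene) pair exceeding a score cutoff, the
#' machine-readable companion of the genome scan: columns `chrom`, `pos`,
#' `gene_id`, `score`, ordered by (chrom, pos, gene_id).
#'
#' @param pairs data.frame with columns `chrom`, `pos`, `gene_id`, `score`.
#' @param path output CSV path.
#' @param min_score pairs with `score > min_score` are written (strict).
#' @return Number of rows written, invisibly.
#' @export
write_pair_table <- function(pairs, path, min_score = 0.75) {
  stopifnot(all(c("chrom", "pos", "gene_id", "score") %in% names(pairs)))
  if (any(is.na(pairs$score)))
    stop("unscored pair (NA score); score pairs before writing")
  keep <- pairs$score > min_score
  out <- pairs[keep, c("chrom", "pos", "gene_id", "score"), drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$gene_id), , drop = FALSE]
  out$score <- round(out$score, 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(nrow(out))
}

#' Read a scored pair table written by [write_pair_table()]
#' @param path CSV path.
#' @return data.frame with columns `chrom`, `pos`, `gene_id`, `score`.
#' @export
read_pair_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "gene_id", "score") %in% names(df)))
  df$pos <- as.integer(df$pos)
  df
}

# Shared TSV reader: header required, named columns checked, parse errors
# reported with a line number.
read_tsv_checked <- function(path, required) {
  n_fields <- utils::count.fields(path, sep = "\t")
  if (length(unique(n_fields)) > 1L)
    stop("ragged row at line ", which(n_fields != n_fields[1])[1],
         " of ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, na.strings = "NA"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path)
  df
}
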