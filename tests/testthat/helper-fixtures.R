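# Small in-code fixtures shared across test files.

# A meth_panel built directly from a values matrix; site ids s1, s2, ...
# placed on one chromosome 10 kb apart unless positions are given.
toy_panel <- function(values, chrom = NULL, pos = NULL, coverage = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("c%02d", seq_len(ncol(values)))
  sites <- data.frame(site_id = sprintf("s%03d", seq_len(n)),
                      chrom = if (is.null(chrom)) rep("chr1", n) else chrom,
                      pos = if (is.null(pos)) seq_len(n) * 10000L else pos,
                      stringsAsFactors = FALSE)
  rownames(values) <- sites$site_id
  if (!is.null(coverage)) {
    coverage <- as.matrix(coverage)
    dimnames(coverage) <- dimnames(values)
  }
  meth_panel(sites, values, coverage)
}

# A small gene-models table on two chromosomes.
toy_genes <- function() {
  gene_models(data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(2e6, 5e6, 2e6),
    tes = c(2.1e6, 4.9e6, 2.05e6),
    alt_promoters = I(list(integer(0), 5.2e6, integer(0))),
    stringsAsFactors = FALSE))
}

# Key helper: match scored pairs against a truth table of (gene, site).
pair_key <- function(gene_id, site_id) paste(gene_id, site_id, sep = "|")
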