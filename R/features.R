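# Correlation features of a (CpG, gene) sample and the linear score.
# A "sample" is one CpG's methylation profile against one gene's expression
# profile across the shared cell types. Four features: the positive and
# negative parts of the Pearson and Spearman correlations, encoded as
# magnitudes (max(r, 0) and max(-r, 0)), so that a model with positive
# weight on the "negative" features rewards anti-correlated pairs.

FEATURE_NAMES <- c("pos_pearson", "neg_pearson", "pos_spearman",
                   "neg_spearman")

#' Correlation features for one CpG-gene sample
#'
#' Pearson r and Spearman rho are computed over pairwise-complete cells
#' (Spearman with average ranks for ties). Zero-variance profiles yield
#' zero correlations; fewer than `min_pairs` complete cells yields the
#' all-zero vector (the pair is uninformative, not an error).
#'
#' @param meth numeric vector of percent methylation across cell types.
#' @param expr numeric vector of log2 expression, same cell order.
#' @param min_pairs minimum number of complete (non-missing in both)
#'   cells for the correlations to be trusted.
#' @return Named numeric vector `(pos_pearson, neg_pearson, pos_spearman,
#'   neg_spearman)`.
#' @export
extract_features <- function(meth, expr, min_pairs = 10L) {
  stopifnot(length(meth) == length(expr))
  ok <- !is.na(meth) & !is.na(expr)
  if (sum(ok) < min_pairs)
    return(stats::setNames(numeric(4), FEATURE_NAMES))
  m <- meth[ok]; e <- expr[ok]
  r <- if (stats::sd(m) == 0 || stats::sd(e) == 0) 0 else
    stats::cor(m, e)
  rho <- if (stats::sd(m) == 0 || stats::sd(e) == 0) 0 else
    stats::cor(m, e, method = "spearman")
  stats::setNames(c(max(r, 0), max(-r, 0), max(rho, 0), max(-rho, 0)),
                  FEATURE_NAMES)
}

# Vectorized feature extraction for aligned row pairs: row i of `M`
# (methylation) against row i of `E` (expression). Complete rows go
# through standardized matrix arithmetic; rows with NAs fall back to
# extract_features(). Returns an n x 4 matrix.
feature_matrix <- function(M, E, min_pairs = 10L) {
  stopifnot(identical(dim(M), dim(E)))
  n <- nrow(M); C <- ncol(M)
  out <- matrix(0, n, 4L, dimnames = list(NULL, FEATURE_NAMES))
  if (n == 0L) return(out)
  has_na <- rowSums(is.na(M) | is.na(E)) > 0L
  cc <- which(!has_na)
  if (length(cc) && C >= min_pairs) {
    r <- row_cor(M[cc, , drop = FALSE], E[cc, , drop = FALSE])
    Mr <- t(apply(M[cc, , drop = FALSE], 1L, rank))
    Er <- t(apply(E[cc, , drop = FALSE], 1L, rank))
    rho <- row_cor(Mr, Er)
    out[cc, 1L] <- pmax(r, 0); out[cc, 2L] <- pmax(-r, 0)
    out[cc, 3L] <- pmax(rho, 0); out[cc, 4L] <- pmax(-rho, 0)
  }
  for (i in which(has_na))
    out[i, ] <- extract_features(M[i, ], E[i, ], min_pairs)
  out
}

# Row-wise Pearson correlation of two matrices with complete rows;
# zero-variance rows give 0.
row_cor <- function(A, B) {
  A <- A - rowMeans(A); B <- B - rowMeans(B)
  sa <- sqrt(rowSums(A^2)); sb <- sqrt(rowSums(B^2))
  r <- rowSums(A * B) / (sa * sb)
  r[!is.finite(r)] <- 0
  pmin(pmax(r, -1), 1)
}

#' Raw (unnormalized) model score of feature vectors
#'
#' The inner product of the model weights with the 4 correlation features.
#'
#' @param weights a `pair_ranker` model, or a numeric 4-vector ordered as
#'   `(pos_pearson, neg_pearson, pos_spearman, neg_spearman)`.
#' @param features numeric 4-vector or an n x 4 matrix/data.frame.
#' @return Numeric score(s).
#' @export
raw_score <- function(weights, features) {
  w <- if (inherits(weights, "pair_ranker")) weights$w else as.numeric(weights)
  if (length(w) != 4L) stop("weights must have 4 components")
  if (is.data.frame(features)) features <- as.matrix(features[FEATURE_NAMES])
  if (is.null(dim(features))) {
    if (length(features) != 4L) stop("feature vector must have 4 components")
    return(sum(w * features))
  }
  as.numeric(features %*% w)
}

#' Normalize raw scores to the 0-1 range
#'
#' Affine map of the raw scores of a scoring universe onto \[0, 1\]:
#' `(s - min) / (max - min)`. Scores are only comparable within the
#' universe they were normalized over.
#'
#' @param scores numeric vector of raw scores (the scoring universe).
#' @return Scores mapped to \[0, 1\] (minimum at 0, maximum at 1).
#' @export
normalize_scores <- function(scores) {
  rng <- range(scores, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("degenerate score table: all raw scores are equal; ",
         "normalization to [0, 1] is undefined")
  (scores - rng[1]) / (rng[2] - rng[1])
}
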