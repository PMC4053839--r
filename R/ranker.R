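# The ranking model over methylation-expression correlation features.
# A gene "query" is the set of candidate CpG samples for one gene (its true
# promoter CpGs plus an excess of false CpGs from other chromosomes); the
# model is a 4-weight linear scorer trained so that true samples rank above
# false ones within each query, with mean average precision (MAP) on
# held-out queries as the model-selection criterion.

#' Build ranking queries from promoter pairs
#'
#' For each gene with at least one true promoter CpG, assembles a query of
#' its true samples plus a `neg_ratio`-fold excess of false samples: the
#' same promoter CpG pool paired with genes from other chromosomes (every
#' false sample's CpG lies on a different chromosome than the query gene).
#'
#' @param promoter_pairs data.frame with columns `gene_id`, `site_id` of
#'   true promoter pairs.
#' @param genes [gene_models()] data.frame.
#' @param meth a [meth_panel()] containing the promoter CpGs.
#' @param expr genes x cell types expression matrix.
#' @param neg_ratio false samples per true sample.
#' @param seed RNG seed for the false-sample draw.
#' @param min_pairs passed to [extract_features()].
#' @return List of queries; each is a list with `gene_id`, `site_id`,
#'   `label` (logical), `features` (n x 4 matrix).
#' @export
build_training_set <- function(promoter_pairs, genes, meth, expr,
                               neg_ratio = 50L, seed = 1L,
                               min_pairs = 10L) {
  stopifnot(all(c("gene_id", "site_id") %in% names(promoter_pairs)))
  set.seed(seed)
  site_chrom <- meth$sites$chrom[match(promoter_pairs$site_id,
                                       meth$sites$site_id)]
  if (any(is.na(site_chrom))) stop("promoter pair site missing from panel")
  pool_sites <- promoter_pairs$site_id
  gsplit <- split(promoter_pairs$site_id, promoter_pairs$gene_id)

  queries <- lapply(names(gsplit), function(g) {
    true_sites <- gsplit[[g]]
    g_chrom <- genes$chrom[match(g, genes$gene_id)]
    if (is.na(g_chrom)) stop("gene ", g, " missing from gene models")
    cand <- pool_sites[site_chrom != g_chrom]
    if (!length(cand))
      stop("gene ", g, " has no cross-chromosome promoter CpGs to draw ",
           "false samples from")
    n_false <- neg_ratio * length(true_sites)
    false_sites <- if (length(cand) >= n_false) sample(cand, n_false)
      else sample(cand, n_false, replace = TRUE)
    sid <- c(true_sites, false_sites)
    M <- meth$values[match(sid, meth$sites$site_id), , drop = FALSE]
    E <- expr[rep(match(g, rownames(expr)), length(sid)), , drop = FALSE]
    list(gene_id = g, site_id = sid,
         label = c(rep(TRUE, length(true_sites)),
                   rep(FALSE, length(false_sites))),
         features = feature_matrix(M, E, min_pairs))
  })
  names(queries) <- names(gsplit)
  queries
}

#' Average precision of one ranked query
#'
#' Samples are ranked by descending score with ties broken by `site_id`
#' lexicographic order; AP is the mean of precision-at-rank over the ranks
#' of the true samples.
#'
#' @param score numeric scores.
#' @param label logical, `TRUE` for true samples.
#' @param site_id tie-break ids (defaults to the index).
#' @return AP in \[0, 1\]; `NA` when the query has no true sample.
#' @export
average_precision <- function(score, label, site_id = seq_along(score)) {
  if (!any(label)) return(NA_real_)
  o <- order(-score, site_id)
  lab <- label[o]
  ranks <- which(lab)
  mean(seq_along(ranks) / ranks)
}

#' Mean average precision over queries
#'
#' @param queries list of queries carrying `score`, `label`, `site_id`
#'   fields (see [build_training_set()]; scores added by [score_queries()]
#'   or supplied directly).
#' @return MAP in \[0, 1\]. Queries without true samples are excluded
#'   (with a message).
#' @export
mean_average_precision <- function(queries) {
  ap <- vapply(queries, function(q)
    average_precision(q$score, q$label, q$site_id), numeric(1))
  if (anyNA(ap))
    message(sum(is.na(ap)), " query(ies) without true samples excluded")
  mean(ap, na.rm = TRUE)
}

# True-minus-false feature difference rows for one query (the pairwise
# ranking constraints).
query_differences <- function(q) {
  it <- which(q$label); jf <- which(!q$label)
  if (!length(it) || !length(jf)) return(NULL)
  idx <- expand.grid(t = it, f = jf)
  q$features[idx$t, , drop = FALSE] - q$features[idx$f, , drop = FALSE]
}

# L2-regularized squared-hinge pairwise ranking fit:
#   min_w 0.5 ||w||^2 + C/n * sum_i max(0, 1 - D_i w)^2
# Convex and differentiable; BFGS from the origin is deterministic.
fit_rank_weights <- function(D, C) {
  n <- nrow(D)
  obj <- function(w) {
    s <- pmax(0, 1 - as.numeric(D %*% w))
    0.5 * sum(w^2) + C / n * sum(s^2)
  }
  grad <- function(w) {
    s <- pmax(0, 1 - as.numeric(D %*% w))
    w - 2 * C / n * as.numeric(crossprod(D, s))
  }
  fit <- stats::optim(rep(0, 4), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  stats::setNames(fit$par, FEATURE_NAMES)
}

#' Fit the linear ranking model
#'
#' The central fitting function. Queries are split into training and test
#' sets (4:1 by default); the regularization constant is chosen from
#' `c_grid` by `cv_folds`-fold cross-validation on the training queries,
#' maximizing held-out MAP; the final weights are refit on all training
#' queries and evaluated once on the test split. The fit itself is a
#' linear pairwise ranking machine: an L2-regularized squared hinge on
#' true-minus-false feature differences within each query.
#'
#' @param queries list of queries from [build_training_set()].
#' @param c_grid candidate regularization constants.
#' @param cv_folds number of cross-validation folds.
#' @param test_fraction held-out test fraction (0.2 = a 4:1 split).
#' @param seed RNG seed for the splits; the optimization is deterministic.
#' @return An object of class `pair_ranker`: fields `w` (named 4-vector),
#'   `provenance` (`"trained"`), `best_c`, `cv_map` (mean CV MAP per C),
#'   `train_map`, `test_map`, `n_queries`.
#' @export
train_ranking_model <- function(queries, c_grid = 10^(0:4), cv_folds = 10L,
                                test_fraction = 0.2, seed = 1L) {
  nq <- length(queries)
  if (nq < 2L * cv_folds)
    stop("need at least ", 2L * cv_folds, " queries for ", cv_folds,
         "-fold cross-validation with a test split")
  feat_all <- do.call(rbind, lapply(queries, `[[`, "features"))
  if (all(feat_all == 0))
    stop("degenerate features: all zero across all queries")
  set.seed(seed)
  perm <- sample.int(nq)
  n_test <- max(1L, round(nq * test_fraction))
  test_ix <- perm[seq_len(n_test)]
  train_ix <- perm[-seq_len(n_test)]

  diffs <- lapply(queries, query_differences)
  fold <- rep_len(seq_len(cv_folds), length(train_ix))[
    sample.int(length(train_ix))]

  score_with <- function(w, ix) {
    qs <- lapply(queries[ix], function(q) {
      q$score <- as.numeric(q$features %*% w); q
    })
    suppressMessages(mean_average_precision(qs))
  }

  cv_map <- vapply(c_grid, function(C) {
    mean(vapply(seq_len(cv_folds), function(k) {
      fit_ix <- train_ix[fold != k]
      D <- do.call(rbind, diffs[fit_ix])
      w <- fit_rank_weights(D, C)
      score_with(w, train_ix[fold == k])
    }, numeric(1)))
  }, numeric(1))
  names(cv_map) <- signif(c_grid, 4)
  best_c <- c_grid[which.max(cv_map)]

  w <- fit_rank_weights(do.call(rbind, diffs[train_ix]), best_c)
  structure(list(w = w, provenance = "trained", best_c = best_c,
                 cv_map = cv_map,
                 train_map = score_with(w, train_ix),
                 test_map = score_with(w, test_ix),
                 n_queries = nq, n_test = n_test),
            class = "pair_ranker")
}

#' The published 4-weight model
#'
#' The reference weight vector of the promoter-trained
#' methylation-expression model: `pos_pearson = -0.0058`,
#' `neg_pearson = 0.0104`, `pos_spearman = -0.0038`,
#' `neg_spearman = 0.0088`. Positive weight on the negative-correlation
#' magnitudes (and negative weight on the positive ones) rewards
#' anti-correlated pairs. Normalized scores are invariant to the overall
#' scale of the weights, so this constant reproduces downstream scoring
#' exactly.
#'
#' @return A `pair_ranker` object with `provenance = "published"`.
#' @export
published_model <- function() {
  structure(list(w = stats::setNames(c(-0.0058, 0.0104, -0.0038, 0.0088),
                                     FEATURE_NAMES),
                 provenance = "published"),
            class = "pair_ranker")
}

#' @export
print.pair_ranker <- function(x, ...) {
  cat("<pair_ranker> linear methylation-expression ranking model (",
      x$provenance, ")\n", sep = "")
  print(signif(x$w, 4))
  if (!is.null(x$best_c))
    cat("regularization C =", x$best_c,
        "| train MAP =", round(x$train_map, 4),
        "| test MAP =", round(x$test_map, 4), "\n")
  invisible(x)
}

#' @export
coef.pair_ranker <- function(object, ...) object$w

#' @export
summary.pair_ranker <- function(object, ...) {
  out <- list(weights = object$w, provenance = object$provenance,
              best_c = object$best_c, cv_map = object$cv_map,
              train_map = object$train_map, test_map = object$test_map,
              n_queries = object$n_queries)
  class(out) <- "summary.pair_ranker"
  out
}

#' @export
print.summary.pair_ranker <- function(x, ...) {
  cat("Linear ranking model over 4 correlation features (",
      x$provenance, ")\n\nWeights:\n", sep = "")
  print(signif(x$weights, 4))
  if (!is.null(x$cv_map)) {
    cat("\nCross-validated MAP by regularization constant:\n")
    print(round(x$cv_map, 4))
    cat("\nChosen C =", x$best_c, "; training MAP =",
        round(x$train_map, 4), "; held-out test MAP =",
        round(x$test_map, 4), "\n")
  }
  invisible(x)
}

#' Predict scores from a fitted ranking model
#'
#' @param object a `pair_ranker`.
#' @param newdata either an n x 4 feature matrix/data.frame, or a pair
#'   data.frame with `gene_id`/`site_id` columns (then `meth` and `expr`
#'   must be supplied).
#' @param meth,expr panel and expression matrix for pair input.
#' @param type `"raw"` for inner-product scores, `"score"` to normalize to
#'   \[0, 1\] over the rows of `newdata` (the scoring universe).
#' @param ... unused.
#' @return Numeric vector of scores.
#' @export
predict.pair_ranker <- function(object, newdata, meth = NULL, expr = NULL,
                                type = c("raw", "score"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata) &&
      all(c("gene_id", "site_id") %in% names(newdata))) {
    if (is.null(meth) || is.null(expr))
      stop("pair input needs `meth` and `expr`")
    newdata <- pair_features(newdata, meth, expr)
  }
  s <- raw_score(object, newdata)
  if (type == "score") normalize_scores(s) else s
}

# Feature matrix for a (gene_id, site_id) pair table.
pair_features <- function(pairs, meth, expr, min_pairs = 10L) {
  si <- match(pairs$site_id, meth$sites$site_id)
  gi <- match(pairs$gene_id, rownames(expr))
  if (anyNA(si)) stop("pair site(s) missing from panel")
  if (anyNA(gi)) stop("pair gene(s) missing from expression matrix")
  feature_matrix(meth$values[si, , drop = FALSE],
                 expr[gi, , drop = FALSE], min_pairs)
}

#' Score a pair table with a model
#'
#' Computes features, raw scores and 0-1 normalized scores for a table of
#' candidate (gene, CpG) pairs. Normalization is over the rows of `pairs`
#' (the scoring universe), so scores from different universes are not
#' directly comparable.
#'
#' @param model a `pair_ranker`.
#' @param pairs data.frame with `gene_id` and `site_id` columns.
#' @param meth a [meth_panel()].
#' @param expr genes x cell types expression matrix.
#' @param min_pairs passed to feature extraction.
#' @return `pairs` with added columns `raw_score` and `score`, plus
#'   `chrom`/`pos` if absent.
#' @export
score_pairs <- function(model, pairs, meth, expr, min_pairs = 10L) {
  f <- pair_features(pairs, meth, expr, min_pairs)
  pairs$raw_score <- raw_score(model, f)
  pairs$score <- normalize_scores(pairs$raw_score)
  if (is.null(pairs$chrom)) {
    si <- match(pairs$site_id, meth$sites$site_id)
    pairs$chrom <- meth$sites$chrom[si]
    pairs$pos <- meth$sites$pos[si]
  }
  pairs
}

#' Score queries and normalize over the evaluation universe
#'
#' Adds `raw` and `score` fields to each query; normalization is over all
#' samples of all queries jointly.
#'
#' @param model a `pair_ranker`.
#' @param queries list of queries (see [build_training_set()]).
#' @return The queries with `raw` and `score` fields.
#' @export
score_queries <- function(model, queries) {
  raws <- lapply(queries, function(q) raw_score(model, q$features))
  norm <- unname(normalize_scores(unlist(raws, use.names = FALSE)))
  off <- 0L
  for (i in seq_along(queries)) {
    n <- length(raws[[i]])
    queries[[i]]$raw <- raws[[i]]
    queries[[i]]$score <- norm[off + seq_len(n)]
    off <- off + n
  }
  queries
}

#' Hypergeometric minimum-rank query p-value
#'
#' For a query with `n` ranked samples of which `T` are true, the minimum
#' rank X of a true sample satisfies
#' `Pr(X = x) = choose(n - x, T - 1) / choose(n, T)` (the event X = x picks
#' the remaining T - 1 true samples from ranks below x), and the p-value is
#' the tail sum `Pr(X <= x) = sum_{i=1..x} choose(n - i, T - 1) /
#' choose(n, T)`.
#'
#' @param n total samples in the query.
#' @param T number of true samples (1 <= T <= n).
#' @param x observed minimum true rank (1 <= x <= n - T + 1).
#' @return `Pr(X <= x)`.
#' @export
query_pvalue <- function(n, T, x) {
  if (T < 1 || T > n) stop("require 1 <= T <= n")
  if (x < 1 || x > n - T + 1) stop("require 1 <= x <= n - T + 1")
  sum(exp(lchoose(n - seq_len(x), T - 1) - lchoose(n, T)))
}

#' Evaluate promoter-gene pairing by matched comparisons
#'
#' The default (`protocol = "matched"`) pits each true sample against one
#' uniformly drawn false sample from its query: a prediction is made when
#' the higher of the two normalized scores reaches `threshold`, and the
#' prediction succeeds when the true member wins (ties count 1/2). By
#' symmetry the success rate of a score-free model is exactly 50%, the
#' null this evaluation is calibrated against. `protocol = "top"` instead
#' makes one prediction per query whose top sample reaches the threshold,
#' succeeding when that top sample is true.
#'
#' @param queries scored queries ([score_queries()]); scores must be
#'   normalized over the evaluation universe.
#' @param threshold score threshold in \[0, 1\].
#' @param seed RNG seed for the matched draw.
#' @param protocol `"matched"` (default) or `"top"`.
#' @return List: `success_rate`, `sensitivity` (predictions per true
#'   sample, resp. per query for `"top"`), `fdr` (= 1 - success_rate),
#'   `n_predictions`, `n_comparisons`.
#' @export
evaluate_promoter_pairing <- function(queries, threshold, seed = 1L,
                                      protocol = c("matched", "top")) {
  protocol <- match.arg(protocol)
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  set.seed(seed)
  if (protocol == "matched") {
    wins <- 0; n_pred <- 0L; n_true <- 0L
    for (q in queries) {
      it <- which(q$label); jf <- which(!q$label)
      if (!length(it) || !length(jf)) next
      n_true <- n_true + length(it)
      for (i in it) {
        j <- jf[sample.int(length(jf), 1L)]
        st <- q$score[i]; sf <- q$score[j]
        if (max(st, sf) >= threshold) {
          n_pred <- n_pred + 1L
          wins <- wins + (st > sf) + 0.5 * (st == sf)
        }
      }
    }
    sr <- if (n_pred > 0) wins / n_pred else NA_real_
    list(success_rate = sr,
         sensitivity = if (n_true > 0) n_pred / n_true else NA_real_,
         fdr = 1 - sr, n_predictions = n_pred, n_comparisons = n_true)
  } else {
    ok <- 0L; n_pred <- 0L
    for (q in queries) {
      if (!any(q$label)) next
      o <- order(-q$score, q$site_id)
      if (q$score[o[1]] >= threshold) {
        n_pred <- n_pred + 1L
        ok <- ok + q$label[o[1]]
      }
    }
    sr <- if (n_pred > 0) ok / n_pred else NA_real_
    list(success_rate = sr,
         sensitivity = if (length(queries)) n_pred / length(queries)
           else NA_real_,
         fdr = 1 - sr, n_predictions = n_pred,
         n_comparisons = length(queries))
  }
}
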