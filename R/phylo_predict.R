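# Phylogeny-only trait predictors. All averaging happens on the natural-log
# doubling-time scale (rates are multiplicative), exponentiated at the end,
# so every estimate is a convex combination of training values on ln scale.

#' Nearest-neighbour growth prediction
#'
#' Predicts a query's doubling time as the geometric mean of the doubling
#' times of its k phylogenetically closest training species. Ties at the
#' k-th distance are all included, making the result independent of input
#' order. A query carrying its own trait is excluded from its neighbour
#' list.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param traits Named doubling times in hours (vector or data frame with
#'   `species`, `doubling_h`).
#' @param query Tip label to predict.
#' @param k Number of neighbours (default 5).
#' @param dmat Optional precomputed patristic matrix.
#' @return A `phylo_prediction` list: `query`, `estimate` (hours), `method`,
#'   `neighbors_used`, `d_p`.
#' @export
nnm_predict <- function(tree, traits, query, k = 5, dmat = NULL) {
  if (is.null(dmat)) {
    validate_phylogeny(tree)
    dmat <- patristic_matrix(tree)
  }
  y <- as_trait_vector(traits)
  if (any(y <= 0)) stop_validation("doubling times must be positive")
  if (!query %in% rownames(dmat)) stop_lookup(sprintf("unknown tip: %s", query))
  training <- setdiff(intersect(names(y), rownames(dmat)), query)
  if (!length(training)) stop_domain("no training species with traits on the tree")
  d <- dmat[query, training]
  ord <- order(d, training)  # label tie-break for determinism
  kk <- min(k, length(d))
  kth <- d[ord[kk]]
  sel <- training[d <= kth]
  est <- exp(mean(log(y[sel])))
  structure(list(query = query, estimate = unname(est), method = "nnm",
                 neighbors_used = length(sel), d_p = mean(d[sel])),
            class = "phylo_prediction")
}

# BM best linear unbiased prediction for one or more query tips given
# training tips on the same tree. Works on the ln scale; returns named
# ln-scale estimates. Factorizes the training covariance once, so sweeping
# many queries against one training set is cheap.
blup_ln <- function(tree, ln_traits, queries, dmat_vcv = NULL) {
  training <- names(ln_traits)
  if (length(training) < 2) stop_domain("need at least 2 training species")
  C <- if (is.null(dmat_vcv)) ape::vcv(tree) else dmat_vcv
  miss <- setdiff(c(training, queries), rownames(C))
  if (length(miss)) stop_lookup(sprintf("tips not in tree: %s",
                                        paste(miss, collapse = ", ")))
  Ct <- C[training, training, drop = FALSE]
  ch <- tryCatch(chol(Ct), error = function(e)
    stop_numeric("singular BM covariance among training tips"))
  Cinv <- chol2inv(ch)
  y <- ln_traits
  one <- rep(1, length(y))
  mu <- as.numeric(crossprod(one, Cinv %*% y)) / sum(Cinv)
  w <- Cinv %*% (y - mu)
  cq <- C[queries, training, drop = FALSE]
  setNames(as.numeric(mu + cq %*% w), queries)
}

#' Brownian-motion growth prediction (independent-contrasts estimator)
#'
#' Predicts a query's doubling time as the Brownian-motion best linear
#' unbiased prediction given the training tips: the GLS estimate
#' `mu + c_q' C^{-1} (y - mu)` on the ln scale, where C is the BM tip
#' covariance (shared root paths) and `c_q` the query-training covariances.
#' This coincides with the ancestral-state estimate at the query's
#' attachment point produced by Felsenstein's contrasts pruning recursion
#' (each cherry collapsed to a 1/branch-length weighted average with an
#' extended branch), and therefore with distance-weighted neighbour
#' averaging under BM.
#'
#' @inheritParams nnm_predict
#' @return A `phylo_prediction` list (`method = "phylopred"`).
#' @export
phylopred_predict <- function(tree, traits, query, dmat = NULL) {
  validate_phylogeny(tree)
  y <- as_trait_vector(traits)
  if (any(y <= 0)) stop_validation("doubling times must be positive")
  if (!query %in% tree$tip.label) stop_lookup(sprintf("unknown tip: %s", query))
  training <- setdiff(intersect(names(y), tree$tip.label), query)
  if (length(training) < 2) stop_domain("need at least 2 training species")
  # prune tips that are neither training nor the query
  keep <- c(training, query)
  sub <- if (length(keep) < ape::Ntip(tree)) ape::keep.tip(tree, keep) else tree
  est_ln <- blup_ln(sub, log(y[training]), query)
  dp <- mean_k_nearest_distance(tree, query, training, k = 5, dmat = dmat)
  structure(list(query = query, estimate = unname(exp(est_ln)),
                 method = "phylopred", neighbors_used = length(training),
                 d_p = dp),
            class = "phylo_prediction")
}

#' @export
print.phylo_prediction <- function(x, ...) {
  cat(sprintf("%s(%s) = %.3g h (neighbors %d, D_p %.3g)\n", x$method,
              x$query, x$estimate, x$neighbors_used, x$d_p))
  invisible(x)
}
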