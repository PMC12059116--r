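# Phylogenetic-signal statistics under the Brownian-motion (BM) model.
# Both statistics work on the GLS machinery implied by the BM tip
# covariance C (shared root-to-MRCA path lengths).

# Align traits with tips; returns list(y, C, labels). Traits enter on the
# natural-log scale when log_transform = TRUE (the package convention for
# doubling times).
signal_setup <- function(tree, traits, log_transform = FALSE, min_n = 4) {
  validate_phylogeny(tree)
  y <- as_trait_vector(traits)
  common <- intersect(tree$tip.label, names(y))
  if (length(common) < min_n)
    stop_validation(sprintf("need at least %d species with traits on the tree", min_n))
  if (length(common) < length(y) && !any(names(y) %in% tree$tip.label))
    stop_validation("no trait species match the tree tips")
  sub <- if (length(common) < ape::Ntip(tree)) ape::keep.tip(tree, common) else tree
  y <- y[sub$tip.label]
  if (log_transform) {
    if (any(y <= 0)) stop_validation("log transform requires positive traits")
    y <- log(y)
  }
  if (isTRUE(all.equal(var(y), 0)) || var(y) == 0)
    stop_degenerate("trait is constant across species")
  C <- ape::vcv(sub)
  list(y = y, C = C, tree = sub)
}

# GLS pieces under covariance C: phylogenetic mean and the two mean squared
# errors entering Blomberg's K.
gls_mse <- function(y, Cinv) {
  n <- length(y)
  one <- rep(1, n)
  denom <- sum(Cinv)
  a_hat <- as.numeric(crossprod(one, Cinv %*% y)) / denom
  r <- y - a_hat
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(crossprod(r, Cinv %*% r)) / (n - 1)
  c(mse0 = mse0, mse = mse)
}

#' Blomberg's K
#'
#' Variance-ratio statistic of phylogenetic signal: the observed ratio of
#' the ordinary to the GLS mean squared error around the phylogenetically
#' corrected mean, scaled by its Brownian-motion expectation, so K = 1 under
#' BM, K -> 0 with no signal. Significance by permuting trait values across
#' tips and asking whether the observed GLS error is smaller than permuted
#' ones (one-sided).
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param traits Named numeric vector (or data frame) of trait values; at
#'   least 4 species must match tips and the trait must vary.
#' @param test Run the permutation test (default TRUE).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed for the permutation test.
#' @param log_transform Analyze ln(trait) (default FALSE).
#' @return A `signal_result` list: `statistic_name`, `estimate`, `p_value`,
#'   `n_species`.
#' @export
blomberg_k <- function(tree, traits, test = TRUE, n_perm = 999, seed = NULL,
                       log_transform = FALSE) {
  s <- signal_setup(tree, traits, log_transform)
  y <- s$y; C <- s$C; n <- length(y)
  Cinv <- chol2inv(chol(C))
  obs <- gls_mse(y, Cinv)
  expected_ratio <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  K <- (obs["mse0"] / obs["mse"]) / expected_ratio
  p <- NA_real_
  if (test) {
    p <- with_seed(seed, {
      perm_mse <- vapply(seq_len(n_perm), function(i) {
        gls_mse(sample(y), Cinv)["mse"]
      }, numeric(1))
      (1 + sum(perm_mse <= obs["mse"])) / (n_perm + 1)
    })
  }
  structure(list(statistic_name = "K", estimate = unname(K), p_value = p,
                 n_species = n, n_perm = if (test) n_perm else 0L),
            class = "signal_result")
}

# Profile log-likelihood of the lambda model: covariance C with off-diagonal
# scaled by lambda, diagonal untouched; mean and rate profiled out.
lambda_loglik <- function(lambda, y, C) {
  n <- length(y)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Cinv <- chol2inv(ch)
  one <- rep(1, n)
  mu <- as.numeric(crossprod(one, Cinv %*% y)) / sum(Cinv)
  r <- y - mu
  s2 <- as.numeric(crossprod(r, Cinv %*% r)) / n
  if (s2 <= 0) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  -n / 2 * log(2 * pi * s2) - logdet / 2 - n / 2
}

#' Pagel's lambda
#'
#' Maximum-likelihood estimate of the branch-length transformation lambda in
#' \[0, 1\] under Brownian motion (off-diagonal tip covariances scaled by
#' lambda). lambda = 1 is pure BM; lambda = 0 removes all phylogenetic
#' covariance. The p-value is a likelihood-ratio test against lambda = 0
#' (chi-squared, 1 df). Optimization is bounded scalar maximization with
#' multi-start (intervals anchored at 0, 0.5 and 1, tolerance 1e-8). On a
#' star phylogeny lambda is unidentifiable and the result is flagged.
#'
#' @inheritParams blomberg_k
#' @return A `signal_result` list with `estimate`, `p_value`,
#'   `log_likelihoods` (at the estimate and at lambda = 0), `n_species`,
#'   and `flag` ("ok" or "star").
#' @export
pagel_lambda <- function(tree, traits, log_transform = FALSE) {
  s <- signal_setup(tree, traits, log_transform)
  y <- s$y; C <- s$C; n <- length(y)
  offdiag <- C; diag(offdiag) <- 0
  if (max(abs(offdiag)) <= 1e-12 * max(diag(C))) {
    return(structure(list(statistic_name = "lambda", estimate = NA_real_,
                          p_value = NA_real_,
                          log_likelihoods = c(at_estimate = NA_real_,
                                              at_null = lambda_loglik(0, y, C)),
                          n_species = n, flag = "star"),
                     class = "signal_result"))
  }
  f <- function(l) lambda_loglik(l, y, C)
  cands <- list(c(0, 0.5), c(0.5, 1))
  opts <- lapply(cands, function(iv)
    optimize(f, interval = iv, maximum = TRUE, tol = 1e-8))
  vals <- c(vapply(opts, `[[`, numeric(1), "objective"), f(0), f(1))
  args <- c(vapply(opts, `[[`, numeric(1), "maximum"), 0, 1)
  if (all(!is.finite(vals)))
    stop_numeric("lambda likelihood not finite anywhere on [0, 1]")
  best <- which.max(vals)
  lam <- min(max(args[best], 0), 1)
  ll_hat <- vals[best]
  ll0 <- f(0)
  lr <- max(0, 2 * (ll_hat - ll0))
  p <- pchisq(lr, df = 1, lower.tail = FALSE)
  structure(list(statistic_name = "lambda", estimate = lam, p_value = p,
                 log_likelihoods = c(at_estimate = ll_hat, at_null = ll0),
                 n_species = n, flag = "ok"),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s = %.4g (n = %d, p = %.4g)\n", x$statistic_name,
              x$estimate, x$n_species, x$p_value))
  invisible(x)
}

#' Write signal results as TSV
#'
#' @param results A list of `signal_result` objects.
#' @param path Output path.
#' @export
write_signal_tsv <- function(results, path) {
  if (inherits(results, "signal_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(statistic = r$statistic_name, estimate = r$estimate,
               p_value = r$p_value, n_species = r$n_species)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
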