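# The hybrid core: a logistic gate scoring the probability that the CUB
# regression beats the phylogenetic prediction for a given query, and three
# ways of combining the two component estimates with that probability.

#' Gate probability
#'
#' Evaluates the trained logistic gate: `P = logistic(beta0 + beta_y *
#' ln(y_cub) + beta_d * d_p + beta_yd * ln(y_cub) * d_p)`, the probability
#' that the CUB-based estimate outperforms the phylogenetic estimate for a
#' query with CUB prediction `y_cub` (hours) at phylogenetic distance `d_p`
#' from its 5 nearest training relatives.
#'
#' @param model A `gate_model` from [fit_gate()].
#' @param y_cub CUB-predicted doubling time in hours (> 0).
#' @param d_p Mean distance to the 5 nearest training tips (>= 0).
#' @return Probability in (0, 1).
#' @export
gate_probability <- function(model, y_cub, d_p) {
  if (!inherits(model, "gate_model")) stop_validation("not a gate_model")
  if (!all(is.finite(y_cub)) || any(y_cub <= 0))
    stop_domain("y_cub must be finite and positive")
  if (!all(is.finite(d_p)) || any(d_p < 0))
    stop_domain("d_p must be finite and non-negative")
  ly <- log(y_cub)
  plogis(model$beta0 + model$beta_y * ly + model$beta_d * d_p +
           model$beta_yd * ly * d_p)
}

check_combine_args <- function(y_cub, y_phylo, p) {
  if (any(y_cub <= 0) || any(y_phylo <= 0))
    stop_domain("component estimates must be positive")
  if (any(p < 0) || any(p > 1)) stop_domain("p must lie in [0, 1]")
}

#' Combine component predictions
#'
#' Three combination modes for the two component estimates, weighted by the
#' gate probability `p` (the weight on the CUB estimate):
#' * arithmetic: `y_cub * p + y_phylo * (1 - p)` (the default mode);
#' * geometric: `y_cub^p * y_phylo^(1 - p)`;
#' * binary: `y_cub` when `p > 0.5`, else `y_phylo`.
#'
#' @param y_cub,y_phylo Component doubling-time estimates in hours (> 0).
#' @param p Gate probability in \[0, 1\].
#' @return Combined doubling time in hours.
#' @export
combine_arithmetic <- function(y_cub, y_phylo, p) {
  check_combine_args(y_cub, y_phylo, p)
  y_cub * p + y_phylo * (1 - p)
}

#' @rdname combine_arithmetic
#' @export
combine_geometric <- function(y_cub, y_phylo, p) {
  check_combine_args(y_cub, y_phylo, p)
  y_cub^p * y_phylo^(1 - p)
}

#' @rdname combine_arithmetic
#' @export
combine_binary <- function(y_cub, y_phylo, p) {
  check_combine_args(y_cub, y_phylo, p)
  ifelse(p > 0.5, y_cub, y_phylo)
}

combine_mode <- function(mode) {
  switch(match.arg(mode, c("arithmetic", "geometric", "binary")),
         arithmetic = combine_arithmetic,
         geometric = combine_geometric,
         binary = combine_binary)
}

# Ridge-penalized logistic fit via Newton iterations; used when the plain
# ML fit separates. Intercept unpenalized.
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Fit the logistic gate
#'
#' Maximum-likelihood logistic regression of the binary outcome "the CUB
#' estimate outperformed the phylogenetic estimate" on `ln(y_cub)`, `d_p`
#' and their interaction. Labels should be produced out-of-sample (see
#' [derive_gate_labels()]). When the classes are perfectly separable the
#' plain fit diverges; a small ridge penalty (default 1e-4) is then applied
#' automatically and the result flagged, so coefficients are always finite.
#'
#' @param records Data frame with columns `y_cub` (hours), `d_p`, `label`
#'   (0/1).
#' @param ridge Ridge strength used on separation (default 1e-4).
#' @param min_n Minimum records (default 20).
#' @return A `gate_model` list: `beta0`, `beta_y`, `beta_d`, `beta_yd`,
#'   `n`, `converged`, `separation`, `se`.
#' @export
fit_gate <- function(records, ridge = 1e-4, min_n = 20) {
  need <- c("y_cub", "d_p", "label")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_validation("records need columns y_cub, d_p, label")
  records <- records[stats::complete.cases(records[need]), ]
  if (nrow(records) < min_n)
    stop_fit(sprintf("need at least %d labeled records, got %d", min_n,
                     nrow(records)))
  if (length(unique(records$label)) < 2)
    stop_fit("labels are single-class: the gate has no contrast to learn")
  df <- data.frame(label = as.integer(records$label),
                   ly = log(records$y_cub), dp = records$d_p)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(label ~ ly * dp, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (sep || anyNA(beta) || any(abs(beta) > 1e3)) {
    sep <- TRUE
    X <- cbind(1, df$ly, df$dp, df$ly * df$dp)
    beta <- ridge_logistic(X, df$label, lambda = ridge)
    names(beta) <- c("(Intercept)", "ly", "dp", "ly:dp")
    se <- rep(NA_real_, 4)
    warning("separation detected in gate fit; ridge-stabilized coefficients returned",
            call. = FALSE)
  }
  structure(list(beta0 = unname(beta["(Intercept)"]),
                 beta_y = unname(beta["ly"]),
                 beta_d = unname(beta["dp"]),
                 beta_yd = unname(beta["ly:dp"]),
                 n = nrow(df), converged = isTRUE(fit$converged) || sep,
                 separation = sep,
                 se = setNames(unname(se), c("beta0", "beta_y", "beta_d", "beta_yd"))),
            class = "gate_model")
}

#' @export
print.gate_model <- function(x, ...) {
  cat(sprintf(
    "logistic gate (n = %d%s): logit(P) = %.3g %+.3g ln(y) %+.3g D_p %+.3g ln(y)*D_p\n",
    x$n, if (x$separation) ", ridge-stabilized" else "",
    x$beta0, x$beta_y, x$beta_d, x$beta_yd))
  invisible(x)
}

# A degenerate gate returning a fixed probability; used as a fallback when
# gate labels carry no contrast (all 0 or all 1).
constant_gate <- function(p) {
  structure(list(beta0 = stats::qlogis(min(max(p, 1e-6), 1 - 1e-6)),
                 beta_y = 0, beta_d = 0, beta_yd = 0,
                 n = 0L, converged = TRUE, separation = FALSE,
                 se = rep(NA_real_, 4)),
            class = "gate_model")
}

#' Hybrid growth prediction for one query
#'
#' Runs the full gated prediction: CUB estimate from the genome's codon
#' usage, Brownian-motion phylogenetic estimate from the tree and training
#' traits, gate probability from the two, and the mode-specific
#' combination. When the genome fails the CUB quality filter the prediction
#' falls back to the phylogenetic estimate (gate forced to 0, flagged);
#' when the query is missing from the tree it falls back to the CUB
#' estimate (gate forced to 1, flagged).
#'
#' @param cub_model A fitted `cub_model`.
#' @param gate A fitted `gate_model`.
#' @param tree Reference phylogeny containing the query tip.
#' @param traits Training doubling times (vector or data frame).
#' @param profile A `cub_profile` for the query genome, or a
#'   `genome_record` (profiled on the fly), or NULL when the genome failed
#'   upstream.
#' @param query Query species id; defaults to the profile's genome id.
#' @param mode Combination mode (default "arithmetic").
#' @param k Neighbours for D_p (default 5).
#' @param ogt Optional optimal growth temperature for the CUB component.
#' @param dmat Optional precomputed patristic matrix.
#' @return A `growth_prediction` one-row data frame: `query`, `y_cub`,
#'   `y_phylo`, `d_p`, `p_gate`, `y_hybrid`, `mode`, `flags`.
#' @export
hybrid_predict <- function(cub_model, gate, tree, traits, profile,
                           query = NULL, mode = "arithmetic", k = 5,
                           ogt = NULL, dmat = NULL) {
  mode <- match.arg(mode, c("arithmetic", "geometric", "binary"))
  if (inherits(profile, "genome_record"))
    profile <- tryCatch(cub_profile(profile), phygrow_quality_error = identity)
  failed_cub <- is.null(profile) || inherits(profile, "condition")
  if (is.null(query))
    query <- if (!failed_cub) profile$genome_id else
      stop_validation("query id required when no CUB profile is available")

  flags <- character(0)
  y_cub <- NA_real_
  if (!failed_cub) y_cub <- predict_cub(cub_model, profile, ogt = ogt)
  else flags <- c(flags, "cub_failed")

  in_tree <- query %in% tree$tip.label
  y_phylo <- NA_real_
  d_p <- NA_real_
  if (in_tree) {
    pp <- phylopred_predict(tree, traits, query, dmat = dmat)
    y_phylo <- pp$estimate
    d_p <- mean_k_nearest_distance(tree, query,
                                   setdiff(names(as_trait_vector(traits)), query),
                                   k = k, dmat = dmat)
  } else flags <- c(flags, "no_phylogeny")

  if (failed_cub && !in_tree)
    stop_domain(sprintf("query %s has neither a usable genome nor a tree position", query))

  if (failed_cub) {
    p <- 0; y_hybrid <- y_phylo
  } else if (!in_tree) {
    p <- 1; y_hybrid <- y_cub
  } else {
    p <- gate_probability(gate, y_cub, d_p)
    y_hybrid <- combine_mode(mode)(y_cub, y_phylo, p)
  }
  out <- data.frame(query = query, y_cub = y_cub, y_phylo = y_phylo,
                    d_p = d_p, p_gate = p, y_hybrid = y_hybrid, mode = mode,
                    flags = paste(flags, collapse = ";"),
                    stringsAsFactors = FALSE)
  class(out) <- c("growth_prediction", class(out))
  out
}

#' Serialize a gate model
#'
#' @param model A `gate_model`.
#' @param path Output path.
#' @export
write_gate_model <- function(model, path) {
  lines <- c("format=phygrow_gate_model/1",
             sprintf("version=%s", as.character(packageVersion("phygrow"))),
             sprintf("n=%d", model$n),
             sprintf("separation=%s", model$separation),
             sprintf("beta0=%.17g", model$beta0),
             sprintf("beta_y=%.17g", model$beta_y),
             sprintf("beta_d=%.17g", model$beta_d),
             sprintf("beta_yd=%.17g", model$beta_yd))
  writeLines(lines, path)
  invisible(path)
}

#' Read a serialized gate model
#'
#' @param path Path written by [write_gate_model()].
#' @return A `gate_model`.
#' @export
read_gate_model <- function(path) {
  kv <- read_kv(path, "phygrow_gate_model/1")
  structure(list(beta0 = as.numeric(kv[["beta0"]]),
                 beta_y = as.numeric(kv[["beta_y"]]),
                 beta_d = as.numeric(kv[["beta_d"]]),
                 beta_yd = as.numeric(kv[["beta_yd"]]),
                 n = as.integer(kv[["n"]]),
                 converged = TRUE,
                 separation = as.logical(kv[["separation"]]),
                 se = rep(NA_real_, 4)),
            class = "gate_model")
}
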