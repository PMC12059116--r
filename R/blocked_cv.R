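# Phylogenetically blocked cross-validation: folds are clades obtained by
# cutting the tree at a uniform depth, so each test set is an entire
# lineage held out from training. Sweeping the number of clades n sweeps
# the phylogenetic distance between training and test data.

#' Cross-validation configuration
#'
#' @param n_values Clade counts to sweep (default 10 to 410 in steps of 10,
#'   one scenario per value).
#' @param slow_threshold Doubling time (h) above which a species counts as
#'   slow-growing (default 5; species at exactly 5 h are "fast").
#' @param fast_inset_threshold Doubling time (h) below which a species
#'   enters the very-fast stratum (default 0.5).
#' @param k Neighbours for the fold-level distance D_p (default 5).
#' @param seed Integer seed passed to stochastic predictors.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_values = seq(10, 410, by = 10), slow_threshold = 5,
                      fast_inset_threshold = 0.5, k = 5, seed = 1) {
  if (any(diff(n_values) <= 0) || any(n_values < 2))
    stop_domain("n_values must be strictly increasing and >= 2")
  structure(list(n_values = as.integer(n_values),
                 slow_threshold = slow_threshold,
                 fast_inset_threshold = fast_inset_threshold,
                 k = k, seed = seed),
            class = "cv_config")
}

#' Build blocked folds by cutting the tree into n clades
#'
#' @param tree A rooted `phylo` object.
#' @param n Number of clades (>= 2; with n = 1 there is no training data).
#' @return A list of folds, each `list(test, train)` of tip labels, with
#'   attributes `n` (achieved clade count), `requested_n`, `cut_depth`,
#'   `exact`.
#' @export
make_folds <- function(tree, n) {
  if (n < 2) stop_domain("n must be >= 2 (n = 1 leaves no training data)")
  part <- cut_into_clades(tree, n)
  tips <- tree$tip.label
  folds <- lapply(part$clades, function(cl)
    list(test = cl, train = setdiff(tips, cl)))
  attr(folds, "n") <- part$n_clades
  attr(folds, "requested_n") <- part$requested_n
  attr(folds, "cut_depth") <- part$cut_depth
  attr(folds, "exact") <- part$exact
  folds
}

# ---- Predictor interface -------------------------------------------------
# A predictor is a list(name, fit, predict):
#   fit(tree, traits, train_tips, dmat)          -> opaque state
#   predict(state, tree, traits, test_tips, dmat) -> named doubling times (h)
# Species a predictor cannot handle come back NA and are recorded, never
# silently dropped.

#' Built-in predictors for blocked cross-validation
#'
#' Constructors for the predictors compared in the package's evaluation:
#' `predictor_nnm()` (geometric mean of the k nearest training species),
#' `predictor_phylopred()` (Brownian-motion BLUP), `predictor_cub()` (the
#' codon-usage regression, re-fit on each training fold), and
#' `predictor_hybrid()` (the full gated ensemble: per-fold CUB fit, gate
#' labels from an inner blocked CV on the training clades, logistic gate,
#' mode-specific combination).
#'
#' @param k Neighbours for the NNM (default 5).
#' @param profiles Named list of `cub_profile` objects (names = species).
#' @param use_ogt Pass OGT to the CUB regression (needs `ogt` in traits).
#' @param ogt Named OGT vector for prediction-time lookups.
#' @param mode Combination mode for the hybrid (default "arithmetic").
#' @param inner_n Clade count(s) of the inner CV that generates gate labels
#'   (default NULL: adaptive depths at 10%, 30% and 80% of the training
#'   size, pooled; see [derive_gate_labels()]).
#' @param min_cub_n Minimum genomes for a CUB fit (default 10).
#' @return A predictor list usable with [cv_evaluate()] and [cv_sweep()].
#' @name predictors
NULL

#' @rdname predictors
#' @export
predictor_nnm <- function(k = 5) {
  list(name = "nnm",
       fit = function(tree, traits, train_tips, dmat) {
         y <- as_trait_vector(traits)
         y[intersect(train_tips, names(y))]
       },
       predict = function(state, tree, traits, test_tips, dmat) {
         vapply(test_tips, function(q) {
           tryCatch(nnm_predict(tree, state, q, k = k, dmat = dmat)$estimate,
                    phygrow_error = function(e) NA_real_)
         }, numeric(1))
       })
}

#' @rdname predictors
#' @export
predictor_phylopred <- function() {
  cache <- new.env(parent = emptyenv())
  list(name = "phylopred",
       fit = function(tree, traits, train_tips, dmat) {
         y <- as_trait_vector(traits)
         y <- y[intersect(train_tips, names(y))]
         if (length(y) < 2) stop_domain("fewer than 2 training species")
         if (is.null(cache$C)) cache$C <- ape::vcv(tree)
         list(ln_y = log(y), vcv = cache$C)
       },
       predict = function(state, tree, traits, test_tips, dmat) {
         est <- blup_ln(tree, state$ln_y, test_tips, dmat_vcv = state$vcv)
         exp(est)
       })
}

#' @rdname predictors
#' @export
predictor_cub <- function(profiles, use_ogt = FALSE, ogt = NULL,
                          min_cub_n = 10) {
  list(name = "cub",
       fit = function(tree, traits, train_tips, dmat) {
         pr <- profiles[intersect(train_tips, names(profiles))]
         if (!length(pr)) stop_domain("no training species with CUB profiles")
         fit_cub_model(pr, traits, use_ogt = use_ogt, min_n = min_cub_n)
       },
       predict = function(state, tree, traits, test_tips, dmat) {
         vapply(test_tips, function(q) {
           pr <- profiles[[q]]
           if (is.null(pr)) return(NA_real_)
           predict_cub(state, pr, ogt = if (state$use_ogt) ogt[[q]] else NULL)
         }, numeric(1))
       })
}

#' @rdname predictors
#' @export
predictor_hybrid <- function(profiles, mode = "arithmetic",
                             inner_n = NULL,
                             use_ogt = FALSE, ogt = NULL, min_cub_n = 10,
                             k = 5) {
  cache <- new.env(parent = emptyenv())
  list(name = paste0("hybrid_", mode),
       fit = function(tree, traits, train_tips, dmat) {
         y <- as_trait_vector(traits)
         train_tips <- intersect(train_tips, names(y))
         sub <- ape::keep.tip(tree, train_tips)
         if (is.null(cache$C)) cache$C <- ape::vcv(tree)
         labels <- derive_gate_labels(sub, traits, profiles, inner_n = inner_n,
                                      use_ogt = use_ogt, ogt = ogt,
                                      min_cub_n = min_cub_n, k = k,
                                      dmat = dmat, C = cache$C)
         gate <- tryCatch(fit_gate(labels, min_n = 10),
                          phygrow_fit_error = function(e)
                            constant_gate(mean(labels$label)))
         cub <- fit_cub_model(profiles[intersect(train_tips, names(profiles))],
                              traits, use_ogt = use_ogt, min_n = min_cub_n)
         list(gate = gate, cub = cub, ln_y = log(y[train_tips]),
              vcv = cache$C, train = train_tips)
       },
       predict = function(state, tree, traits, test_tips, dmat) {
         ln_phylo <- blup_ln(tree, state$ln_y, test_tips, dmat_vcv = state$vcv)
         vapply(test_tips, function(q) {
           y_ph <- exp(ln_phylo[[q]])
           pr <- profiles[[q]]
           if (is.null(pr)) return(y_ph)  # CUB fallback: gate forced to 0
           y_cub <- predict_cub(state$cub, pr,
                                ogt = if (state$cub$use_ogt) ogt[[q]] else NULL)
           dp <- mean_k_nearest_distance(tree, q, state$train, k = k,
                                         dmat = dmat)
           p <- gate_probability(state$gate, y_cub, dp)
           combine_mode(mode)(y_cub, y_ph, p)
         }, numeric(1))
       })
}

# Stratified ln-scale MSE for one fold.
strata_mse <- function(pred, truth, slow_threshold, fast_inset_threshold) {
  err <- (log(pred) - log(truth))^2
  strata <- list(all = rep(TRUE, length(truth)),
                 slow = truth > slow_threshold,
                 fast = truth <= slow_threshold,
                 fast_inset = truth < fast_inset_threshold)
  lapply(strata, function(sel) {
    sel <- sel & !is.na(err)
    if (!any(sel)) return(c(mse = NA_real_, n = 0))
    c(mse = mean(err[sel]), n = sum(sel))
  })
}

#' Evaluate predictors on blocked folds
#'
#' Fits every predictor on each fold's training tips and scores its test
#' predictions as mean squared error on the natural-log doubling-time
#' scale, overall and within growth strata (slow: > `slow_threshold` h;
#' fast: <= threshold; fast_inset: < `fast_inset_threshold` h). Each fold
#' also records its phylogenetic distance `fold_dp`: the minimum over test
#' species of the per-species mean distance to the 5 nearest training
#' species. Predictor failures on a fold are recorded with a reason, never
#' silently dropped.
#'
#' @param tree A `phylo` object.
#' @param traits Doubling times (vector or data frame).
#' @param folds Folds from [make_folds()].
#' @param predictors Named or unnamed list of predictor objects (see
#'   [predictors]).
#' @param config A `cv_config` (thresholds and k).
#' @param dmat Optional precomputed patristic matrix.
#' @return Data frame with one row per (fold, predictor, stratum):
#'   `n`, `cut_depth`, `fold`, `fold_dp`, `predictor`, `stratum`, `mse`,
#'   `n_species`, `status`.
#' @export
cv_evaluate <- function(tree, traits, folds, predictors,
                        config = cv_config(), dmat = NULL) {
  validate_phylogeny(tree)
  y <- as_trait_vector(traits)
  if (is.null(dmat)) dmat <- patristic_matrix(tree)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors))))
    names(predictors) <- vapply(predictors, `[[`, character(1), "name")
  n_ach <- attr(folds, "n")
  cut_depth <- attr(folds, "cut_depth")
  rows <- list()
  for (f in seq_along(folds)) {
    test <- intersect(folds[[f]]$test, names(y))
    train <- intersect(folds[[f]]$train, names(y))
    if (!length(test)) next
    fold_dp <- min(vapply(test, function(q)
      mean_k_nearest_distance(tree, q, train, k = config$k, dmat = dmat),
      numeric(1)))
    for (pn in names(predictors)) {
      pr <- predictors[[pn]]
      res <- tryCatch({
        state <- pr$fit(tree, traits, train, dmat)
        pred <- pr$predict(state, tree, traits, test, dmat)
        list(pred = pred[test], status = "ok")
      }, phygrow_error = function(e)
        list(pred = NULL, status = conditionMessage(e)),
        error = function(e) list(pred = NULL, status = conditionMessage(e)))
      if (identical(res$status, "ok")) {
        sm <- strata_mse(res$pred, y[test], config$slow_threshold,
                         config$fast_inset_threshold)
        for (st in names(sm)) {
          rows[[length(rows) + 1L]] <- data.frame(
            n = n_ach, cut_depth = cut_depth, fold = f, fold_dp = fold_dp,
            predictor = pn, stratum = st, mse = sm[[st]][["mse"]],
            n_species = sm[[st]][["n"]], status = "ok",
            stringsAsFactors = FALSE)
        }
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          n = n_ach, cut_depth = cut_depth, fold = f, fold_dp = fold_dp,
          predictor = pn, stratum = "all", mse = NA_real_,
          n_species = length(test), status = res$status,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Sweep blocked cross-validation over cutting depths
#'
#' Runs [cv_evaluate()] for every clade count in `config$n_values` and
#' aggregates per (n, predictor, stratum): mean MSE over folds (equal
#' weights), the cut depth, and the per-n minimum fold distance
#' `fold_dp_min`. One aggregate record per n per predictor per stratum is
#' a "scenario".
#'
#' @inheritParams cv_evaluate
#' @return A list: `summary` (aggregate data frame with `n`, `requested_n`,
#'   `cut_depth`, `fold_dp_min`, `predictor`, `stratum`, `mse`,
#'   `n_species`, `n_folds_ok`) and `folds` (the per-fold records).
#' @export
cv_sweep <- function(tree, traits, predictors, config = cv_config(),
                     dmat = NULL) {
  validate_phylogeny(tree)
  if (max(config$n_values) > ape::Ntip(tree))
    stop_domain("n_values exceed the number of tips")
  if (is.null(dmat)) dmat <- patristic_matrix(tree)
  per_fold <- list()
  summaries <- list()
  for (n in config$n_values) {
    folds <- withCallingHandlers(make_folds(tree, n),
                                 warning = function(w) invokeRestart("muffleWarning"))
    fr <- cv_evaluate(tree, traits, folds, predictors, config, dmat)
    fr$requested_n <- n
    per_fold[[as.character(n)]] <- fr
    ok <- fr[fr$status == "ok" & !is.na(fr$mse), ]
    if (!nrow(ok)) next
    agg <- do.call(rbind, lapply(split(ok, list(ok$predictor, ok$stratum),
                                       drop = TRUE), function(g) {
      data.frame(n = g$n[1], requested_n = n, cut_depth = g$cut_depth[1],
                 fold_dp_min = min(fr$fold_dp), predictor = g$predictor[1],
                 stratum = g$stratum[1],
                 mse = mean(g$mse), n_species = sum(g$n_species),
                 n_folds_ok = nrow(g), stringsAsFactors = FALSE)
    }))
    summaries[[as.character(n)]] <- agg
  }
  out <- list(summary = do.call(rbind, summaries),
              folds = do.call(rbind, per_fold))
  rownames(out$summary) <- NULL
  rownames(out$folds) <- NULL
  class(out) <- "cv_sweep"
  out
}

#' Write a sweep summary as tidy TSV
#'
#' @param sweep A `cv_sweep` result.
#' @param path Output path.
#' @param header Optional comment lines written before the table.
#' @export
write_sweep_tsv <- function(sweep, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(sweep$summary, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Derive out-of-sample gate labels by inner blocked CV
#'
#' Produces the training records for the logistic gate: for every species
#' in the training data, an out-of-sample CUB prediction and phylogenetic
#' (BM BLUP) prediction obtained by leave-one-clade-out CV at `inner_n`
#' clades, the species' distance `d_p` to its 5 nearest training
#' relatives, and the binary label `1` when the CUB squared error on ln
#' doubling time is less than or equal to the phylogenetic one (ties
#' favour the globally stabler CUB model).
#'
#' @param tree Phylogeny of the training species.
#' @param traits Doubling times.
#' @param profiles Named list of `cub_profile`s.
#' @param inner_n Clade counts of the inner CV. A vector pools label
#'   records across several cutting depths; the default (NULL) uses clade
#'   counts at 10%, 30% and 80% of the available species, so the gate sees
#'   out-of-sample comparisons across the whole range of phylogenetic
#'   distances it will be applied to — from deep cuts (distant training
#'   data) to near-leave-one-out (close relatives). Values are clipped to
#'   the available species count.
#' @param use_ogt,ogt OGT covariate handling as in [predictor_cub()].
#' @param min_cub_n Minimum genomes for an inner CUB fit (default 10).
#' @param k Neighbours for `d_p` (default 5).
#' @param dmat,C Optional precomputed patristic and BM covariance matrices
#'   of the full tree (subset internally); pruning does not change either.
#' @return Data frame with columns `species`, `y_cub`, `y_phylo`, `d_p`,
#'   `label`.
#' @export
derive_gate_labels <- function(tree, traits, profiles, inner_n = NULL,
                               use_ogt = FALSE, ogt = NULL, min_cub_n = 10,
                               k = 5, dmat = NULL, C = NULL) {
  validate_phylogeny(tree)
  y <- as_trait_vector(traits)
  species <- Reduce(intersect, list(tree$tip.label, names(y), names(profiles)))
  if (!length(species))
    stop_domain("no species shared between tree, traits and CUB profiles")
  sub <- if (length(species) < ape::Ntip(tree)) ape::keep.tip(tree, species) else tree
  if (is.null(inner_n))
    inner_n <- round(length(species) * c(0.1, 0.3, 0.8))
  inner_n <- unique(pmax(2L, pmin(as.integer(inner_n),
                                  length(species) - 1L)))
  folds <- list()
  for (n_in in inner_n) {
    folds <- c(folds,
               withCallingHandlers(make_folds(sub, n_in),
                                   warning = function(w) invokeRestart("muffleWarning")))
  }
  # pruning does not change tip-pair path lengths or shared depths, so
  # precomputed full-tree matrices can simply be subset
  dmat <- if (is.null(dmat)) patristic_matrix(sub) else dmat[species, species]
  C <- if (is.null(C)) ape::vcv(sub) else C[species, species]
  cub_he <- vapply(profiles[species], `[[`, numeric(1), "cub_he")
  ln_y <- log(y[species])
  acc <- list()
  for (f in folds) {
    test <- intersect(f$test, species)
    train <- intersect(f$train, species)
    if (!length(test) || length(train) < max(2, min_cub_n)) next
    x_tr <- cub_he[train]
    if (sd(x_tr) == 0) next
    if (use_ogt) {
      cub <- tryCatch(fit_cub_model(profiles[train], traits, use_ogt = TRUE,
                                    min_n = min_cub_n),
                      phygrow_error = function(e) NULL)
      if (is.null(cub)) next
      ln_cub <- log(vapply(test, function(q)
        tryCatch(predict_cub(cub, profiles[[q]], ogt = ogt[[q]]),
                 phygrow_error = function(e) NA_real_), numeric(1)))
    } else {
      beta <- stats::.lm.fit(cbind(1, x_tr), ln_y[train])$coefficients
      ln_cub <- beta[1] + beta[2] * cub_he[test]
    }
    ln_phylo <- blup_ln(sub, ln_y[train], test, dmat_vcv = C)
    dsub <- dmat[test, train, drop = FALSE]
    kk <- min(k, length(train))
    dp <- apply(dsub, 1, function(r) mean(sort.int(r, partial = kk)[seq_len(kk)]))
    keep <- !is.na(ln_cub)
    if (!any(keep)) next
    acc[[length(acc) + 1L]] <- data.frame(
      species = test[keep], y_cub = exp(ln_cub[keep]),
      y_phylo = exp(ln_phylo[test][keep]), d_p = dp[keep],
      label = as.integer((ln_cub[keep] - ln_y[test][keep])^2 <=
                           (ln_phylo[test][keep] - ln_y[test][keep])^2),
      stringsAsFactors = FALSE)
  }
  if (!length(acc)) stop_domain("no gate labels could be derived")
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}

#' Compare gate combination modes under blocked CV
#'
#' Runs the full gated-ensemble fit (per-fold CUB regression, inner-CV gate
#' labels, logistic gate) once per fold and scores every requested
#' combination mode on the same fitted state, so mode comparisons are not
#' confounded by refitting noise.
#'
#' @inheritParams cv_evaluate
#' @param profiles Named list of `cub_profile`s.
#' @param n Clade count for the outer folds.
#' @param modes Combination modes to score (default arithmetic, binary).
#' @param inner_n Inner label depths (see [derive_gate_labels()]).
#' @return Named vector of pooled ln-scale MSEs, one per mode.
#' @export
compare_gate_modes <- function(tree, traits, profiles, n,
                               modes = c("arithmetic", "binary"),
                               inner_n = NULL, config = cv_config(),
                               dmat = NULL) {
  validate_phylogeny(tree)
  y <- as_trait_vector(traits)
  if (is.null(dmat)) dmat <- patristic_matrix(tree)
  C <- ape::vcv(tree)
  folds <- withCallingHandlers(make_folds(tree, n),
                               warning = function(w) invokeRestart("muffleWarning"))
  err <- sapply(modes, function(m) numeric(0), simplify = FALSE)
  for (f in folds) {
    train <- intersect(f$train, names(y))
    test <- intersect(intersect(f$test, names(y)), names(profiles))
    if (!length(test) || length(train) < 10) next
    sub <- ape::keep.tip(tree, train)
    labels <- derive_gate_labels(sub, traits, profiles, inner_n = inner_n,
                                 k = config$k, dmat = dmat, C = C)
    gate <- tryCatch(fit_gate(labels, min_n = 10),
                     phygrow_fit_error = function(e)
                       constant_gate(mean(labels$label)))
    cub <- fit_cub_model(profiles[intersect(train, names(profiles))], traits)
    ln_ph <- blup_ln(tree, log(y[train]), test, dmat_vcv = C)
    y_cub <- vapply(test, function(q) predict_cub(cub, profiles[[q]]),
                    numeric(1))
    dsub <- dmat[test, train, drop = FALSE]
    kk <- min(config$k, length(train))
    dp <- apply(dsub, 1, function(r) mean(sort.int(r, partial = kk)[seq_len(kk)]))
    p <- gate_probability(gate, y_cub, dp)
    for (m in modes) {
      comb <- combine_mode(m)(y_cub, exp(ln_ph[test]), p)
      err[[m]] <- c(err[[m]], (log(comb) - log(y[test]))^2)
    }
  }
  vapply(err, mean, numeric(1))
}
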