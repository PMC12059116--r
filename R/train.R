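# Deployment-level training and prediction: one call to fit the CUB
# regression and the gate on a full training set, one call to predict a
# batch of query genomes with all fallback rules applied.

#' Train the full hybrid growth model
#'
#' Fits the CUB regression on all training genomes, derives out-of-sample
#' gate labels by an inner blocked cross-validation, and fits the logistic
#' gate. Species missing from any input are reported in the training
#' summary, not silently dropped.
#'
#' @param tree Reference phylogeny containing the training species.
#' @param traits Trait table (`species`, `doubling_h`, optional `ogt`).
#' @param profiles Named list of `cub_profile`s.
#' @param use_ogt Use OGT in the CUB regression.
#' @param inner_n Inner CV clade count(s) for gate labels (default NULL:
#'   adaptive depths pooled across the distance range; see
#'   [derive_gate_labels()]).
#' @param mode Default combination mode stored with the model.
#' @param k Neighbours for D_p (default 5).
#' @return A `growth_model` list: `cub_model`, `gate`, `tree`, `traits`,
#'   `mode`, `k`, `summary` (species counts and drop reasons).
#' @export
train_growth_model <- function(tree, traits, profiles, use_ogt = FALSE,
                               inner_n = NULL, mode = "arithmetic",
                               k = 5) {
  validate_phylogeny(tree)
  y <- as_trait_vector(traits)
  usable <- Reduce(intersect, list(tree$tip.label, names(y), names(profiles)))
  dropped <- setdiff(union(names(y), names(profiles)), usable)
  if (!length(usable)) stop_domain("no species usable for training")
  ogt <- if (is.data.frame(traits) && "ogt" %in% names(traits))
    setNames(traits$ogt, traits$species) else NULL
  labels <- derive_gate_labels(tree, traits, profiles, inner_n = inner_n,
                               use_ogt = use_ogt, ogt = ogt, k = k)
  gate <- tryCatch(fit_gate(labels),
                   phygrow_fit_error = function(e)
                     constant_gate(mean(labels$label)))
  cub <- fit_cub_model(profiles[usable], traits, use_ogt = use_ogt)
  structure(list(cub_model = cub, gate = gate, tree = tree, traits = traits,
                 mode = mode, k = k,
                 summary = list(n_used = length(usable),
                                n_dropped = length(dropped),
                                dropped = dropped,
                                n_gate_labels = nrow(labels))),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("hybrid growth model: %d training species (%d dropped), mode %s\n",
              x$summary$n_used, x$summary$n_dropped, x$mode))
  print(x$cub_model)
  print(x$gate)
  invisible(x)
}

#' Predict growth for a batch of genomes
#'
#' Applies [hybrid_predict()] to every query, with routing rules: genomes
#' with `psi > psi_threshold` are profiled in metagenome mode and flagged;
#' genomes failing the CUB quality filter fall back to the phylogenetic
#' prediction; queries absent from the tree fall back to the CUB
#' prediction. Every input genome yields exactly one output row.
#'
#' @param model A `growth_model` from [train_growth_model()].
#' @param genomes Named list of `genome_record`s (or `cub_profile`s).
#' @param psi_threshold Contamination score above which metagenome mode is
#'   used (default 0.6).
#' @param mode Override the model's combination mode.
#' @return A data frame, one row per genome, with `query`, `y_cub`,
#'   `y_phylo`, `d_p`, `p_gate`, `y_hybrid`, `mode`, `flags`.
#' @export
predict_growth <- function(model, genomes, psi_threshold = 0.6, mode = NULL) {
  if (!inherits(model, "growth_model")) stop_validation("not a growth_model")
  mode <- mode %||% model$mode
  dmat <- patristic_matrix(model$tree)
  ogt_tab <- if (is.data.frame(model$traits) && "ogt" %in% names(model$traits))
    setNames(model$traits$ogt, model$traits$species) else NULL
  rows <- lapply(names(genomes), function(id) {
    g <- genomes[[id]]
    flags <- character(0)
    if (inherits(g, "genome_record")) {
      meta <- !is.null(g$psi) && g$psi > psi_threshold
      if (meta) flags <- c(flags, "metagenome_mode")
      prof <- tryCatch(cub_profile(g, metagenome_mode = meta),
                       phygrow_quality_error = function(e) e)
      ogt_q <- g$ogt %||% unname(ogt_tab[id])
    } else {
      prof <- g
      ogt_q <- unname(ogt_tab[id])
    }
    if (model$cub_model$use_ogt && (is.null(ogt_q) || is.na(ogt_q)))
      prof <- structure(class = c("phygrow_domain_error", "condition"),
                        list(message = "missing OGT"))
    row <- tryCatch(
      hybrid_predict(model$cub_model, model$gate, model$tree, model$traits,
                     profile = prof, query = id, mode = mode, k = model$k,
                     ogt = ogt_q, dmat = dmat),
      phygrow_error = function(e)
        data.frame(query = id, y_cub = NA_real_, y_phylo = NA_real_,
                   d_p = NA_real_, p_gate = NA_real_, y_hybrid = NA_real_,
                   mode = mode, flags = "failed", stringsAsFactors = FALSE))
    if (length(flags))
      row$flags <- paste(c(flags, Filter(nzchar, row$flags)), collapse = ";")
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
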