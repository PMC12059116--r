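# Phylogeny handling: Newick I/O, patristic distances, depth-based clade
# cutting. Trees are `ape` "phylo" objects throughout; every public entry
# point validates with validate_phylogeny().

#' Validate a phylogeny
#'
#' Checks that a tree is a rooted `phylo` object with unique, non-empty tip
#' labels and a full set of non-negative branch lengths.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly, if valid; otherwise a validation error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop_validation("not a 'phylo' object")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop_validation("every edge must carry a branch length")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop_validation("branch lengths must be non-negative and non-missing")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop_validation("empty tip label")
  if (anyDuplicated(labs)) stop_validation("duplicate tip labels")
  invisible(tree)
}

#' Read a rooted Newick tree
#'
#' @param path Path to a file containing one Newick string with branch
#'   lengths on every edge.
#' @return A validated `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("tree file not found: %s", path))
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop_format(sprintf("could not parse Newick in %s", path))
  tryCatch(validate_phylogeny(tree), phygrow_validation_error = function(e)
    stop_validation(conditionMessage(e)))
  tree
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

# Root-to-node path lengths (tips first, then internal nodes), ape order.
node_depths <- function(tree) ape::node.depth.edgelength(tree)

#' Root-to-tip span of a tree
#'
#' @param tree A `phylo` object.
#' @return The maximum root-to-tip path length.
#' @export
root_age <- function(tree) {
  validate_phylogeny(tree)
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

#' Ultrametricity check
#'
#' A tree is treated as ultrametric when the root-to-tip spread is at most
#' `tol` times the root age.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance (default 1e-6).
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  validate_phylogeny(tree)
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  age <- max(d)
  if (age == 0) return(TRUE)
  (age - min(d)) <= tol * age
}

#' Patristic distance matrix
#'
#' @param tree A `phylo` object.
#' @return Symmetric matrix of path lengths between all tip pairs.
#' @export
patristic_matrix <- function(tree) {
  validate_phylogeny(tree)
  stats::cophenetic(tree)
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths along the unique path between tips `a` and `b`.
#'
#' @param tree A `phylo` object.
#' @param a,b Tip labels.
#' @return A non-negative scalar.
#' @export
patristic_distance <- function(tree, a, b) {
  validate_phylogeny(tree)
  labs <- tree$tip.label
  miss <- setdiff(c(a, b), labs)
  if (length(miss)) stop_lookup(sprintf("unknown tip label(s): %s",
                                        paste(miss, collapse = ", ")))
  if (a == b) return(0)
  ia <- match(a, labs); ib <- match(b, labs)
  dn <- ape::dist.nodes(tree)
  unname(dn[ia, ib])
}

# Tip descendants for every node (index list over 1..Ntip+Nnode).
tip_descendants <- function(tree) {
  ntip <- ape::Ntip(tree); nnode <- tree$Nnode
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1]; ch <- edge[r, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

# Lineage count at depth t from the root: edges spanning t plus tips that
# terminated before t (kept as singleton lineages so cuts always partition
# the tip set, including on non-ultrametric trees).
lineages_at_depth <- function(tree, t, depths = node_depths(tree)) {
  parent_d <- depths[tree$edge[, 1]]
  child_d <- depths[tree$edge[, 2]]
  spanning <- parent_d < t & t <= child_d
  tipd <- depths[seq_len(ape::Ntip(tree))]
  sum(spanning) + sum(tipd < t)
}

#' Cut a tree into clades at a uniform depth
#'
#' Slices all edges at a single distance from the root so that exactly `n`
#' lineages cross the cut; each crossing edge defines one clade (the tips
#' below it), and tips that terminate above the cut become singleton clades.
#' When a multifurcation makes the lineage count jump past `n`, the smallest
#' achievable count `m >= n` is returned and flagged with a warning.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param n Requested number of clades, `1 <= n <=` number of tips.
#' @return An object of class `clade_partition`: a list with `n_clades`,
#'   `cut_depth` (distance from the present on ultrametric trees, otherwise
#'   from the root), `clades` (list of tip-label character vectors),
#'   `requested_n`, and `exact` (FALSE when `n` was unattainable).
#' @export
cut_into_clades <- function(tree, n) {
  validate_phylogeny(tree)
  ntip <- ape::Ntip(tree)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop_domain("'n' must be a positive integer")
  if (n > ntip) stop_domain(sprintf("n = %d exceeds the %d tips", n, ntip))
  n <- as.integer(n)
  depths <- node_depths(tree)
  age <- max(depths[seq_len(ntip)])
  ultra <- is_ultrametric_tree(tree)
  from_present <- function(t) if (ultra) age - t else t

  if (n == 1L) {
    out <- list(n_clades = 1L, cut_depth = from_present(0),
                clades = list(tree$tip.label), requested_n = 1L, exact = TRUE)
    class(out) <- "clade_partition"
    return(out)
  }

  # Lineage count is piecewise constant between node depths; scan bands.
  bps <- sort(unique(c(0, depths)))
  mids <- (bps[-length(bps)] + bps[-1]) / 2
  counts <- vapply(mids, lineages_at_depth, integer(1),
                   tree = tree, depths = depths)
  hit <- which(counts == n)
  exact <- length(hit) > 0
  if (!exact) {
    cand <- which(counts >= n)
    if (!length(cand)) stop_domain("no cut depth attains the requested clade count")
    m <- min(counts[cand])
    hit <- which(counts == m)
    warning(sprintf(
      "no cut yields exactly %d clades (lineage count jumps past it); using %d",
      n, m), call. = FALSE)
  }
  band <- hit[1]
  t_cut <- mids[band]

  parent_d <- depths[tree$edge[, 1]]
  child_d <- depths[tree$edge[, 2]]
  span <- which(parent_d < t_cut & t_cut <= child_d)
  desc <- tip_descendants(tree)
  clades <- lapply(span, function(e) tree$tip.label[desc[[tree$edge[e, 2]]]])
  dead <- which(depths[seq_len(ntip)] < t_cut)
  clades <- c(clades, lapply(dead, function(i) tree$tip.label[i]))

  out <- list(n_clades = length(clades), cut_depth = from_present(t_cut),
              clades = clades, requested_n = n, exact = exact)
  class(out) <- "clade_partition"
  out
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("clade partition: %d clades (requested %d%s), cut depth %.4g\n",
              x$n_clades, x$requested_n,
              if (x$exact) "" else ", inexact", x$cut_depth))
  invisible(x)
}

#' Mean distance to the k nearest training tips
#'
#' The per-species phylogenetic distance D_p: the mean patristic distance
#' from a query tip to its `min(k, |training|)` closest tips in a training
#' set. A query that appears in the training set is excluded from its own
#' neighbour list.
#'
#' @param tree A `phylo` object.
#' @param query A tip label.
#' @param training Character vector of training tip labels.
#' @param k Number of neighbours (default 5); fewer are used when the
#'   training set is smaller.
#' @param dmat Optional precomputed patristic matrix (for repeated calls).
#' @return A non-negative scalar.
#' @export
mean_k_nearest_distance <- function(tree, query, training, k = 5, dmat = NULL) {
  if (is.null(dmat)) {
    validate_phylogeny(tree)
    dmat <- patristic_matrix(tree)
  }
  if (!query %in% rownames(dmat)) stop_lookup(sprintf("unknown tip: %s", query))
  training <- setdiff(unique(training), query)
  if (!length(training)) stop_domain("training set is empty")
  miss <- setdiff(training, rownames(dmat))
  if (length(miss)) stop_lookup(sprintf("training tips not in tree: %s",
                                        paste(miss, collapse = ", ")))
  d <- sort(dmat[query, training])
  mean(d[seq_len(min(k, length(d)))])
}
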