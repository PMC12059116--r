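# Independent oracles used across the suite. Each one takes a different
# computational route from the implementation it checks.

# Patristic distance via MRCA depths: d(a, b) = depth(a) + depth(b)
# - 2 * depth(MRCA(a, b)).
mrca_depth_distance <- function(tree, a, b) {
  if (a == b) return(0)
  depths <- ape::node.depth.edgelength(tree)
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  m <- ape::getMRCA(tree, c(a, b))
  depths[ia] + depths[ib] - 2 * depths[m]
}

# Brute-force NNM: sort all patristic distances, take the k nearest
# (including ties at the k-th), geometric-mean their traits.
nnm_bruteforce <- function(tree, traits, query, k) {
  d <- ape::cophenetic.phylo(tree)[query, ]
  d <- d[names(d) != query & names(d) %in% names(traits)]
  kth <- sort(d)[min(k, length(d))]
  sel <- names(d)[d <= kth]
  exp(mean(log(traits[sel])))
}

# Felsenstein's contrasts pruning recursion, run outward from the query's
# attachment node on the unrooted edge graph: each subtree is collapsed to
# a pseudo-tip with a 1/branch-length weighted average and an extended
# branch length v + 1/sum(1/v_i). Returns the ln-scale estimate at the
# attachment node, which is the BM BLUP of the query.
pruning_blup_ln <- function(tree, ln_traits, query) {
  ntip <- ape::Ntip(tree)
  qi <- match(query, tree$tip.label)
  edges <- tree$edge
  lens <- tree$edge.length
  nbr <- function(node) {
    rows <- which(edges[, 1] == node | edges[, 2] == node)
    lapply(rows, function(r) {
      other <- if (edges[r, 1] == node) edges[r, 2] else edges[r, 1]
      list(node = other, len = lens[r])
    })
  }
  collapse <- function(node, from, len_in) {
    if (node <= ntip) {
      return(list(x = ln_traits[[tree$tip.label[node]]], v = len_in))
    }
    kids <- Filter(function(e) e$node != from && e$node != qi, nbr(node))
    parts <- lapply(kids, function(e) collapse(e$node, node, e$len))
    wsum <- sum(vapply(parts, function(p) 1 / p$v, numeric(1)))
    x <- sum(vapply(parts, function(p) p$x / p$v, numeric(1))) / wsum
    list(x = x, v = len_in + 1 / wsum)
  }
  attach_node <- {
    r <- which(edges[, 2] == qi)
    edges[r, 1]
  }
  kids <- Filter(function(e) e$node != qi, nbr(attach_node))
  parts <- lapply(kids, function(e) collapse(e$node, attach_node, e$len))
  wsum <- sum(vapply(parts, function(p) 1 / p$v, numeric(1)))
  sum(vapply(parts, function(p) p$x / p$v, numeric(1))) / wsum
}

# Small random trees with strictly positive branch lengths.
random_tree <- function(n, ultrametric = FALSE, min_len = 0.05) {
  if (ultrametric) {
    ape::rphylo(n, birth = 1, death = 0)
  } else {
    tr <- ape::rtree(n)
    tr$edge.length <- tr$edge.length + min_len
    tr
  }
}

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
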