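#' Metabolic distance between two networks
#'
#' The fraction of compounds and reactions in which two networks differ:
#' d = (|C_A xor C_B| + |R_A xor R_B|) / (|C_A u C_B| + |R_A u R_B|),
#' a Steinhaus-type (symmetric-difference over union) distance on the
#' combined compound and reaction sets. Ranges over \[0, 1\]: 0 iff the
#' networks have identical compound and reaction sets, 1 iff fully
#' disjoint; it is a true metric.
#'
#' @param netA,netB `caro_network`s.
#' @return distance in \[0, 1\].
#' @export
metabolic_distance <- function(netA, netB) {
  ca <- netA$compounds$id
  cb <- netB$compounds$id
  ra <- paste(netA$reactions$substrate, netA$reactions$product, sep = "\r")
  rb <- paste(netB$reactions$substrate, netB$reactions$product, sep = "\r")
  denom <- length(union(ca, cb)) + length(union(ra, rb))
  if (denom == 0L) stop("both networks are empty")
  sym <- function(a, b) length(setdiff(a, b)) + length(setdiff(b, a))
  (sym(ca, cb) + sym(ra, rb)) / denom
}

#' Pairwise metabolic distance matrix
#'
#' Optionally restricts each network to a single role (dietary,
#' intermediate, or expressed subnetworks) before computing distances;
#' reactions are kept only when both endpoints carry the role. A pair in
#' which both filtered networks are empty gets `NA`, not 0.
#'
#' @param networks named list of species networks.
#' @param role_filter optional role name.
#' @return symmetric matrix with species ids as dimnames.
#' @export
pairwise_matrix <- function(networks, role_filter = NULL) {
  if (length(networks) < 2L) stop("need at least two species")
  if (!is.null(role_filter))
    networks <- lapply(networks, filter_role, role = role_filter)
  ids <- names(networks)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- tryCatch(metabolic_distance(networks[[i]], networks[[j]]),
                    error = function(e) NA_real_)
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Neighbour-joining tree from a metabolic distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}). Negative branch
#' lengths, an artefact of NJ on non-additive matrices, are clamped to
#' zero with the deficit moved to the sibling edge (the classic
#' adjustment); the number of clamped edges is recorded in
#' `attr(, "n_clamped")`.
#'
#' @param d symmetric distance matrix (n >= 3, no missing entries).
#' @return an unrooted `phylo` tree with metabolic branch lengths.
#' @export
neighbor_joining <- function(d) {
  if (any(is.na(d))) stop("distance matrix has missing entries")
  if (nrow(d) < 3L) stop("need at least three taxa")
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (i in neg) {
    parent <- tr$edge[i, 1L]
    sib <- which(tr$edge[, 1L] == parent)
    sib <- setdiff(sib, i)
    if (length(sib))
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + tr$edge.length[i]
    tr$edge.length[i] <- 0
  }
  attr(tr, "n_clamped") <- length(neg)
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' Counts bipartitions present in exactly one tree. Trees with identical
#' topologies have RF 0; the maximum for n taxa is 2(n - 3). Tip sets are
#' pruned to their intersection when they differ (with a message).
#'
#' @param t1,t2 `phylo` trees.
#' @return list with `rf`, `rf_max` = 2(n - 3), and `n` shared tips.
#' @export
robinson_foulds <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) stop("need at least four shared tips")
  if (length(shared) < length(t1$tip.label) ||
      length(shared) < length(t2$tip.label)) {
    message("pruning trees to ", length(shared), " shared tips")
    t1 <- ape::keep.tip(t1, shared)
    t2 <- ape::keep.tip(t2, shared)
  }
  list(rf = as.integer(phangorn::RF.dist(t1, t2)),
       rf_max = rf_max(length(shared)),
       n = length(shared))
}

#' @rdname robinson_foulds
#' @param n number of taxa.
#' @export
rf_max <- function(n) 2L * (as.integer(n) - 3L)

#' Strict consensus of a set of trees
#'
#' Keeps only bipartitions present in every input tree.
#'
#' @param trees a list of `phylo` trees (or `multiPhylo`) on a shared tip set.
#' @return a `phylo` tree.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) return(trees)
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1)
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths on the path between two tips, in the tree's
#' branch-length units (millions of years for dated trees). On an
#' ultrametric tree this equals twice the divergence time.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param a,b tip labels.
#' @return non-negative numeric.
#' @export
patristic_distance <- function(tree, a, b) {
  if (!all(c(a, b) %in% tree$tip.label))
    stop("unknown tip: ", paste(setdiff(c(a, b), tree$tip.label), collapse = ", "))
  if (a == b) return(0)
  pm <- patristic_matrix(tree)
  pm[a, b]
}

#' @rdname patristic_distance
#' @export
patristic_matrix <- function(tree) {
  ape::cophenetic.phylo(tree)
}
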