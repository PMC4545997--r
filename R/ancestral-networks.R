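# Name of a node in ape numbering: tip label for tips, "node<k>" otherwise.
node_name <- function(tree, v) {
  nt <- length(tree$tip.label)
  ifelse(v <= nt, tree$tip.label[v], paste0("node", v))
}

#' Assemble ancestral networks from reconstructed states
#'
#' At every node of the tree, the network holds the MAP-present compound
#' characters and the MAP-present reaction characters whose both endpoints
#' are present (reactions with a missing endpoint are dropped and
#' counted). Tip networks are rebuilt from the observed character states,
#' so tips and internal nodes are comparable. Roles: a compound dietary in
#' the global network is dietary, all others intermediate (plumage
#' expression is not a reconstructed character).
#'
#' @param recon result of [reconstruct_states()].
#' @param global the global network (for dietary flags and validation).
#' @param prune_unreachable drop non-dietary compounds unreachable from the
#'   node's dietary set (report kept in `attr(, "pruned")`)?
#' @return named list of `caro_species_network`s: tip labels plus
#'   `"node<k>"` for internal nodes.
#' @export
assemble_ancestral_networks <- function(recon, global,
                                        prune_unreachable = FALSE) {
  states <- rbind(recon$tip_states, recon$map)
  chars <- colnames(states)
  is_rxn <- grepl("->", chars, fixed = TRUE)
  out <- list()
  for (nm in rownames(states)) {
    present <- chars[states[nm, ] == 1L]
    comp <- setdiff(present, present[grepl("->", present, fixed = TRUE)])
    rxn_chars <- intersect(present, chars[is_rxn])
    ends <- strsplit(rxn_chars, "->", fixed = TRUE)
    ok <- vapply(ends, function(e) all(e %in% comp), TRUE)
    n_dropped <- sum(!ok)
    rxn <- if (any(ok)) {
      e <- do.call(rbind, ends[ok])
      data.frame(id = rxn_chars[ok], substrate = e[, 1], product = e[, 2],
                 stringsAsFactors = FALSE)
    } else NULL
    dietary <- intersect(comp, global$dietary)
    pruned <- character(0)
    if (prune_unreachable && length(comp)) {
      reach <- reachable_from_diet(comp,
                                   if (is.null(rxn)) character(0) else rxn$substrate,
                                   if (is.null(rxn)) character(0) else rxn$product,
                                   dietary)
      pruned <- setdiff(comp, reach)
      comp <- intersect(comp, reach)
      if (!is.null(rxn))
        rxn <- rxn[rxn$substrate %in% comp & rxn$product %in% comp, , drop = FALSE]
      dietary <- intersect(dietary, comp)
    }
    roles <- lapply(stats::setNames(comp, comp), function(x)
      if (x %in% dietary) "dietary" else "intermediate")
    net <- species_network(nm, "maximum", comp, rxn, roles, validate = FALSE)
    attr(net, "n_dropped_reactions") <- n_dropped
    attr(net, "pruned") <- pruned
    out[[nm]] <- net
  }
  out
}

reaction_keys <- function(net) {
  paste0(net$reactions$substrate, "->", net$reactions$product)
}

#' Per-branch rates of metabolic elaboration
#'
#' For every branch, counts reaction gains (present in the child's network
#' but not the parent's) and losses, and reports the elaboration rate =
#' gains / branch duration (reactions per My). Branches are classified
#' into regimes: `stasis_or_shrinkage` (no gains), `highly_elevated`
#' (rate in the upper quartile of the strictly positive rates -- including
#' zeros would make the quartile degenerate on stasis-heavy trees), and
#' `normal` otherwise. Zero-duration branches get an undefined rate
#' (events still counted) and are never classified as elevated.
#'
#' @param tree `phylo` tree (branch lengths in My).
#' @param node_networks networks at every node, named as produced by
#'   [assemble_ancestral_networks()].
#' @return data.frame with one row per edge: parent, child (names),
#'   duration, gains, losses, rate, regime.
#' @export
branch_rates <- function(tree, node_networks) {
  nedge <- nrow(tree$edge)
  parent <- node_name(tree, tree$edge[, 1L])
  child <- node_name(tree, tree$edge[, 2L])
  gains <- losses <- integer(nedge)
  for (e in seq_len(nedge)) {
    rp <- reaction_keys(node_networks[[parent[e]]])
    rc <- reaction_keys(node_networks[[child[e]]])
    gains[e] <- length(setdiff(rc, rp))
    losses[e] <- length(setdiff(rp, rc))
  }
  duration <- tree$edge.length
  rate <- ifelse(duration > 0, gains / duration, NA_real_)
  pos <- rate[!is.na(rate) & rate > 0]
  thr <- if (length(pos)) quantile(pos, 0.75, names = FALSE) else Inf
  regime <- ifelse(gains == 0, "stasis_or_shrinkage",
                   ifelse(!is.na(rate) & rate >= thr, "highly_elevated",
                          "normal"))
  data.frame(parent = parent, child = child, duration = duration,
             gains = gains, losses = losses, rate = rate, regime = regime,
             stringsAsFactors = FALSE)
}

#' Dietary gains across rate-regime transitions
#'
#' For each parent-branch -> child-branch pair whose ancestral branch is
#' in the highly elevated regime, records the descendant regime and
#' whether the child branch gained at least one new dietary compound
#' (dietary compound present in the child's node network but absent from
#' its parent node's network). Tabulates n (elevated -> elevated
#' transitions), k (those with a dietary gain), n_bust (elevated ->
#' stasis/shrinkage) and the continuity-corrected one-proportion z of
#' k/n against 0.5.
#'
#' @param tree `phylo` tree.
#' @param rates data.frame from [branch_rates()].
#' @param node_networks node networks (see [assemble_ancestral_networks()]).
#' @return list with `n`, `k`, `n_bust`, `z`, and the per-transition table.
#' @export
dietary_transitions <- function(tree, rates, node_networks) {
  edge_child <- rates$child
  elevated <- which(rates$regime == "highly_elevated")
  rows <- NULL
  for (e in elevated) {
    v <- rates$child[e]
    kids <- which(rates$parent == v)
    for (f in kids) {
      w <- rates$child[f]
      gained <- length(setdiff(node_networks[[w]]$dietary,
                               node_networks[[v]]$dietary)) > 0L
      rows <- rbind(rows, data.frame(
        ancestor_branch = v, descendant_branch = w,
        descendant_regime = rates$regime[f], gained_diet = gained,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows))
    return(list(n = 0L, k = 0L, n_bust = 0L, z = NA_real_, table = NULL))
  ee <- rows[rows$descendant_regime == "highly_elevated", , drop = FALSE]
  n <- nrow(ee)
  k <- sum(ee$gained_diet)
  n_bust <- sum(rows$descendant_regime == "stasis_or_shrinkage")
  list(n = n, k = k, n_bust = n_bust,
       z = if (n > 0L) sign_test_z(k, n) else NA_real_, table = rows)
}

#' Continuity-corrected one-proportion (sign test) z statistic
#'
#' z = (k - c - n p0) / sqrt(n p0 (1 - p0)), with the continuity
#' correction c = 1/2 applied toward the null.
#'
#' @param k successes; @param n trials; @param p0 null proportion.
#' @param continuity apply the half-count correction?
#' @return z (attribute `p` carries the two-sided normal p-value).
#' @export
sign_test_z <- function(k, n, p0 = 0.5, continuity = TRUE) {
  stopifnot(n >= 1L, k >= 0L, k <= n)
  cc <- if (continuity) 0.5 * sign(k - n * p0) else 0
  z <- (k - cc - n * p0) / sqrt(n * p0 * (1 - p0))
  structure(z, p = 2 * pnorm(-abs(z)))
}

#' Waiting times for compound gains and losses by distance from diet
#'
#' Counts compound gain and loss events over all branches (from the node
#' networks), bins compounds by their shortest distance from the dietary
#' set on the global network, and reports the mean waiting time per event
#' in each bin: total tree time / number of events, with a nonparametric
#' bootstrap SE over compounds. Bins with zero events report a waiting
#' time of `Inf` (longer than the total tree length).
#'
#' @param tree `phylo` tree.
#' @param node_networks node networks.
#' @param global global network (distance binning).
#' @param B bootstrap replicates.
#' @param seed RNG seed.
#' @return data.frame: distance, n_compounds, gains, losses, my_per_gain,
#'   my_per_gain_se, my_per_loss, my_per_loss_se.
#' @export
waiting_times_by_distance <- function(tree, node_networks, global,
                                      B = 1000L, seed = 1L) {
  total_time <- sum(tree$edge.length)
  dist <- distance_from_diet(global)
  comp_ids <- global$compounds$id
  gains <- losses <- stats::setNames(numeric(length(comp_ids)), comp_ids)
  parent <- node_name(tree, tree$edge[, 1L])
  child <- node_name(tree, tree$edge[, 2L])
  for (e in seq_along(parent)) {
    cp <- node_networks[[parent[e]]]$compounds$id
    cv <- node_networks[[child[e]]]$compounds$id
    g <- intersect(setdiff(cv, cp), comp_ids)
    l <- intersect(setdiff(cp, cv), comp_ids)
    gains[g] <- gains[g] + 1
    losses[l] <- losses[l] + 1
  }
  set.seed(seed)
  out <- NULL
  for (d in sort(unique(dist[is.finite(dist)]))) {
    cc <- comp_ids[dist[comp_ids] == d]
    wt <- function(ev) if (sum(ev) > 0) total_time / sum(ev) else Inf
    boot_se <- function(ev) {
      if (length(cc) < 2L) return(NA_real_)
      reps <- vapply(seq_len(B), function(b)
        wt(ev[sample(cc, replace = TRUE)]), 0)
      sd(reps[is.finite(reps)])
    }
    out <- rbind(out, data.frame(
      distance = d, n_compounds = length(cc),
      gains = sum(gains[cc]), losses = sum(losses[cc]),
      my_per_gain = wt(gains[cc]), my_per_gain_se = boot_se(gains[cc]),
      my_per_loss = wt(losses[cc]), my_per_loss_se = boot_se(losses[cc])))
  }
  out
}

#' Realized fraction of a dietary compound's biochemical scope
#'
#' The proportion of the compounds reachable from a dietary carotenoid in
#' the full global network (its potential biochemical scope) that are
#' present in, and reachable within, a given (typically ancestral) node
#' network.
#'
#' @param node_net a node or species network.
#' @param dietary_compound a compound in the global dietary set.
#' @param global global network.
#' @return fraction in \[0, 1\]; attribute `absent` flags a dietary
#'   compound missing from the node network (fraction 0).
#' @export
realized_scope_fraction <- function(node_net, dietary_compound, global) {
  if (!dietary_compound %in% global$dietary)
    stop(dietary_compound, " is not a global dietary compound")
  scope <- names(which(is.finite(
    scope_expansion(global, dietary_compound)$generation_of)))
  if (!dietary_compound %in% node_net$compounds$id)
    return(structure(0, absent = TRUE))
  realized <- reachable_from_diet(node_net$compounds$id,
                                  node_net$reactions$substrate,
                                  node_net$reactions$product,
                                  dietary_compound)
  structure(length(intersect(realized, scope)) / length(scope),
            absent = FALSE)
}

#' Attribute a species' longest pathway to its dietary scopes
#'
#' Finds one maximal dietary-to-expressed pathway and attributes each
#' compound on it to the dietary compound that reaches it in the fewest
#' biochemical generations within the species network; ties are split
#' equally. The returned fractions sum to 1 and partition the elongation
#' by the dietary scopes that contributed to it.
#'
#' @param net species network with longest elongation >= 1.
#' @return named numeric vector over dietary compounds, summing to 1.
#' @export
elongation_contributions <- function(net) {
  expressed <- role_compounds(net, "expressed")
  res <- longest_simple_path(net, net$dietary, expressed, return_path = TRUE)
  if (res$length < 1L) stop("longest elongation must be >= 1")
  path <- res$path
  g <- as_igraph(net)
  dm <- igraph::distances(g, v = net$dietary, to = path, mode = "out")
  shares <- stats::setNames(numeric(length(net$dietary)), net$dietary)
  for (j in seq_along(path)) {
    d <- dm[, j]
    nearest <- rownames(dm)[is.finite(d) & d == min(d)]
    shares[nearest] <- shares[nearest] + 1 / length(nearest)
  }
  shares / length(path)
}
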