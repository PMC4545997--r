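#' Classify compound roles from inventory evidence
#'
#' Compounds are `dietary` if consumed with diet, `expressed` if found in
#' plumage, and `intermediate` if found in any other tissue (plasma, liver,
#' gut, fat, faeces, seminal fluid, integument) or later inserted as a
#' required pathway link. Roles can overlap: a dietary compound deposited
#' unchanged in plumage is both dietary and expressed.
#'
#' @param records data.frame of inventory records for one species
#'   (`compound_id`, `evidence`).
#' @return named list compound id -> character vector of roles.
#' @export
classify_roles <- function(records) {
  if (!nrow(records)) stop("no inventory records")
  bad <- setdiff(unique(records$evidence), evidence_vocabulary())
  if (length(bad))
    stop("unknown evidence token: ", paste(bad, collapse = ", "))
  role_of <- function(ev) {
    if (ev == "diet") "dietary"
    else if (ev == "plumage") "expressed"
    else "intermediate"
  }
  roles <- tapply(vapply(records$evidence, role_of, ""), records$compound_id,
                  function(r) sort(unique(r)), simplify = FALSE)
  lapply(roles, identity)
}

# Global graph restricted by the diet-link rule: drop edges directly joining
# two of this species' dietary compounds unless the pair is whitelisted.
restricted_global <- function(global, dietary, confirmed_pairs = NULL) {
  rxn <- global$reactions
  if (!nrow(rxn)) return(global)
  forbidden <- rxn$substrate %in% dietary & rxn$product %in% dietary
  if (!is.null(confirmed_pairs) && nrow(as.data.frame(confirmed_pairs))) {
    cp <- as.data.frame(confirmed_pairs)
    ok <- paste(rxn$substrate, rxn$product) %in%
      c(paste(cp[[1]], cp[[2]]), paste(cp[[2]], cp[[1]]))
    forbidden <- forbidden & !ok
  }
  global$reactions <- rxn[!forbidden, , drop = FALSE]
  global
}

#' Remove direct diet-to-diet reactions from a species network
#'
#' Dietary compounds are not linked by direct enzymatic reactions even when
#' such a reaction exists on the global network, unless the link has been
#' experimentally confirmed for the focal species.
#'
#' @param net a species network.
#' @param confirmed_pairs optional two-column data.frame of confirmed
#'   (substrate, product) dietary pairs (order-insensitive whitelist).
#' @return the network with forbidden edges removed.
#' @export
enforce_diet_link_rule <- function(net, confirmed_pairs = NULL) {
  out <- restricted_global(net, net$dietary, confirmed_pairs)
  validate_species_network(out)
  out
}

# All cheapest dietary -> target paths in g (shortest over all dietary
# sources at the global minimum distance), ordered deterministically by
# decreasing observed-compound coverage then lexicographic node sequence.
candidate_paths_to <- function(g, dietary, target, observed) {
  dietary <- intersect(dietary, igraph::V(g)$name)
  if (!length(dietary)) return(NULL)
  dm <- igraph::distances(g, v = dietary, to = target, mode = "out")
  if (!any(is.finite(dm))) return(NULL)
  best_len <- min(dm)
  cand <- list()
  for (d in dietary[dm[, 1] == best_len]) {
    ps <- igraph::all_shortest_paths(g, from = d, to = target,
                                     mode = "out")$vpaths
    cand <- c(cand, lapply(ps, function(p) igraph::V(g)$name[p]))
  }
  cover <- vapply(cand, function(p) sum(p %in% observed), 1L)
  keys <- vapply(cand, paste, "", collapse = "\r")
  cand[order(-cover, keys)]
}

path_edges <- function(p) {
  if (length(p) < 2L) character(0) else paste(p[-length(p)], p[-1L], sep = "\r")
}

# Pick one cheapest path per target so the union of their reactions is as
# small as possible. Exhaustive over all combinations when feasible
# (deterministic tie-break: first combination in candidate order, which
# prefers observed coverage then lexicographic paths); greedy otherwise.
choose_path_union <- function(cands, combo_budget = 4096) {
  counts <- lengths(cands)
  if (prod(counts) <= combo_budget && length(cands)) {
    combos <- do.call(expand.grid, lapply(counts, seq_len))
    best <- NULL; best_n <- Inf
    for (i in seq_len(nrow(combos))) {
      sel <- mapply(function(ps, j) ps[[j]], cands, unlist(combos[i, ]),
                    SIMPLIFY = FALSE)
      u <- unique(unlist(lapply(sel, path_edges)))
      if (length(u) < best_n) {
        best_n <- length(u); best <- sel
      }
    }
    best
  } else {
    chosen <- list()
    have <- character(0)
    for (e in names(cands)) {
      gain <- vapply(cands[[e]], function(p)
        length(setdiff(path_edges(p), have)), 1L)
      pick <- cands[[e]][[which.min(gain)]]
      chosen[[e]] <- pick
      have <- union(have, path_edges(pick))
    }
    chosen
  }
}

#' Build the minimum species network
#'
#' The minimum network holds the fewest reactions required to produce the
#' species' plumage compounds from its dietary carotenoids: the union, over
#' expressed compounds, of one cheapest directed dietary-to-expressed path
#' on the global network, with the path combination chosen to minimise the
#' size of the union (exhaustive search up to a combination budget, greedy
#' beyond it). Among equal-length paths, those passing through the most
#' observed compounds are preferred, then the lexicographically smallest
#' node sequence, so rebuilding is byte-identical. Unobserved
#' compounds required on a chosen path are inserted with role
#' `intermediate`. Expressed compounds unreachable from every dietary
#' compound are kept without a producing path and listed in
#' `attr(, "violations")`.
#'
#' @param global the global carotenoid network.
#' @param roles named role list from [classify_roles()].
#' @param species_id species identifier.
#' @param confirmed_pairs whitelist for [enforce_diet_link_rule()].
#' @return a `caro_species_network` of kind `"minimum"`.
#' @export
build_minimum_network <- function(global, roles, species_id = "sp",
                                  confirmed_pairs = NULL) {
  recorded <- names(roles)
  dietary <- names(roles)[vapply(roles, function(r) "dietary" %in% r, TRUE)]
  expressed <- names(roles)[vapply(roles, function(r) "expressed" %in% r, TRUE)]
  g <- as_igraph(restricted_global(global, dietary, confirmed_pairs))
  violations <- character(0)
  cands <- list()
  for (e in sort(setdiff(expressed, dietary))) {
    if (!e %in% igraph::V(g)$name) { violations <- c(violations, e); next }
    ps <- candidate_paths_to(g, dietary, e, recorded)
    if (is.null(ps)) { violations <- c(violations, e); next }
    cands[[e]] <- ps
  }
  chosen <- choose_path_union(cands)
  edges <- unique(unlist(lapply(chosen, path_edges)))
  inserted <- setdiff(unique(unlist(chosen)), recorded)
  if (is.null(edges)) edges <- character(0)
  comp <- union(recorded, inserted)
  roles2 <- roles
  for (x in inserted) roles2[[x]] <- "intermediate"
  rxn <- if (length(edges)) {
    sp <- do.call(rbind, strsplit(sort(edges), "\r", fixed = TRUE))
    gk <- paste(global$reactions$substrate, global$reactions$product, sep = "\r")
    data.frame(id = global$reactions$id[match(paste(sp[, 1], sp[, 2], sep = "\r"), gk)],
               substrate = sp[, 1], product = sp[, 2], stringsAsFactors = FALSE)
  } else NULL
  net <- species_network(species_id, "minimum",
                         comp[order(comp)], rxn, roles2[order(names(roles2))],
                         validate = FALSE)
  attr(net, "violations") <- violations
  suppressWarnings(validate_species_network(net))
  if (length(violations))
    warning("species ", species_id,
            ": expressed compounds unreachable from the dietary set: ",
            paste(violations, collapse = ", "))
  net
}

#' Build the maximum species network
#'
#' The maximum network records all biochemically possible reactions on the
#' global network that could produce the species' plumage compounds from
#' its dietary and intermediate compounds: every global reaction whose
#' endpoints are recorded compounds and which lies on some directed
#' dietary-to-expressed path. Interior path nodes are restricted to
#' recorded compounds unless `allow_unrecorded_interior = TRUE`, in which
#' case any global compound on such a path is pulled in with role
#' `intermediate`. The maximum network is always a superset of the minimum
#' network built from the same inventory.
#'
#' @inheritParams build_minimum_network
#' @param allow_unrecorded_interior admit unrecorded global compounds as
#'   path interiors?
#' @return a `caro_species_network` of kind `"maximum"`.
#' @export
build_maximum_network <- function(global, roles, species_id = "sp",
                                  confirmed_pairs = NULL,
                                  allow_unrecorded_interior = FALSE) {
  recorded <- names(roles)
  dietary <- names(roles)[vapply(roles, function(r) "dietary" %in% r, TRUE)]
  expressed <- names(roles)[vapply(roles, function(r) "expressed" %in% r, TRUE)]
  restricted <- restricted_global(global, dietary, confirmed_pairs)
  pool <- if (allow_unrecorded_interior) restricted$compounds$id else
    intersect(recorded, restricted$compounds$id)
  rxn <- restricted$reactions[restricted$reactions$substrate %in% pool &
                                restricted$reactions$product %in% pool, , drop = FALSE]
  sub <- caro_network(pool, rxn, intersect(dietary, pool), validate = FALSE)
  g <- as_igraph(sub)
  vn <- igraph::V(g)$name
  from_diet <- rep(FALSE, length(vn))
  to_expr <- rep(FALSE, length(vn))
  names(from_diet) <- names(to_expr) <- vn
  d0 <- intersect(dietary, vn)
  e0 <- intersect(expressed, vn)
  if (length(d0)) {
    dm <- igraph::distances(g, v = d0, mode = "out")
    from_diet[colnames(dm)] <- apply(dm, 2, min) < Inf
  }
  if (length(e0)) {
    dm <- igraph::distances(g, v = e0, mode = "in")
    to_expr[colnames(dm)] <- apply(dm, 2, min) < Inf
  }
  # a reaction u->v lies on a dietary->expressed path iff u is reachable
  # from the diet and an expressed compound is reachable from v
  keep <- from_diet[rxn$substrate] & to_expr[rxn$product]
  rxn <- rxn[keep, , drop = FALSE]
  on_path <- vn[from_diet & to_expr]
  comp <- sort(union(recorded, on_path))
  roles2 <- roles
  for (x in setdiff(comp, recorded)) roles2[[x]] <- "intermediate"
  excluded <- setdiff(recorded, on_path)
  ord <- order(rxn$substrate, rxn$product)
  net <- species_network(species_id, "maximum", comp,
                         rxn[ord, , drop = FALSE],
                         roles2[order(names(roles2))], validate = FALSE)
  attr(net, "off_path_compounds") <- excluded
  attr(net, "violations") <- setdiff(expressed,
                                     union(dietary, on_path))
  suppressWarnings(validate_species_network(net))
  if (length(attr(net, "violations")))
    warning("species ", species_id,
            ": expressed compounds unreachable from the dietary set: ",
            paste(attr(net, "violations"), collapse = ", "))
  net
}

#' Build minimum and maximum networks for every species in an inventory
#'
#' When multiple inventories exist per species (sex/age variants), records
#' are pooled so the fullest network per species is used.
#'
#' @param global global network.
#' @param inventory data.frame from [read_inventory()].
#' @param kind `"minimum"`, `"maximum"`, or both.
#' @param confirmed_pairs whitelist for the diet-link rule.
#' @return named list (species) of lists with the requested networks.
#' @export
build_species_networks <- function(global, inventory,
                                   kind = c("minimum", "maximum"),
                                   confirmed_pairs = NULL) {
  kind <- match.arg(kind, several.ok = TRUE)
  out <- list()
  for (sp in sort(unique(inventory$species_id))) {
    rec <- inventory[inventory$species_id == sp, , drop = FALSE]
    roles <- classify_roles(rec)
    nets <- list()
    if ("minimum" %in% kind)
      nets$minimum <- build_minimum_network(global, roles, sp, confirmed_pairs)
    if ("maximum" %in% kind)
      nets$maximum <- build_maximum_network(global, roles, sp, confirmed_pairs)
    out[[sp]] <- nets
  }
  out
}
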