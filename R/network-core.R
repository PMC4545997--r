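#' @importFrom stats quantile sd cor lm coef pf pnorm pt qnorm anova as.dist
#' @importFrom utils read.delim read.csv write.csv combn head
NULL

# Internal representation: a carotenoid network is a list with
#   compounds : data.frame(id, name)
#   reactions : data.frame(id, substrate, product)   (unary directed edges)
#   dietary   : character vector of compound ids (the dietary entry points)
# A species network additionally carries species_id, kind ("minimum" or
# "maximum") and roles, a named list compound id -> subset of
# {"dietary", "intermediate", "expressed"}.

#' Construct a carotenoid reaction network
#'
#' A network is a directed graph whose nodes are carotenoid compounds and
#' whose edges are unary enzymatic reactions (one substrate, one product).
#' Dietary compounds are the externally ingested entry points from which all
#' metabolism starts; birds cannot synthesise carotenoids de novo.
#'
#' @param compounds character vector of compound ids, or a data.frame with
#'   columns `id` and optionally `name`.
#' @param reactions data.frame with columns `substrate` and `product`
#'   (and optionally `id`); each row is one directed reaction.
#' @param dietary character vector of compound ids flagged as dietary.
#' @param validate validate invariants (no self-loops, no parallel edges,
#'   endpoints present, dietary subset of compounds)?
#' @return an object of class `caro_network`.
#' @export
caro_network <- function(compounds, reactions = NULL, dietary = character(),
                         validate = TRUE) {
  if (is.data.frame(compounds)) {
    comp <- data.frame(id = as.character(compounds$id),
                       name = if ("name" %in% names(compounds))
                         as.character(compounds$name) else as.character(compounds$id),
                       stringsAsFactors = FALSE)
  } else {
    comp <- data.frame(id = as.character(compounds),
                       name = as.character(compounds),
                       stringsAsFactors = FALSE)
  }
  if (is.null(reactions) || nrow(as.data.frame(reactions)) == 0L) {
    rxn <- data.frame(id = character(), substrate = character(),
                      product = character(), stringsAsFactors = FALSE)
  } else {
    reactions <- as.data.frame(reactions)
    rxn <- data.frame(
      id = if ("id" %in% names(reactions)) as.character(reactions$id)
           else paste0(reactions$substrate, "->", reactions$product),
      substrate = as.character(reactions$substrate),
      product = as.character(reactions$product),
      stringsAsFactors = FALSE)
  }
  net <- structure(list(compounds = comp, reactions = rxn,
                        dietary = unique(as.character(dietary))),
                   class = "caro_network")
  if (validate) validate_network(net)
  net
}

#' Validate network invariants
#'
#' Checks id uniqueness, self-loops, parallel edges, endpoint existence and
#' that the dietary set is a subset of the compound set. Called by the
#' constructors; exported because loaders and simulators re-validate.
#'
#' @param net a `caro_network`.
#' @return `net`, invisibly; errors describe the offending row.
#' @export
validate_network <- function(net) {
  comp <- net$compounds$id
  if (anyDuplicated(comp))
    stop("duplicate compound ids: ",
         paste(unique(comp[duplicated(comp)]), collapse = ", "))
  rxn <- net$reactions
  if (nrow(rxn)) {
    loops <- rxn$substrate == rxn$product
    if (any(loops))
      stop("self-loop reaction at row ", which(loops)[1L],
           " (", rxn$substrate[which(loops)[1L]], ")")
    key <- paste(rxn$substrate, rxn$product, sep = "\r")
    if (anyDuplicated(key))
      stop("parallel duplicate reaction at row ", which(duplicated(key))[1L])
    missing <- setdiff(c(rxn$substrate, rxn$product), comp)
    if (length(missing))
      stop("reaction endpoint not in compound set: ",
           paste(missing, collapse = ", "))
  }
  extra <- setdiff(net$dietary, comp)
  if (length(extra))
    stop("dietary compounds absent from compound set: ",
         paste(extra, collapse = ", "))
  invisible(net)
}

#' Construct a per-species metabolic network
#'
#' @param species_id species identifier.
#' @param kind `"minimum"` (fewest reactions producing the plumage compounds)
#'   or `"maximum"` (all biochemically possible reactions among recorded
#'   compounds).
#' @param compounds,reactions,dietary as in [caro_network()].
#' @param roles named list mapping compound id to a character vector drawn
#'   from `c("dietary", "intermediate", "expressed")`; every compound must
#'   hold at least one role.
#' @param validate check invariants, including that every expressed
#'   non-dietary compound is reachable from a dietary compound. Reachability
#'   violations are reported as a warning and recorded in
#'   `attr(net, "violations")` rather than failing, because real inventories
#'   contain orphan observations.
#' @return an object of class `c("caro_species_network", "caro_network")`.
#' @export
species_network <- function(species_id, kind = c("minimum", "maximum"),
                            compounds, reactions = NULL, roles,
                            dietary = NULL, validate = TRUE) {
  kind <- match.arg(kind)
  if (is.null(dietary))
    dietary <- names(roles)[vapply(roles, function(r) "dietary" %in% r, TRUE)]
  net <- caro_network(compounds, reactions, dietary, validate = FALSE)
  net$species_id <- as.character(species_id)
  net$kind <- kind
  net$roles <- roles
  class(net) <- c("caro_species_network", class(net))
  if (validate) validate_species_network(net)
  net
}

#' @rdname species_network
#' @param net a species network.
#' @export
validate_species_network <- function(net) {
  validate_network(net)
  comp <- net$compounds$id
  roles <- net$roles
  if (!setequal(names(roles), comp))
    stop("roles must be given for exactly the compound set")
  bad <- names(roles)[!vapply(roles, length, 1L) |
                        !vapply(roles, function(r)
                          all(r %in% c("dietary", "intermediate", "expressed")), TRUE)]
  if (length(bad))
    stop("invalid or empty role set for: ", paste(bad, collapse = ", "))
  expressed <- role_compounds(net, "expressed")
  need <- setdiff(expressed, net$dietary)
  if (length(need)) {
    d <- distance_from_diet(net)
    orphans <- need[!is.finite(d[need])]
    if (length(orphans)) {
      attr(net, "violations") <- orphans
      warning("expressed compounds unreachable from the dietary set: ",
              paste(orphans, collapse = ", "))
    }
  }
  invisible(net)
}

#' Compounds holding a given role
#' @param net a species network.
#' @param role one of `"dietary"`, `"intermediate"`, `"expressed"`.
#' @return character vector of compound ids.
#' @export
role_compounds <- function(net, role) {
  names(net$roles)[vapply(net$roles, function(r) role %in% r, TRUE)]
}

#' Convert a network to an igraph object
#' @param net a `caro_network`.
#' @return a directed `igraph` graph with vertex names equal to compound ids.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = nrow(net$compounds), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = net$compounds$id)
  if (nrow(net$reactions))
    g <- igraph::add_edges(g, rbind(match(net$reactions$substrate, net$compounds$id),
                                    match(net$reactions$product, net$compounds$id)))
  g
}

#' @export
print.caro_network <- function(x, ...) {
  cat(sprintf("<caro_network> %d compounds, %d reactions, %d dietary\n",
              nrow(x$compounds), nrow(x$reactions), length(x$dietary)))
  invisible(x)
}

#' @export
print.caro_species_network <- function(x, ...) {
  cat(sprintf("<species network: %s (%s)> %d compounds, %d reactions, %d dietary, %d expressed\n",
              x$species_id, x$kind, nrow(x$compounds), nrow(x$reactions),
              length(x$dietary), length(role_compounds(x, "expressed"))))
  invisible(x)
}

#' Shortest distance (in reactions) from the dietary set
#'
#' Distance 0 for dietary compounds themselves; `Inf` for compounds with no
#' inbound directed path from any dietary compound.
#'
#' @param net a `caro_network`.
#' @param compound_id optional compound id(s) to query; default all.
#' @return named numeric vector of distances (reaction counts; `Inf` =
#'   unreachable).
#' @export
distance_from_diet <- function(net, compound_id = NULL) {
  ids <- net$compounds$id
  if (!is.null(compound_id)) {
    unknown <- setdiff(compound_id, ids)
    if (length(unknown))
      stop("unknown compound id: ", paste(unknown, collapse = ", "))
  }
  out <- rep(Inf, length(ids))
  names(out) <- ids
  if (length(net$dietary)) {
    g <- as_igraph(net)
    dm <- igraph::distances(g, v = net$dietary, mode = "out")
    out[colnames(dm)] <- apply(dm, 2, min)
  }
  if (is.null(compound_id)) out else out[compound_id]
}

# Longest simple directed path lengths from a set of sources, by exhaustive
# depth-first enumeration with an expansion budget. Exact at the scale of
# carotenoid networks (<= ~66 nodes, sparse); NP-hard in general, so the
# budget guards pathological inputs.
longest_simple_path <- function(net, from, to, budget = 1e6,
                                return_path = FALSE) {
  ids <- net$compounds$id
  n <- length(ids)
  adj <- vector("list", n)
  if (nrow(net$reactions)) {
    s <- match(net$reactions$substrate, ids)
    p <- match(net$reactions$product, ids)
    for (k in seq_along(s)) adj[[s[k]]] <- c(adj[[s[k]]], p[k])
  }
  is_target <- logical(n)
  is_target[match(to, ids)] <- TRUE
  best <- -1L
  best_path <- integer(0)
  expansions <- 0L
  visited <- logical(n)
  stack <- integer(n + 1L)
  dfs <- function(v, depth) {
    expansions <<- expansions + 1L
    if (expansions > budget)
      stop("longest-path search exceeded expansion budget (", budget, ")")
    stack[depth + 1L] <<- v
    if (is_target[v] && depth > best) {
      best <<- depth
      if (return_path) best_path <<- stack[seq_len(depth + 1L)]
    }
    for (w in adj[[v]]) {
      if (!visited[w]) {
        visited[w] <<- TRUE
        dfs(w, depth + 1L)
        visited[w] <<- FALSE
      }
    }
  }
  for (src in match(from, ids)) {
    visited[] <- FALSE
    visited[src] <- TRUE
    dfs(src, 0L)
  }
  if (return_path) {
    return(list(length = best, path = ids[best_path]))
  }
  best
}

#' Metabolic elongation: longest dietary-to-expressed pathway
#'
#' The maximum, over (dietary, expressed) compound pairs, of the longest
#' simple directed path length, in reactions. Species that deposit dietary
#' carotenoids unchanged ("direct deposition") score 0.
#'
#' @param net a species network with at least one expressed compound.
#' @param budget expansion budget for the exhaustive path search.
#' @return non-negative integer path length (reactions).
#' @export
longest_elongation <- function(net, budget = 1e6) {
  expressed <- role_compounds(net, "expressed")
  if (!length(expressed)) stop("nothing expressed")
  dietary <- net$dietary
  if (!length(dietary)) return(0L)
  best <- longest_simple_path(net, dietary, expressed, budget)
  max(best, 0L)
}

#' Average directed shortest-path length
#'
#' Mean shortest directed path length over all ordered reachable pairs of
#' distinct compounds; unreachable pairs are excluded and their count is
#' reported in `attr(, "n_excluded")`. The combined avian analyses gloss
#' this quantity as "network diameter".
#'
#' @param net a `caro_network` with at least two compounds.
#' @return mean path length with attribute `n_excluded`.
#' @export
avg_path_length <- function(net) {
  n <- nrow(net$compounds)
  if (n < 2L) stop("need at least two compounds")
  dm <- igraph::distances(as_igraph(net), mode = "out")
  diag(dm) <- NA
  vals <- dm[!is.na(dm)]
  finite <- vals[is.finite(vals)]
  if (!length(finite)) stop("no reachable ordered pair of compounds")
  structure(mean(finite), n_excluded = sum(!is.finite(vals)))
}

#' Newman-Girvan modularity of the best greedy partition
#'
#' Community structure is found by deterministic greedy agglomeration
#' (fast-greedy) on the undirected projection of the reaction graph;
#' `seed` fixes tie-breaking so results are reproducible.
#'
#' @param net a `caro_network` with at least one reaction.
#' @param seed integer RNG seed.
#' @return list with `membership` (named integer vector) and `modularity`.
#' @export
modularity_score <- function(net, seed = 1L) {
  if (!nrow(net$reactions)) stop("modularity undefined on an edgeless network")
  g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  cl <- igraph::cluster_fast_greedy(g)
  memb <- igraph::membership(cl)
  q <- igraph::modularity(g, memb)
  # never return a partition worse than the trivial one-community split
  # (modularity 0), which greedy agglomeration can on degenerate graphs
  if (q < 0) {
    memb[] <- 1L
    q <- igraph::modularity(g, memb)
  }
  list(membership = memb, modularity = q)
}

#' Basic connectivity statistics
#'
#' @param net a `caro_network`.
#' @return data.frame with metrics `n_compounds`, `n_reactions`,
#'   `reactions_per_compound`.
#' @export
connectivity_stats <- function(net) {
  nc <- nrow(net$compounds)
  nr <- nrow(net$reactions)
  ratio <- if (nc == 0L) {
    warning("empty network: reactions-per-compound reported as 0")
    0
  } else nr / nc
  data.frame(metric = c("n_compounds", "n_reactions", "reactions_per_compound"),
             value = c(nc, nr, ratio), stringsAsFactors = FALSE)
}

#' Restrict a species network to compounds holding one role
#'
#' Keeps compounds holding `role` and reactions with both endpoints
#' retained. Used for the role-specific divergence analyses.
#'
#' @param net a species network.
#' @param role one of `"dietary"`, `"intermediate"`, `"expressed"`.
#' @return a plain `caro_network` (roles are no longer meaningful).
#' @export
filter_role <- function(net, role) {
  keep <- role_compounds(net, role)
  rxn <- net$reactions[net$reactions$substrate %in% keep &
                         net$reactions$product %in% keep, , drop = FALSE]
  caro_network(net$compounds[net$compounds$id %in% keep, , drop = FALSE],
               rxn, intersect(net$dietary, keep))
}
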