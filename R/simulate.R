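#' Simulation configuration
#'
#' Defaults state the world the analysis assumes: a global network of 100
#' compounds with 15 dietary entry points, layered up to 8 enzymatic steps
#' from the diet with sparse cross-links; a 152-tip pure-birth phylogeny
#' rescaled to 113.5 My; fast recruitment of reactions whose substrate is
#' available (`alpha` = 1/My per candidate) against slow reaction loss
#' (`beta` = 0.002/My); dietary acquisition on a ~20 My timescale after
#' the compound is first encountered (`diet_gain` = 0.05/My) and rare
#' dietary loss (`diet_loss` = 0.002/My); and a
#' dietary-rescue generative rule in which elongation beyond the
#' accessible horizon (3 reactions from the dietary set) requires
#' acquisition of a new dietary compound.
#'
#' @param n_compounds total compounds in the global network.
#' @param n_dietary dietary entry points (layer 0).
#' @param n_reactions total reactions; `NULL` derives the count from
#'   `cross_link_prob` (backbone tree plus random adjacent-layer
#'   cross-links).
#' @param layer_depth deepest layer (max distance from diet, reactions).
#' @param cross_link_prob probability of each candidate cross-link
#'   (redundancy control) when `n_reactions` is `NULL`.
#' @param tips tree tip count.
#' @param birth,death birth-death rates (per My) before rescaling.
#' @param root_age tree height after rescaling (My).
#' @param alpha,beta per-candidate reaction gain and loss rates (events/My).
#' @param diet_gain,diet_loss dietary-compound acquisition and loss rates
#'   (events/My; loss never removes the last dietary compound).
#' @param horizon accessible-horizon cutoff (reactions) used in rescue mode.
#' @param n_expressed_obs plumage carotenoids reported per species in the
#'   emitted inventories (the deepest terminal compounds; real species
#'   express a handful of their terminal metabolites in plumage).
#' @param rescue_mode does a newly acquired dietary compound enable
#'   further elongation? Gains whose product would lie more than `horizon`
#'   reactions from the permitting dietary set are always forbidden; with
#'   rescue on, every acquired dietary compound joins that set (resetting
#'   the counter, so elongation can continue past the horizon), while with
#'   rescue off the horizon stays anchored at the founding dietary
#'   compound and acquisitions never extend it.
#' @param seed mandatory integer seed.
#' @return list of class `caro_sim_config`.
#' @export
sim_config <- function(n_compounds = 100L, n_dietary = 15L,
                       n_reactions = NULL,
                       layer_depth = 8L, cross_link_prob = 0.10,
                       tips = 152L, birth = 0.1, death = 0,
                       root_age = 113.5, alpha = 1, beta = 0.002,
                       diet_gain = 0.05, diet_loss = 0.002,
                       horizon = 3L, rescue_mode = TRUE,
                       n_expressed_obs = 6L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_compounds > n_dietary, n_dietary >= 1L, layer_depth >= 1L,
            cross_link_prob >= 0, cross_link_prob <= 1, tips >= 2L,
            alpha >= 0, beta >= 0, root_age > 0)
  if (!is.null(n_reactions) && n_reactions < n_compounds - n_dietary)
    stop("infeasible config: need n_reactions >= n_compounds - n_dietary")
  structure(as.list(environment()), class = "caro_sim_config")
}

#' Generate a layered global carotenoid-style network
#'
#' Roughly a third of the dietary compounds are root entry points (layer
#' 0); every other compound is placed on a layer 1..layer_depth and
#' receives one backbone reaction from the layer above (so every compound
#' is reachable and its distance from the root layer equals its layer).
#' Cross-links between adjacent layers add path redundancy: with
#' `cross_link_prob = 0` every non-root compound has in-degree 1 (a pure
#' out-tree). The remaining dietary compounds are drawn from the interior
#' layers: like zeaxanthin in the avian network, they are both ingestible
#' and producible, so an elongating pathway can encounter the biochemical
#' domain of another dietary entry point -- the structural basis of
#' dietary rescue.
#'
#' @param config a [sim_config()].
#' @return a validated `caro_network`.
#' @export
generate_global_network <- function(config) {
  set.seed(config$seed)
  nd <- max(1L, ceiling(config$n_dietary / 3))
  nm <- config$n_compounds - nd
  dietary <- sprintf("d%02d", seq_len(nd))
  others <- sprintf("m%03d", seq_len(nm))
  # spread non-dietary compounds over layers 1..layer_depth
  layer <- sort(rep_len(seq_len(config$layer_depth), nm))
  names(layer) <- others
  by_layer <- split(others, layer)
  by_layer <- c(list(`0` = dietary), by_layer)
  edges <- NULL
  for (l in seq_len(config$layer_depth)) {
    kids <- by_layer[[as.character(l)]]
    if (is.null(kids)) next
    parents <- by_layer[[as.character(l - 1L)]]
    src <- sample(parents, length(kids), replace = TRUE)
    edges <- rbind(edges, cbind(src, kids))
    # redundancy: extra links from the same upper layer
    if (length(parents) > 1L) {
      cand <- expand.grid(s = parents, p = kids, stringsAsFactors = FALSE)
      cand <- cand[paste(cand$s, cand$p) != paste(src, kids)[match(cand$p, kids)], ]
      if (is.null(config$n_reactions)) {
        take <- stats::runif(nrow(cand)) < config$cross_link_prob
        edges <- rbind(edges, as.matrix(cand[take, ]))
      }
    }
  }
  if (!is.null(config$n_reactions)) {
    extra_needed <- config$n_reactions - nrow(edges)
    if (extra_needed > 0L) {
      cand <- NULL
      for (l in seq_len(config$layer_depth)) {
        kids <- by_layer[[as.character(l)]]
        parents <- by_layer[[as.character(l - 1L)]]
        if (is.null(kids)) next
        cand <- rbind(cand, as.matrix(expand.grid(parents, kids,
                                                  stringsAsFactors = FALSE)))
      }
      have <- paste(edges[, 1], edges[, 2])
      cand <- cand[!paste(cand[, 1], cand[, 2]) %in% have, , drop = FALSE]
      take <- sample(nrow(cand), min(extra_needed, nrow(cand)))
      edges <- rbind(edges, cand[take, , drop = FALSE])
    }
  }
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  # interior dietary compounds: ingestible carotenoids that other
  # pathways can also reach (cf. zeaxanthin), spread over mid layers
  n_interior <- config$n_dietary - nd
  interior <- character(0)
  if (n_interior > 0L) {
    pool <- others[layer >= 2L & layer <= max(2L, config$layer_depth - 2L)]
    interior <- sort(sample(pool, min(n_interior, length(pool))))
  }
  net <- caro_network(c(dietary, others),
                      data.frame(id = sprintf("r%03d", seq_len(nrow(edges))),
                                 substrate = edges[, 1], product = edges[, 2],
                                 stringsAsFactors = FALSE),
                      dietary = c(dietary, interior))
  stopifnot(all(is.finite(distance_from_diet(net))))
  net
}

#' Generate an ultrametric birth-death phylogeny
#'
#' Birth-death tree conditioned on the tip count, rescaled to the
#' configured root age (default 113.5 My).
#'
#' @param config a [sim_config()].
#' @return an ultrametric `phylo` tree with tips `sp001`, `sp002`, ...
#' @export
generate_phylogeny <- function(config) {
  set.seed(config$seed + 1L)
  tr <- ape::rphylo(config$tips, birth = config$birth, death = config$death)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * config$root_age / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(config$tips))
  tr
}

# Internal state of one lineage: acquired dietary compounds plus the
# reactions currently wired; compounds are implied by reachability.
state_compounds <- function(st) {
  reachable_from_diet(unique(c(st$dietary, st$rxn$substrate, st$rxn$product)),
                      st$rxn$substrate, st$rxn$product, st$dietary)
}

prune_state <- function(st) {
  keep_c <- state_compounds(st)
  st$rxn <- st$rxn[st$rxn$substrate %in% keep_c & st$rxn$product %in% keep_c, ,
                   drop = FALSE]
  st
}

# BFS depth of every compound touched by the lineage's reactions from its
# dietary set; named vector, Inf = unreachable (pruned away).
lineage_depth <- function(dietary, sub, prod) {
  ids <- unique(c(dietary, sub, prod))
  depth <- rep(Inf, length(ids))
  names(depth) <- ids
  depth[dietary] <- 0
  frontier <- dietary
  g <- 0
  while (length(frontier)) {
    g <- g + 1
    nxt <- unique(prod[sub %in% frontier & !is.finite(depth[prod])])
    depth[nxt] <- g
    frontier <- nxt
  }
  depth
}

#' Simulate carotenoid network evolution along a phylogeny
#'
#' The root lineage starts from one dietary compound and its immediate
#' products. Along every branch a Gillespie process runs: frontier
#' reactions (substrate already reachable) are gained at rate `alpha`
#' each, present reactions are lost at rate `beta` each (followed by
#' pruning to keep every compound reachable from the dietary set), and
#' dietary compounds are acquired at rate `diet_gain` each -- once their
#' biochemical scope has been encountered by the lineage -- and lost at
#' rate `diet_loss` (never the last one). Gains beyond the accessible
#' horizon are forbidden; in rescue mode every acquired dietary compound
#' resets the horizon counter, so elongation past the horizon requires a
#' rescuing dietary acquisition first and can then continue, whereas with
#' rescue off the horizon is anchored at the founding dietary compound and
#' elongation stalls there.
#'
#' Tip inventories are emitted in the input format of the species
#' builders: dietary compounds as `diet` evidence, pathway end points
#' (out-degree 0) as `plumage`, other compounds as `plasma`.
#'
#' @param global global network from [generate_global_network()].
#' @param tree phylogeny from [generate_phylogeny()].
#' @param config a [sim_config()].
#' @return list with `inventories` (data.frame), `node_networks` (true
#'   networks at every node, tips included), `events` (event log), `tree`.
#' @export
simulate_network_evolution <- function(global, tree, config) {
  set.seed(config$seed + 2L)
  gs <- global$reactions$substrate
  gp <- global$reactions$product
  gkey <- paste0(gs, "->", gp)
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- tree$edge[nrow(tree$edge), 1L]
  # root the radiation at the best-connected dietary entry point so the
  # ancestral lineage has a non-empty gain frontier.
  # Lineage state: dietary compound ids + integer indices into the global
  # reaction table (compounds are implied by reachability).
  outdeg <- vapply(global$dietary, function(d) sum(gs == d), 0L)
  d0 <- global$dietary[which.max(outdeg)]
  root_diet <- d0
  prune_idx <- function(st) {
    depth <- lineage_depth(st$dietary, gs[st$rxn], gp[st$rxn])
    ok <- is.finite(depth[gs[st$rxn]]) & is.finite(depth[gp[st$rxn]])
    st$rxn <- st$rxn[ok]
    st
  }
  states <- vector("list", nn)
  states[[root]] <- prune_idx(list(dietary = d0,
                                   rxn = head(which(gs == d0), 2L)))
  ev_node <- ev_type <- ev_item <- character(0)
  ev_time <- numeric(0)
  log_event <- function(node, time, type, item) {
    ev_node <<- c(ev_node, node); ev_time <<- c(ev_time, time)
    ev_type <<- c(ev_type, type); ev_item <<- c(ev_item, item)
  }
  for (e in rev(seq_len(nrow(tree$edge)))) {
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    st <- states[[u]]
    t_len <- tree$edge.length[e]
    t_now <- 0
    node_lab <- node_name(tree, v)
    repeat {
      depth <- lineage_depth(st$dietary, gs[st$rxn], gp[st$rxn])
      comp <- names(depth)[is.finite(depth)]
      have <- logical(length(gs))
      have[st$rxn] <- TRUE
      frontier <- which(gs %in% comp & !have)
      if (length(frontier)) {
        if (config$rescue_mode) {
          # horizon measured from the full (current) dietary set: every
          # acquired dietary compound resets the counter and enables
          # further elongation
          frontier <- frontier[depth[gs[frontier]] + 1 <= config$horizon]
        } else {
          # no rescue: the horizon is anchored at the founding dietary
          # compound(s) and later acquisitions never extend it
          depth0 <- lineage_depth(intersect(root_diet, st$dietary),
                                  gs[st$rxn], gp[st$rxn])
          d0u <- rep(Inf, length(frontier))
          hit <- gs[frontier] %in% names(depth0)
          d0u[hit] <- depth0[gs[frontier][hit]]
          frontier <- frontier[d0u + 1 <= config$horizon]
        }
      }
      # a dietary compound becomes acquirable once the lineage's network
      # has encountered it (the compound is producible within the network)
      acq <- setdiff(intersect(global$dietary, comp), st$dietary)
      losable_diet <- if (length(st$dietary) > 1L) st$dietary else character(0)
      rates <- c(gain = config$alpha * length(frontier),
                 loss = config$beta * length(st$rxn),
                 dgain = config$diet_gain * length(acq),
                 dloss = config$diet_loss * length(losable_diet))
      total <- sum(rates)
      if (total <= 0) break
      t_now <- t_now + stats::rexp(1L, total)
      if (t_now > t_len) break
      kind <- sample(names(rates), 1L, prob = rates)
      if (kind == "gain") {
        k <- frontier[sample.int(length(frontier), 1L)]
        st$rxn <- c(st$rxn, k)
        log_event(node_lab, t_now, "gain_reaction", gkey[k])
      } else if (kind == "loss") {
        k <- sample.int(length(st$rxn), 1L)
        log_event(node_lab, t_now, "loss_reaction", gkey[st$rxn[k]])
        st$rxn <- st$rxn[-k]
        st <- prune_idx(st)
      } else if (kind == "dgain") {
        d <- acq[sample.int(length(acq), 1L)]
        st$dietary <- c(st$dietary, d)
        log_event(node_lab, t_now, "gain_dietary", d)
      } else {
        d <- losable_diet[sample.int(length(losable_diet), 1L)]
        st$dietary <- setdiff(st$dietary, d)
        st <- prune_idx(st)
        log_event(node_lab, t_now, "loss_dietary", d)
      }
    }
    states[[v]] <- st
  }
  events <- if (length(ev_node))
    data.frame(node = ev_node, time = ev_time, type = ev_type,
               item = ev_item, stringsAsFactors = FALSE)
  node_networks <- list()
  inventories <- NULL
  for (v in seq_len(nn)) {
    sti <- states[[v]]
    st <- list(dietary = sti$dietary,
               rxn = global$reactions[sti$rxn, , drop = FALSE])
    nm <- node_name(tree, v)
    comp <- sort(state_compounds(st))
    terminal <- comp[!comp %in% st$rxn$substrate]
    roles <- lapply(stats::setNames(comp, comp), function(x) {
      r <- character(0)
      if (x %in% st$dietary) r <- c(r, "dietary")
      if (x %in% terminal) r <- c(r, "expressed")
      if (!length(r) || (!x %in% terminal && !x %in% st$dietary))
        r <- union(r, "intermediate")
      sort(r)
    })
    rxn <- st$rxn[order(st$rxn$substrate, st$rxn$product), , drop = FALSE]
    node_networks[[nm]] <- species_network(nm, "maximum", comp, rxn, roles,
                                           validate = FALSE)
    if (v <= nt) {
      # observed inventory: plumage evidence for the deepest few terminal
      # metabolites; everything else non-dietary reported from plasma
      depth <- lineage_depth(st$dietary, st$rxn$substrate, st$rxn$product)
      term <- terminal[order(-depth[terminal], terminal)]
      expressed <- head(term, config$n_expressed_obs)
      plasma <- setdiff(comp, union(st$dietary, expressed))
      inventories <- rbind(
        inventories,
        data.frame(species_id = nm,
                   compound_id = c(st$dietary, expressed, plasma),
                   evidence = rep(c("diet", "plumage", "plasma"),
                                  c(length(st$dietary), length(expressed),
                                    length(plasma))),
                   stringsAsFactors = FALSE))
    }
  }
  list(inventories = inventories, node_networks = node_networks,
       events = events, tree = tree)
}

#' Replay an event log from the root state
#'
#' Determinism audit: applying the logged events branch by branch from the
#' reconstructed root state must reproduce every node's network exactly.
#'
#' @param sim result of [simulate_network_evolution()].
#' @param global the global network used to simulate.
#' @return named list of reaction-key/dietary sets per node, in the same
#'   shape as `sim$node_networks`.
#' @export
replay_events <- function(sim, global) {
  tree <- sim$tree
  nt <- length(tree$tip.label)
  root <- tree$edge[nrow(tree$edge), 1L]
  root_nm <- node_name(tree, root)
  rn <- sim$node_networks[[root_nm]]
  st <- list(dietary = rn$dietary, rxn = rn$reactions)
  states <- list()
  states[[root_nm]] <- st
  for (e in rev(seq_len(nrow(tree$edge)))) {
    u <- node_name(tree, tree$edge[e, 1L])
    v <- node_name(tree, tree$edge[e, 2L])
    st <- states[[u]]
    ev <- if (is.null(sim$events)) NULL else
      sim$events[sim$events$node == v, , drop = FALSE]
    if (!is.null(ev) && nrow(ev)) for (i in order(ev$time)) {
      it <- ev$item[i]
      switch(ev$type[i],
             gain_reaction = {
               parts <- strsplit(it, "->", fixed = TRUE)[[1L]]
               st$rxn <- rbind(st$rxn, data.frame(
                 id = it, substrate = parts[1L], product = parts[2L],
                 stringsAsFactors = FALSE))
             },
             loss_reaction = {
               key <- paste0(st$rxn$substrate, "->", st$rxn$product)
               st$rxn <- st$rxn[key != it, , drop = FALSE]
               st <- prune_state(st)
             },
             gain_dietary = st$dietary <- c(st$dietary, it),
             loss_dietary = {
               st$dietary <- setdiff(st$dietary, it)
               st <- prune_state(st)
             })
    }
    states[[v]] <- st
  }
  lapply(states, function(s) list(
    dietary = sort(s$dietary),
    reactions = sort(paste0(s$rxn$substrate, "->", s$rxn$product)),
    compounds = sort(state_compounds(s))))
}
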