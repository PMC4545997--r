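reachable_from_diet <- function(ids, edges_s, edges_p, dietary) {
  reached <- ids %in% dietary
  names(reached) <- ids
  repeat {
    newly <- edges_p[reached[edges_s] & !reached[edges_p]]
    if (!length(newly)) break
    reached[newly] <- TRUE
  }
  names(reached)[reached]
}

#' Reaction-knockout robustness of a species network
#'
#' For each reaction, deletes it alone and measures the fraction of
#' expressed non-dietary compounds still reachable from the dietary set;
#' robustness R is the mean of these retention fractions. Dietary
#' compounds are excluded from the numerator and denominator, since every
#' species trivially loses plumage carotenoids without dietary intake.
#' R = 1 means every expressed compound survives any single enzymatic
#' knockout (fully redundant pathways); low R means linear, vulnerable
#' pathways.
#'
#' @param net species network with >= 1 reaction and >= 1 expressed
#'   non-dietary compound.
#' @return list with `R` and `per_reaction` retention fractions.
#' @export
robustness <- function(net) {
  E <- setdiff(role_compounds(net, "expressed"), net$dietary)
  if (!length(E)) stop("metric excludes dietary compounds: no expressed non-dietary compound")
  if (!nrow(net$reactions)) stop("network has no reactions")
  ids <- net$compounds$id
  s <- net$reactions$substrate
  p <- net$reactions$product
  frac <- vapply(seq_along(s), function(k) {
    kept <- reachable_from_diet(ids, s[-k], p[-k], net$dietary)
    mean(E %in% kept)
  }, 0)
  names(frac) <- net$reactions$id
  list(R = mean(frac), per_reaction = frac)
}

#' Compound-knockout vulnerability of a species network
#'
#' Same construction as [robustness()] but deleting single compounds
#' (with their incident reactions). Dietary compounds are never knocked
#' out, since every species loses plumage carotenoids without dietary
#' intake; expressed compounds are not knocked out either (removing one
#' trivially removes itself, adding a constant). Vulnerability = 1 - mean
#' retention over intermediate-compound knockouts: the propensity for
#' disruption by deletion of any one existing compound.
#'
#' @inheritParams robustness
#' @return list with `vulnerability` and `per_compound` retention.
#' @export
vulnerability <- function(net) {
  E <- setdiff(role_compounds(net, "expressed"), net$dietary)
  if (!length(E)) stop("metric excludes dietary compounds: no expressed non-dietary compound")
  knockable <- setdiff(net$compounds$id, union(net$dietary, E))
  if (!length(knockable)) stop("no knockable (non-dietary) compound")
  ids <- net$compounds$id
  s <- net$reactions$substrate
  p <- net$reactions$product
  frac <- vapply(knockable, function(cmp) {
    keep <- s != cmp & p != cmp
    kept <- reachable_from_diet(setdiff(ids, cmp), s[keep], p[keep], net$dietary)
    mean(E %in% kept & E != cmp)
  }, 0)
  list(vulnerability = 1 - mean(frac), per_compound = frac)
}

#' Biochemical scope expansion from a dietary seed set
#'
#' Iterative network expansion: generation g holds every compound
#' reachable in at most g consecutive reactions ("biochemical
#' generations") from the seed set. With unary reactions this is
#' breadth-first layering, but reactions are evaluated by substrate
#' availability so multi-substrate extensions remain possible. A reaction
#' is counted at the first generation at which both its endpoints are
#' present. Also reports, for every other dietary compound of the global
#' network, the generation at which it is first encountered, and the
#' generation at which the whole network is covered (Inf if never).
#'
#' @param global a `caro_network`.
#' @param seeds dietary compound ids seeding the expansion.
#' @return list of class `caro_scope`: `profile` data.frame (generation,
#'   n_compounds, n_reactions, cumulative), `encounter_generation` (named,
#'   other dietary compounds), `coverage_generation`, `generation_of`
#'   (named vector, Inf = unreachable), `seeds`.
#' @export
scope_expansion <- function(global, seeds) {
  ids <- global$compounds$id
  unknown <- setdiff(seeds, ids)
  if (length(unknown)) stop("unknown seed: ", paste(unknown, collapse = ", "))
  s <- global$reactions$substrate
  p <- global$reactions$product
  gen <- rep(Inf, length(ids))
  names(gen) <- ids
  gen[seeds] <- 0
  current <- seeds
  g <- 0
  profile <- NULL
  count_at <- function() {
    have <- names(gen)[is.finite(gen)]
    c(n_compounds = length(have), n_reactions = sum(s %in% have & p %in% have))
  }
  profile <- rbind(profile, c(generation = 0, count_at()))
  repeat {
    frontier <- p[s %in% current & !is.finite(gen[p])]
    frontier <- unique(frontier)
    if (!length(frontier)) break
    g <- g + 1
    gen[frontier] <- g
    current <- names(gen)[is.finite(gen)]
    profile <- rbind(profile, c(generation = g, count_at()))
  }
  profile <- as.data.frame(profile)
  others <- setdiff(global$dietary, seeds)
  structure(list(
    seeds = seeds,
    profile = profile,
    generation_of = gen,
    encounter_generation = gen[others],
    coverage_generation = if (all(is.finite(gen))) max(gen) else Inf),
    class = "caro_scope")
}

#' Longest structurally possible metabolic pathway
#'
#' The maximum over dietary seeds of the longest simple directed path to
#' any compound of the global network -- the ceiling on metabolic
#' elongation any species network built on that global network can reach.
#'
#' @param global a `caro_network`.
#' @param diet dietary seed set (default the global dietary set).
#' @param budget path-search expansion budget.
#' @return non-negative integer (reactions).
#' @export
max_possible_elaboration <- function(global, diet = global$dietary,
                                     budget = 1e6) {
  if (!length(diet)) stop("empty diet set")
  max(longest_simple_path(global, diet, global$compounds$id, budget), 0L)
}

#' Partition compounds into evolutionarily accessible and inaccessible
#'
#' A compound is accessible if some directed path from the seed set
#' reaches it such that no stretch between consecutive dietary compounds
#' on the path exceeds `cutoff` reactions: encountering an additional
#' dietary compound "rescues" the elongating pathway and resets the
#' counter. Compounds only reachable by longer uninterrupted stretches are
#' flagged inaccessible -- linear pathways that long are unlikely to
#' persist given loss rates.
#'
#' @param global a `caro_network`.
#' @param seeds dietary seed compounds.
#' @param cutoff maximum uninterrupted stretch, in reactions (default 3;
#'   `Inf` marks nothing inaccessible).
#' @return list with `accessible`, `inaccessible`, and `counter` (minimal
#'   steps-since-last-dietary per compound; Inf = not reachable under the
#'   rule).
#' @export
accessible_horizon <- function(global, seeds, cutoff = 3) {
  stopifnot(cutoff >= 1)
  ids <- global$compounds$id
  s <- global$reactions$substrate
  p <- global$reactions$product
  counter <- rep(Inf, length(ids))
  names(counter) <- ids
  counter[seeds] <- 0
  queue <- seeds
  while (length(queue)) {
    u <- queue[1L]
    queue <- queue[-1L]
    for (v in p[s == u]) {
      step <- counter[u] + 1
      if (step > cutoff) next
      val <- if (v %in% global$dietary) 0 else step
      if (val < counter[v]) {
        counter[v] <- val
        queue <- c(queue, v)
      }
    }
  }
  list(accessible = ids[is.finite(counter)],
       inaccessible = ids[!is.finite(counter)],
       counter = counter)
}
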