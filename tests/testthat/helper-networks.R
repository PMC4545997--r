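# Small fixture networks and independent oracles used across test files.

chain_network <- function(ids = c("D", "A", "B"), dietary = ids[1],
                          expressed = ids[length(ids)]) {
  rxn <- data.frame(substrate = ids[-length(ids)], product = ids[-1],
                    stringsAsFactors = FALSE)
  roles <- lapply(stats::setNames(ids, ids), function(x) {
    r <- character(0)
    if (x %in% dietary) r <- c(r, "dietary")
    if (x %in% expressed) r <- c(r, "expressed")
    if (!length(r)) r <- "intermediate"
    r
  })
  species_network("chain", "minimum", ids, rxn, roles)
}

diamond_network <- function() {
  rxn <- data.frame(substrate = c("D", "D", "A", "C"),
                    product = c("A", "C", "B", "B"),
                    stringsAsFactors = FALSE)
  species_network("diamond", "minimum", c("D", "A", "C", "B"), rxn,
                  roles = list(D = "dietary", A = "intermediate",
                               C = "intermediate", B = "expressed"))
}

# random sparse digraph (no self-loops / parallel edges) as a caro_network
random_network <- function(n, m, n_diet = 1L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(s = ids, p = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$p, ]
  take <- sample(nrow(pairs), min(m, nrow(pairs)))
  caro_network(ids, data.frame(substrate = pairs$s[take],
                               product = pairs$p[take]),
               dietary = ids[seq_len(n_diet)])
}

# random species network built on a random DAG so dietary -> expressed
# paths exist; expressed = sinks
random_dag_species <- function(n, extra = 2L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  s <- integer(0); p <- integer(0)
  for (k in 2:n) {
    s <- c(s, sample(k - 1L, 1L))
    p <- c(p, k)
  }
  for (rep in seq_len(extra)) {
    i <- sort(sample(n, 2L))
    if (!any(s == i[1] & p == i[2])) {
      s <- c(s, i[1]); p <- c(p, i[2])
    }
  }
  rxn <- data.frame(substrate = ids[s], product = ids[p],
                    stringsAsFactors = FALSE)
  sinks <- setdiff(ids, rxn$substrate)
  roles <- lapply(stats::setNames(ids, ids), function(x) {
    r <- character(0)
    if (x == ids[1]) r <- c(r, "dietary")
    if (x %in% sinks) r <- c(r, "expressed")
    if (!length(r)) r <- "intermediate"
    r
  })
  species_network("dag", "minimum", ids, rxn, roles)
}

# independent oracle for the longest simple dietary -> target path,
# via igraph's exhaustive simple-path enumeration
oracle_longest_path <- function(net, from, to) {
  g <- as_igraph(net)
  best <- -1L
  for (d in intersect(from, igraph::V(g)$name)) {
    ps <- igraph::all_simple_paths(g, from = d,
                                   to = intersect(to, igraph::V(g)$name),
                                   mode = "out")
    if (length(ps)) best <- max(best, max(lengths(ps)) - 1L)
    if (d %in% to) best <- max(best, 0L)
  }
  best
}

# exhaustive minimum union of one shortest dietary->expressed path per
# expressed compound (oracle for build_minimum_network)
oracle_min_union <- function(global, dietary, expressed) {
  g <- as_igraph(global)
  cand <- list()
  for (e in setdiff(expressed, dietary)) {
    dm <- suppressWarnings(igraph::distances(g, v = dietary, to = e,
                                             mode = "out"))
    if (!any(is.finite(dm))) next
    best <- min(dm)
    paths <- list()
    for (d in dietary[dm[, 1] == best]) {
      ps <- igraph::all_shortest_paths(g, from = d, to = e,
                                       mode = "out")$vpaths
      paths <- c(paths, lapply(ps, function(p) {
        nm <- igraph::V(g)$name[p]
        paste(nm[-length(nm)], nm[-1], sep = "\r")
      }))
    }
    cand[[e]] <- paths
  }
  if (!length(cand)) return(0L)
  combos <- do.call(expand.grid, lapply(cand, seq_along))
  best_n <- Inf
  for (i in seq_len(nrow(combos))) {
    u <- unique(unlist(mapply(function(paths, j) paths[[j]], cand,
                              unlist(combos[i, ]), SIMPLIFY = FALSE)))
    best_n <- min(best_n, length(u))
  }
  best_n
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
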