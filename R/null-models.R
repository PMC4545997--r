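#' Degree-preserving rewiring of a reaction network
#'
#' Repeated double-edge swaps: two reactions (u1 -> v1), (u2 -> v2) are
#' replaced by (u1 -> v2), (u2 -> v1). Every node's in- and out-degree is
#' preserved exactly; swaps that would create a self-loop or a parallel
#' edge are rejected. Compound roles (dietary/expressed/intermediate) stay
#' attached to the nodes, since the dietary-to-expressed path metrics need
#' them. "Degree-preserving Erdos-Renyi randomization" is read
#' as this switching (configuration-model) null: a plain Erdos-Renyi draw
#' would not preserve degrees.
#'
#' @param net a `caro_network` (or species network).
#' @param n_swaps attempted swaps; default 10 x number of reactions.
#' @param seed integer RNG seed (determinism: same seed, same output).
#' @return the rewired network; attribute `n_accepted` counts accepted
#'   swaps.
#' @export
rewire_degree_preserving <- function(net, n_swaps = NULL, seed = 1L) {
  m <- nrow(net$reactions)
  if (m < 2L) {
    warning("fewer than two reactions: no valid swap exists, returning input")
    return(net)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * m
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  s <- net$reactions$substrate
  p <- net$reactions$product
  key <- new.env(hash = TRUE)
  for (k in seq_len(m)) assign(paste(s[k], p[k], sep = "\r"), TRUE, key)
  accepted <- 0L
  for (it in seq_len(n_swaps)) {
    ij <- sample.int(m, 2L)
    i <- ij[1L]; j <- ij[2L]
    a <- s[i]; b <- p[i]; cc <- s[j]; d <- p[j]
    if (a == d || cc == b) next                       # would self-loop
    k1 <- paste(a, d, sep = "\r"); k2 <- paste(cc, b, sep = "\r")
    if (exists(k1, key, inherits = FALSE) ||
        exists(k2, key, inherits = FALSE)) next       # would duplicate
    rm(list = c(paste(a, b, sep = "\r"), paste(cc, d, sep = "\r")),
       envir = key)
    assign(k1, TRUE, key); assign(k2, TRUE, key)
    p[i] <- d; p[j] <- b
    accepted <- accepted + 1L
  }
  out <- net
  out$reactions$substrate <- s
  out$reactions$product <- p
  out$reactions$id <- paste0(s, "->", p)
  stopifnot(identical(sort(table(c(s))), sort(table(net$reactions$substrate))))
  attr(out, "n_accepted") <- accepted
  out
}

# Evaluate one of the null-model metrics on a network; NA when undefined
# (e.g. no dietary -> expressed path survives a rewiring).
eval_network_metric <- function(net, metric, seed = 1L) {
  tryCatch(switch(metric,
                  longest_elongation = as.numeric(longest_elongation(net)),
                  modularity = modularity_score(net, seed = seed)$modularity,
                  avg_path_length = as.numeric(avg_path_length(net)),
                  stop("unknown metric: ", metric)),
           error = function(e) NA_real_)
}

#' Null distribution of a network metric under degree-preserving rewiring
#'
#' Draws `B` independent rewirings of the network, evaluates the metric on
#' each, and summarises the observed value against the null as a z-score
#' (SD units). Replicates on which the metric is undefined are excluded
#' and counted. Degree preservation is asserted on every replicate.
#'
#' @param net a species network.
#' @param metric one of `"longest_elongation"`, `"modularity"`,
#'   `"avg_path_length"`.
#' @param B number of rewired replicates (>= 100 recommended).
#' @param seed integer; replicate r uses seed `seed + r`.
#' @param n_swaps attempted swaps per replicate (default 10 x reactions).
#' @return data.frame with observed, null mean/SD, z, B, seed,
#'   `n_undefined`, and a `degenerate` flag (SD = 0 or all undefined).
#' @export
null_metric_distribution <- function(net, metric, B = 1000L, seed = 1L,
                                     n_swaps = NULL) {
  stopifnot(metric %in% c("longest_elongation", "modularity",
                          "avg_path_length"))
  observed <- eval_network_metric(net, metric, seed = seed)
  deg_in <- sort(table(net$reactions$product))
  deg_out <- sort(table(net$reactions$substrate))
  vals <- numeric(B)
  for (r in seq_len(B)) {
    rn <- rewire_degree_preserving(net, n_swaps = n_swaps, seed = seed + r)
    stopifnot(identical(sort(table(rn$reactions$product)), deg_in),
              identical(sort(table(rn$reactions$substrate)), deg_out),
              nrow(rn$reactions) == nrow(net$reactions))
    vals[r] <- eval_network_metric(rn, metric, seed = seed)
  }
  ok <- !is.na(vals)
  mu <- if (any(ok)) mean(vals[ok]) else NA_real_
  sdv <- if (sum(ok) > 1L) sd(vals[ok]) else NA_real_
  degenerate <- !any(ok) || is.na(sdv) || sdv == 0
  data.frame(metric = metric, observed = observed,
             null_mean = mu, null_sd = sdv,
             z = if (degenerate) NA_real_ else (observed - mu) / sdv,
             B = B, seed = seed, n_undefined = sum(!ok),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Null-model comparison for a set of species networks
#'
#' Runs [null_metric_distribution()] for each species and metric and
#' stacks the results, adding the per-metric mean z across species
#' (the aggregate reported alongside per-species values).
#'
#' @param networks named list of species networks.
#' @param metrics metric names.
#' @param B,seed,n_swaps passed through.
#' @return data.frame with one row per species x metric.
#' @export
null_comparison_table <- function(networks,
                                  metrics = c("longest_elongation",
                                              "modularity",
                                              "avg_path_length"),
                                  B = 1000L, seed = 1L, n_swaps = NULL) {
  out <- NULL
  i <- 0L
  for (sp in names(networks)) {
    i <- i + 1L
    for (metric in metrics) {
      row <- null_metric_distribution(networks[[sp]], metric, B = B,
                                      seed = seed + 1000L * i, n_swaps = n_swaps)
      row <- cbind(species_id = sp, row, stringsAsFactors = FALSE)
      out <- rbind(out, row)
    }
  }
  out
}
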