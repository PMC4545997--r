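#' Presence/absence character matrix from species networks
#'
#' One binary character per compound and per reaction across the union of
#' all species networks, for gain/loss model fitting and ancestral
#' reconstruction.
#'
#' @param networks named list of species networks (one per species; for
#'   paired minimum/maximum lists pass e.g. `lapply(nets, `[[`, "maximum")`).
#' @return integer matrix species x characters with attribute
#'   `char_type` (`"compound"` or `"reaction"`); reaction characters are
#'   named `"substrate->product"`, compound characters carry the compound
#'   id.
#' @export
build_character_matrix <- function(networks) {
  if (length(networks) < 2L) stop("need at least two species")
  if (anyDuplicated(names(networks))) stop("duplicate species id")
  comp_all <- sort(unique(unlist(lapply(networks, function(n) n$compounds$id))))
  rxn_all <- sort(unique(unlist(lapply(networks, function(n)
    paste0(n$reactions$substrate, "->", n$reactions$product)))))
  m <- matrix(0L, length(networks), length(comp_all) + length(rxn_all),
              dimnames = list(names(networks), c(comp_all, rxn_all)))
  for (sp in names(networks)) {
    net <- networks[[sp]]
    m[sp, net$compounds$id] <- 1L
    if (nrow(net$reactions))
      m[sp, paste0(net$reactions$substrate, "->", net$reactions$product)] <- 1L
  }
  attr(m, "char_type") <- rep(c("compound", "reaction"),
                              c(length(comp_all), length(rxn_all)))
  m
}

# 2x2 transition probability matrix of the binary gain/loss CTMC
# (state 0 = absent, 1 = present; alpha = gain rate, beta = loss rate).
transition_matrix <- function(t, alpha, beta) {
  q <- alpha + beta
  e <- exp(-q * t)
  matrix(c((beta + alpha * e) / q, beta * (1 - e) / q,
           alpha * (1 - e) / q, (alpha + beta * e) / q),
         2L, 2L)  # [from, to], column-major: P00 P10 P01 P11
}

# Postorder partial likelihoods for all characters at once.
# Returns list(L = per-node nchar x 2 matrices (row-normalised),
#              logscale = per-character accumulated log normaliser,
#              contrib = per-node contribution M %*% L passed to its parent,
#              post = postorder edge matrix, tree = reordered tree).
pruning_pass <- function(m, tree, alpha, beta) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  nchar <- ncol(m)
  m <- m[tree$tip.label, , drop = FALSE]
  L <- vector("list", nn)
  for (i in seq_len(nt)) {
    li <- matrix(0, nchar, 2L)
    li[cbind(seq_len(nchar), m[i, ] + 1L)] <- 1
    li[is.na(m[i, ]), ] <- 1
    L[[i]] <- li
  }
  for (i in (nt + 1L):nn) L[[i]] <- matrix(1, nchar, 2L)
  contrib <- vector("list", nn)
  logscale <- numeric(nchar)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    P <- transition_matrix(tree$edge.length[e], alpha, beta)
    cv <- L[[v]] %*% t(P)          # row c: sum_s P[.,s] L_v[c,s]
    mx <- pmax(cv[, 1L], cv[, 2L])
    mx[mx == 0] <- 1e-300
    cv <- cv / mx
    logscale <- logscale + log(mx)
    contrib[[v]] <- cv
    L[[u]] <- L[[u]] * cv
  }
  list(L = L, logscale = logscale, contrib = contrib, tree = tree,
       root = tree$edge[nrow(tree$edge), 1L], ntip = nt)
}

# Pooled log-likelihood of the character matrix under rates (alpha, beta)
# with stationary root prior.
gain_loss_loglik <- function(m, tree, alpha, beta) {
  pp <- pruning_pass(m, tree, alpha, beta)
  pi0 <- beta / (alpha + beta)
  lik <- pp$L[[pp$root]] %*% c(pi0, 1 - pi0)
  sum(log(lik) + pp$logscale)
}

#' Maximum-likelihood gain/loss rates for binary characters on a tree
#'
#' Fits the two-state continuous-time Markov model (absent <-> present
#' with gain rate alpha and loss rate beta, events per My) by the pruning
#' algorithm with a stationary root prior, pooling all characters
#' (`pooling = "pooled"`) or fitting each column separately
#' (`"per_character"`). Optimisation is bounded quasi-Newton on log rates
#' with three seeded starts; characters invariant across tips push
#' per-character rates to a bound and are flagged.
#'
#' @param m character matrix (species x characters, 0/1).
#' @param tree dated `phylo` tree; tips must match rownames of `m`.
#' @param pooling `"pooled"` or `"per_character"`.
#' @param seed seed for the multi-start dispersion.
#' @param bounds log-rate box constraints.
#' @return for pooled: list with `alpha`, `beta`, `loglik`, `scope`,
#'   `at_bound`; for per-character: data.frame with one row per character.
#' @export
fit_gain_loss_rates <- function(m, tree, pooling = c("pooled", "per_character"),
                                seed = 1L, bounds = log(c(1e-6, 1e3))) {
  pooling <- match.arg(pooling)
  if (!setequal(rownames(m), tree$tip.label))
    stop("matrix rows and tree tips must match")
  fit_one <- function(mm) {
    nll <- function(par) -gain_loss_loglik(mm, tree, exp(par[1]), exp(par[2]))
    set.seed(seed)
    starts <- rbind(log(c(0.05, 0.05)),
                    log(c(0.01, 0.1)) + stats::rnorm(2, 0, 0.1),
                    log(c(0.1, 0.01)) + stats::rnorm(2, 0, 0.1))
    best <- NULL
    for (srow in seq_len(nrow(starts))) {
      opt <- tryCatch(
        stats::optim(starts[srow, ], nll, method = "L-BFGS-B",
                     lower = bounds[1], upper = bounds[2],
                     control = list(factr = 1e-8 / .Machine$double.eps)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value))
        best <- opt
    }
    if (is.null(best)) stop("rate optimisation failed")
    at_bound <- any(abs(best$par - bounds[1]) < 1e-6 |
                      abs(best$par - bounds[2]) < 1e-6)
    list(alpha = exp(best$par[1]), beta = exp(best$par[2]),
         loglik = -best$value, at_bound = at_bound)
  }
  if (pooling == "pooled") {
    out <- fit_one(m)
    out$scope <- "pooled"
    out
  } else {
    rows <- lapply(colnames(m), function(ch) {
      f <- fit_one(m[, ch, drop = FALSE])
      data.frame(character = ch, alpha = f$alpha, beta = f$beta,
                 loglik = f$loglik, at_bound = f$at_bound,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
}

#' Marginal ancestral state posteriors
#'
#' Up-down (inside-outside) message passing under the fitted gain/loss
#' CTMC: for every internal node and character, the marginal posterior
#' probability of presence and the MAP state (present iff posterior >
#' 0.5; ties resolved to absent).
#'
#' @param m character matrix.
#' @param tree `phylo` tree.
#' @param rates pooled fit from [fit_gain_loss_rates()] (or any list with
#'   `alpha` and `beta`).
#' @return list with `posterior` (internal-node x character matrix of
#'   presence probabilities, rownames `"node<k>"` using ape node numbers),
#'   `map` (same shape, 0/1), `tip_states` (the observed matrix, for
#'   convenience when assembling networks at every node).
#' @export
reconstruct_states <- function(m, tree, rates) {
  alpha <- rates$alpha; beta <- rates$beta
  pp <- pruning_pass(m, tree, alpha, beta)
  tree <- pp$tree
  nt <- pp$ntip
  nn <- nt + tree$Nnode
  nchar <- ncol(m)
  pi0 <- beta / (alpha + beta)
  G <- vector("list", nn)
  G[[pp$root]] <- matrix(rep(c(pi0, 1 - pi0), each = nchar), nchar, 2L)
  # preorder = reverse postorder edge order
  for (e in rev(seq_len(nrow(tree$edge)))) {
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    sib <- L_without <- pp$L[[u]] / pmax(pp$contrib[[v]], 1e-300)
    out_u <- G[[u]] * sib
    P <- transition_matrix(tree$edge.length[e], alpha, beta)
    gv <- out_u %*% P
    gv <- gv / pmax(gv[, 1L] + gv[, 2L], 1e-300)
    G[[v]] <- gv
  }
  internal <- (nt + 1L):nn
  post <- matrix(NA_real_, length(internal), nchar,
                 dimnames = list(paste0("node", internal), colnames(m)))
  for (i in seq_along(internal)) {
    v <- internal[i]
    num <- G[[v]] * pp$L[[v]]
    post[i, ] <- num[, 2L] / pmax(num[, 1L] + num[, 2L], 1e-300)
  }
  list(posterior = post,
       map = (post > 0.5) * 1L,
       tip_states = m[tree$tip.label, , drop = FALSE],
       tree = tree)
}

#' Simulate binary characters along a tree
#'
#' Draws root states from the stationary distribution of the gain/loss
#' CTMC and evolves each character independently along every branch.
#'
#' @param tree `phylo` tree.
#' @param nchar number of characters.
#' @param alpha,beta gain and loss rates (events/My).
#' @param seed RNG seed.
#' @param root_states optional 0/1 vector of length `nchar` fixing the
#'   root states instead of drawing them from the stationary distribution.
#' @return list with `tips` (tip x character matrix) and `nodes` (all-node
#'   x character matrix of true states, rows `"node<k>"`).
#' @export
simulate_binary_characters <- function(tree, nchar, alpha, beta, seed = 1L,
                                       root_states = NULL) {
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  states <- matrix(NA_integer_, nn, nchar)
  root <- tree$edge[nrow(tree$edge), 1L]
  pi1 <- alpha / (alpha + beta)
  states[root, ] <- if (is.null(root_states))
    as.integer(stats::runif(nchar) < pi1) else as.integer(root_states)
  for (e in rev(seq_len(nrow(tree$edge)))) {
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    P <- transition_matrix(tree$edge.length[e], alpha, beta)
    p1 <- P[states[u, ] + 1L, 2L]
    states[v, ] <- as.integer(stats::runif(nchar) < p1)
  }
  tips <- states[seq_len(nt), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  colnames(tips) <- paste0("char", seq_len(nchar))
  rownames(states) <- c(tree$tip.label, paste0("node", (nt + 1L):nn))
  colnames(states) <- colnames(tips)
  list(tips = tips, nodes = states, tree = tree)
}
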