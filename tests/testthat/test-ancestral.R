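two_tip_tree <- function(t1 = 2, t2 = 3) {
  tr <- ape::read.tree(text = sprintf("(a:%g,b:%g);", t1, t2))
  tr
}

test_that("character matrices cover the union of compounds and reactions", {
  a <- chain_network(c("D", "A", "B"))
  b <- chain_network(c("X", "Y"))
  m <- build_character_matrix(list(spA = a, spB = b))
  expect_equal(ncol(m), 5L + 3L)  # 5 compounds + 3 reactions
  expect_equal(sum(m["spA", ] == 1 & m["spB", ] == 1), 0L)  # disjoint
  m2 <- build_character_matrix(list(s1 = a, s2 = a))
  expect_equal(m2["s1", ], m2["s2", ])
  expect_error(build_character_matrix(list(a = a, a = a)), "duplicate")
})

test_that("cherry likelihood matches the closed-form transition product", {
  tr <- two_tip_tree(2, 3)
  m <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("a", "b"), "x"))
  alpha <- 0.3; beta <- 0.7
  P <- function(t) {
    q <- alpha + beta; e <- exp(-q * t)
    matrix(c((beta + alpha * e) / q, beta * (1 - e) / q,
             alpha * (1 - e) / q, (alpha + beta * e) / q), 2, 2)
  }
  pi0 <- beta / (alpha + beta)
  hand <- pi0 * P(2)[1, 2] * P(3)[1, 1] +
    (1 - pi0) * P(2)[2, 2] * P(3)[2, 1]
  expect_equal(caronet:::gain_loss_loglik(m, tr, alpha, beta), log(hand),
               tolerance = 1e-10)
})

test_that("all-absent data approach likelihood one as loss dominates", {
  tr <- two_tip_tree()
  m <- matrix(0L, 2, 3, dimnames = list(c("a", "b"), paste0("c", 1:3)))
  ll <- caronet:::gain_loss_loglik(m, tr, alpha = 1e-6, beta = 50)
  expect_gt(ll, log(0.999) * 3)
})

test_that("pooled rates are recovered from simulated characters", {
  set.seed(21)
  tr <- ape::rphylo(120, 0.2, 0)
  tr$edge.length <- tr$edge.length * 100 / max(ape::node.depth.edgelength(tr))
  ok <- 0L
  for (rep in 1:5) {
    sim <- simulate_binary_characters(tr, 120, alpha = 0.02, beta = 0.05,
                                      seed = 300 + rep)
    fit <- fit_gain_loss_rates(sim$tips, tr, "pooled")
    if (abs(fit$alpha - 0.02) < 0.2 * 0.02 &&
        abs(fit$beta - 0.05) < 0.2 * 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("per-character fits flag invariant characters at the bound", {
  set.seed(5)
  tr <- ape::rphylo(30, 0.2, 0)
  m <- cbind(inv = rep(1L, 30),
             var = rep(c(0L, 1L), 15))
  rownames(m) <- tr$tip.label
  fits <- fit_gain_loss_rates(m, tr, "per_character")
  expect_equal(nrow(fits), 2L)
  expect_true(fits$at_bound[fits$character == "inv"])
})

test_that("ancestral posteriors behave at the root and under symmetry", {
  set.seed(9)
  tr <- ape::rphylo(20, 0.2, 0)
  m <- matrix(1L, 20, 2, dimnames = list(tr$tip.label, c("c1", "c2")))
  rec <- reconstruct_states(m, tr, list(alpha = 0.01, beta = 0.01))
  expect_true(all(rec$posterior[1, ] > 0.99))
  expect_true(all(rec$map == 1L))

  # symmetric cherry with opposite tips: posterior exactly 1/2, MAP absent
  cherry <- ape::read.tree(text = "(a:1,b:1);")
  mc <- matrix(c(0L, 1L), 2, 1, dimnames = list(c("a", "b"), "x"))
  rec2 <- reconstruct_states(mc, cherry, list(alpha = 0.2, beta = 0.2))
  expect_equal(unname(rec2$posterior[1, 1]), 0.5, tolerance = 1e-12)
  expect_equal(unname(rec2$map[1, 1]), 0L)

  # invariance to tip order permutation
  perm <- mc[c("b", "a"), , drop = FALSE]
  rec3 <- reconstruct_states(perm, cherry, list(alpha = 0.2, beta = 0.2))
  expect_equal(rec2$posterior, rec3$posterior)
})

test_that("reconstruction is self-consistent on resimulated data", {
  # shallow enough that the root state is identifiable (the process must
  # not have mixed: total rate x depth stays near one)
  set.seed(31)
  tr <- ape::rphylo(100, 0.2, 0)
  tr$edge.length <- tr$edge.length * 10 / max(ape::node.depth.edgelength(tr))
  sim <- simulate_binary_characters(tr, 150, alpha = 0.01, beta = 0.02,
                                    seed = 77)
  fit <- fit_gain_loss_rates(sim$tips, tr, "pooled")
  rec <- reconstruct_states(sim$tips, tr, fit)
  # simulate fresh tip data from the reconstructed root states and the
  # fitted rates, re-reconstruct, and compare root posteriors
  root_map <- rec$map[1, ]
  sim2 <- simulate_binary_characters(tr, length(root_map), fit$alpha,
                                     fit$beta, seed = 78,
                                     root_states = root_map)
  fit2 <- fit_gain_loss_rates(sim2$tips, tr, "pooled")
  rec2 <- reconstruct_states(sim2$tips, tr, fit2)
  expect_gt(cor(rec$posterior[1, ], rec2$posterior[1, ]), 0.9)
  # and posteriors separate the true root states
  truth <- sim$nodes[rownames(rec$posterior)[1], ]
  expect_gt(mean(rec$posterior[1, truth == 1]),
            mean(rec$posterior[1, truth == 0]))
})

test_that("ancestral networks apply the endpoint-consistency rule", {
  global <- caro_network(c("D", "A", "B"),
                         data.frame(substrate = c("D", "A"),
                                    product = c("A", "B")), dietary = "D")
  tip_states <- matrix(1L, 2, 5,
                       dimnames = list(c("s1", "s2"),
                                       c("A", "B", "D", "A->B", "D->A")))
  map <- matrix(c(1L, 0L, 1L, 1L, 1L), 1, 5,
                dimnames = list("node3", colnames(tip_states)))
  rec <- list(tip_states = tip_states, map = map)
  nets <- assemble_ancestral_networks(rec, global)
  # tips carry the full network
  expect_equal(nrow(nets$s1$reactions), 2L)
  # node3: B absent, so reaction A->B must be dropped
  expect_equal(nrow(nets$node3$reactions), 1L)
  expect_equal(attr(nets$node3, "n_dropped_reactions"), 1L)
  expect_equal(nets$node3$dietary, "D")
  for (n in nets) expect_silent(validate_network(n))
})

test_that("branch rates and regimes follow the quartile convention", {
  # rates 1,2,3,4: threshold 3.25, only the fastest branch is elevated
  expect_equal(unname(quantile(c(1, 2, 3, 4), 0.75)), 3.25)
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  nets <- list()
  mk <- function(n_rxn) {
    ids <- c("D", paste0("x", seq_len(max(n_rxn, 1))))
    rxn <- if (n_rxn > 0)
      data.frame(substrate = c("D", paste0("x", seq_len(n_rxn - 1)))[1:n_rxn],
                 product = paste0("x", seq_len(n_rxn)))
    roles <- lapply(stats::setNames(ids, ids), function(x)
      if (x == "D") "dietary" else "intermediate")
    species_network("m", "maximum", ids, rxn, roles, validate = FALSE)
  }
  # assign networks so gains differ per branch
  nn <- c(a = 1L, b = 2L, c = 3L, d = 4L)
  nets <- lapply(nn, mk)
  nets$node5 <- mk(0L); nets$node6 <- mk(0L); nets$node7 <- mk(0L)
  br <- branch_rates(tr, nets)
  expect_equal(sort(br$gains[br$child %in% letters[1:4]]), 1:4)
  expect_equal(br$regime[br$child == "d"], "highly_elevated")
  expect_equal(br$regime[br$child == "c"], "normal")
  expect_true(all(br$regime[br$gains == 0] == "stasis_or_shrinkage"))
  # parent = child implies rate zero / stasis
  same <- lapply(c(a = 1, b = 1, c = 1, d = 1,
                   node5 = 1, node6 = 1, node7 = 1), function(i) mk(2L))
  br2 <- branch_rates(tr, same)
  expect_true(all(br2$rate == 0))
  expect_true(all(br2$regime == "stasis_or_shrinkage"))
  # 3 gains on a 1.5 My branch = 2 reactions per My
  tr2 <- ape::read.tree(text = "(a:1.5,b:1.5);")
  nets2 <- list(a = mk(3L), b = mk(0L), node3 = mk(0L))
  br3 <- branch_rates(tr2, nets2)
  expect_equal(br3$rate[br3$child == "a"], 2)
})

test_that("sign test z reproduces printed and hand-computed values", {
  expect_equal(round(as.numeric(sign_test_z(32, 33)), 2), 5.22)
  expect_equal(as.numeric(sign_test_z(5, 10, continuity = FALSE)), 0)
  expect_equal(as.numeric(sign_test_z(8, 10)), (8 - 0.5 - 5) / sqrt(2.5),
               tolerance = 1e-12)
  expect_error(sign_test_z(11, 10))
})

test_that("dietary transitions tabulate regimes and gains", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  mk <- function(rxn_n, diet) {
    ids <- c(diet, paste0("y", seq_len(max(rxn_n, 1))))
    rxn <- if (rxn_n > 0)
      data.frame(substrate = c(diet[1], paste0("y", seq_len(rxn_n - 1)))[1:rxn_n],
                 product = paste0("y", seq_len(rxn_n)))
    roles <- lapply(stats::setNames(ids, ids), function(x)
      if (x %in% diet) "dietary" else "intermediate")
    species_network("m", "maximum", ids, rxn, roles, validate = FALSE)
  }
  # node4 = root, node5 = mrca(a,b); root->node5 has many gains
  nets <- list(node4 = mk(0L, "D"), node5 = mk(4L, "D"),
               a = mk(6L, c("D", "E")), b = mk(4L, "D"), c = mk(0L, "D"))
  br <- branch_rates(tr, nets)
  tt <- dietary_transitions(tr, br, nets)
  if (tt$n > 0) expect_lte(tt$k, tt$n)
  # no elevated branches at all
  stasis <- list(node4 = mk(2L, "D"), node5 = mk(2L, "D"),
                 a = mk(2L, "D"), b = mk(2L, "D"), c = mk(2L, "D"))
  br0 <- branch_rates(tr, stasis)
  tt0 <- dietary_transitions(tr, br0, stasis)
  expect_equal(tt0$n, 0L)
})

test_that("waiting times scale with tree length and bin by distance", {
  global <- caro_network(c("D", "A", "B"),
                         data.frame(substrate = c("D", "A"),
                                    product = c("A", "B")), dietary = "D")
  tr <- ape::read.tree(text = "(a:40,b:40):0;")  # total time 80
  mk <- function(comp) {
    roles <- lapply(stats::setNames(comp, comp), function(x)
      if (x == "D") "dietary" else "intermediate")
    species_network("m", "maximum", comp, NULL, roles, validate = FALSE)
  }
  nets <- list(node3 = mk("D"), a = mk(c("D", "B")), b = mk("D"))
  wt <- waiting_times_by_distance(tr, nets, global, B = 50L, seed = 1)
  # one gain of distance-2 compound B over 80 My of tree
  expect_equal(wt$my_per_gain[wt$distance == 2], 80)
  expect_equal(wt$gains[wt$distance == 1], 0)
  expect_equal(wt$my_per_gain[wt$distance == 1], Inf)
  # doubling branch lengths doubles waiting times
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 2
  wt2 <- waiting_times_by_distance(tr2, nets, global, B = 50L, seed = 1)
  expect_equal(wt2$my_per_gain[wt2$distance == 2], 160)
})

test_that("realized scope fractions compare node networks to the global scope", {
  global <- caro_network(c("D", "A", "B"),
                         data.frame(substrate = c("D", "A"),
                                    product = c("A", "B")), dietary = "D")
  full <- species_network("f", "maximum", c("D", "A", "B"),
                          data.frame(substrate = c("D", "A"),
                                     product = c("A", "B")),
                          roles = list(D = "dietary", A = "intermediate",
                                       B = "intermediate"))
  expect_equal(as.numeric(realized_scope_fraction(full, "D", global)), 1)
  isolated <- species_network("i", "maximum", "D", NULL,
                              roles = list(D = "dietary"))
  expect_equal(as.numeric(realized_scope_fraction(isolated, "D", global)),
               1 / 3)
  absent <- species_network("a", "maximum", "A", NULL,
                            roles = list(A = "intermediate"),
                            validate = FALSE)
  res <- realized_scope_fraction(absent, "D", global)
  expect_equal(as.numeric(res), 0)
  expect_true(attr(res, "absent"))
  expect_error(realized_scope_fraction(full, "A", global), "not a global")
})

test_that("elongation contributions attribute paths to nearest diets", {
  single <- chain_network(c("D", "A", "B"))
  expect_equal(elongation_contributions(single), c(D = 1))
  # symmetric merge: D1 -> A -> C, D2 -> B -> C, expressed C; the maximal
  # path crosses one arm, its head nearest to one diet, the tail shared
  sym <- species_network(
    "s", "minimum", c("D1", "D2", "A", "B", "C"),
    data.frame(substrate = c("D1", "D2", "A", "B"),
               product = c("A", "B", "C", "C")),
    roles = list(D1 = "dietary", D2 = "dietary", A = "intermediate",
                 B = "intermediate", C = "expressed"))
  contrib <- elongation_contributions(sym)
  expect_equal(sum(contrib), 1)
  expect_equal(unname(contrib["D1"] + contrib["D2"]), 1)
  # fractions sum to one on random networks with a pathway
  for (s in 1:10) {
    net <- random_dag_species(8, extra = 3, seed = 80 + s)
    if (longest_elongation(net) < 1) next
    expect_equal(sum(elongation_contributions(net)), 1)
  }
  direct <- species_network("d", "minimum", "L", NULL,
                            roles = list(L = c("dietary", "expressed")))
  expect_error(elongation_contributions(direct), ">= 1")
})
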