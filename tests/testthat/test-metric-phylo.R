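test_that("metabolic distance matches hand-enumerated set differences", {
  A <- caro_network(c("c1", "c2", "c3"),
                    data.frame(substrate = c("c1", "c2"),
                               product = c("c2", "c3")))
  B <- caro_network(c("c1", "c2", "c4"),
                    data.frame(substrate = c("c1", "c2"),
                               product = c("c2", "c4")))
  # compounds differ in {c3, c4}, reactions in {c2->c3, c2->c4};
  # unions: 4 compounds + 3 reactions
  expect_equal(metabolic_distance(A, B), 4 / 7)
  expect_equal(metabolic_distance(A, A), 0)
  C <- caro_network(c("x1", "x2"),
                    data.frame(substrate = "x1", product = "x2"))
  expect_equal(metabolic_distance(A, C), 1)
  expect_error(metabolic_distance(caro_network(character(0)),
                                  caro_network(character(0))), "empty")
})

test_that("metabolic distance satisfies the metric axioms", {
  for (s in 1:40) {
    n1 <- random_network(6, 7, seed = 3 * s)
    n2 <- random_network(7, 8, seed = 3 * s + 1)
    n3 <- random_network(5, 6, seed = 3 * s + 2)
    d12 <- metabolic_distance(n1, n2)
    d13 <- metabolic_distance(n1, n3)
    d23 <- metabolic_distance(n2, n3)
    expect_equal(d12, metabolic_distance(n2, n1))
    expect_lte(d12, d13 + d23 + 1e-12)
    expect_gte(d12, 0); expect_lte(d12, 1)
  }
})

test_that("role-filtered pairwise distances behave per role subnetworks", {
  mk <- function(id, expressed) {
    comp <- c("d1", expressed)
    roles <- c(list(d1 = "dietary"),
               lapply(stats::setNames(expressed, expressed),
                      function(x) "expressed"))
    suppressWarnings(species_network(id, "minimum", comp, NULL, roles))
  }
  s1 <- mk("s1", "e1"); s2 <- mk("s2", "e2")
  nets <- list(s1 = s1, s2 = s2)
  # shared dietary subnetworks are identical
  expect_equal(pairwise_matrix(nets, "dietary")["s1", "s2"], 0)
  # disjoint plumage sets are maximally distant
  expect_equal(pairwise_matrix(nets, "expressed")["s1", "s2"], 1)
  # both-empty filtered pair is missing, not zero
  expect_true(is.na(pairwise_matrix(nets, "intermediate")["s1", "s2"]))
  m <- pairwise_matrix(nets)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(s1 = 0, s2 = 0))
})

test_that("neighbour joining recovers additive matrices exactly", {
  for (s in 1:10) {
    set.seed(s)
    tr <- ape::rtree(sample(5:10, 1))
    d <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(nj, ape::unroot(tr)), 0)
    # branch lengths recovered: patristic distances match the input
    expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
  expect_error(neighbor_joining(matrix(NA, 3, 3)), "missing")
})

test_that("three taxa give the closed-form star lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  el <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(el["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(el["c"]), (4 + 5 - 3) / 2)
})

test_that("equidistant taxa resolve deterministically", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("Robinson-Foulds distance counts conflicting bipartitions", {
  set.seed(1)
  tr <- ape::rtree(10)
  expect_equal(robinson_foulds(tr, tr)$rf, 0L)
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(robinson_foulds(t1, t2)$rf, 2L)
  expect_equal(rf_max(152), 298L)
  for (s in 1:10) {
    set.seed(s)
    a <- ape::rtree(8); b <- ape::rtree(8)
    r <- robinson_foulds(a, b)
    expect_gte(r$rf, 0L); expect_lte(r$rf, r$rf_max)
  }
  big <- ape::rtree(12)
  expect_message(pr <- robinson_foulds(big, ape::keep.tip(big, big$tip.label[1:8])),
                 "pruning")
  expect_equal(pr$n, 8L)
})

test_that("strict consensus keeps only shared bipartitions", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  expect_equal(phangorn::RF.dist(strict_consensus(list(t1, t1)), t1), 0)
  q1 <- ape::read.tree(text = "((a,b),(c,d));")
  q2 <- ape::read.tree(text = "((a,c),(b,d));")
  star <- strict_consensus(list(q1, q2))
  expect_equal(star$Nnode, 1L)
})

test_that("patristic distance equals an independent root-path traversal", {
  cherry <- ape::read.tree(text = "(a:5,b:5);")
  expect_equal(patristic_distance(cherry, "a", "b"), 10)
  expect_equal(patristic_distance(cherry, "a", "a"), 0)
  expect_error(patristic_distance(cherry, "a", "zz"), "unknown tip")
  # oracle: sum of root-to-tip depths minus twice the MRCA depth
  for (s in 1:8) {
    set.seed(s)
    tr <- ape::rtree(8)
    depth <- ape::node.depth.edgelength(tr)
    tips <- sample(tr$tip.label, 2)
    i <- match(tips, tr$tip.label)
    mrca <- ape::getMRCA(tr, tips)
    oracle <- depth[i[1]] + depth[i[2]] - 2 * depth[mrca]
    expect_equal(patristic_distance(tr, tips[1], tips[2]), oracle,
                 tolerance = 1e-10)
  }
})

test_that("divergence regressions standardize to b_ST = 1 on proportional data", {
  set.seed(2)
  tr <- ape::rphylo(12, 0.2, 0)
  tr$edge.length <- tr$edge.length * 50 / max(ape::node.depth.edgelength(tr))
  pm <- patristic_matrix(tr)
  d <- pm / max(pm)  # metabolic distance exactly proportional
  res <- divergence_time_regression(list(all = d), tr, bin_width = 20)
  expect_true(all(abs(res$bins$b_st - 1) < 1e-8))
  expect_equal(res$overall$spearman_r, 1, tolerance = 1e-8)
  # shuffled distances: negligible rank correlation
  set.seed(3)
  sh <- d
  sh[upper.tri(sh)] <- sample(sh[upper.tri(sh)])
  sh[lower.tri(sh)] <- t(sh)[lower.tri(sh)]
  res2 <- divergence_time_regression(list(all = sh), tr)
  expect_lt(abs(res2$overall$spearman_r),
            3 / sqrt(res2$overall$n_pairs))
})

test_that("independent contrasts preserve linear relationships", {
  set.seed(4)
  tr <- ape::rtree(16)
  x <- stats::setNames(rnorm(16), tr$tip.label)
  y <- 2 * x
  res <- suppressWarnings(contrasts_regression(tr, x, y))  # perfect fit
  expect_equal(res$slope, 2, tolerance = 1e-10)
  expect_equal(res$b_st, 1, tolerance = 1e-10)

  # star tree: contrasts regression equals ordinary regression on scaled
  # tip differences; check against direct correlation of contrasts
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  xs <- stats::setNames(c(1, 3, 2, 5, 4), star$tip.label)
  ys <- stats::setNames(c(2, 1, 4, 3, 5), star$tip.label)
  suppressMessages(res2 <- contrasts_regression(star, xs, ys))
  expect_equal(res2$b_st,
               sum(res2$contrasts_x * res2$contrasts_y) /
                 sqrt(sum(res2$contrasts_x^2) * sum(res2$contrasts_y^2)))
})

test_that("contrasts recover a known Brownian correlation", {
  set.seed(11)
  r <- 0.7
  ests <- replicate(30, {
    tr <- ape::rphylo(100, 0.3, 0)
    a <- ape::rTraitCont(tr)
    b <- ape::rTraitCont(tr)
    x <- a
    y <- r * a + sqrt(1 - r^2) * b
    contrasts_regression(tr, x, y)$b_st
  })
  expect_lt(abs(mean(ests) - r), 0.1)
})

test_that("one-way F on dietary breadth groups matches hand computation", {
  tab <- data.frame(n_dietary = c(1, 2, 3, 4),
                    elongation = c(1, 2, 3, 4))
  res <- elongation_vs_diet_groups(tab)
  expect_equal(res$F, 8)
  expect_equal(c(res$df1, res$df2), c(1, 2))
  same <- data.frame(n_dietary = c(1, 1, 3, 3),
                     elongation = c(2, 4, 2, 4))
  expect_equal(elongation_vs_diet_groups(same)$F, 0)
  one <- data.frame(n_dietary = c(1, 1, 2), elongation = 1:3)
  expect_error(elongation_vs_diet_groups(one), "empty")
})
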