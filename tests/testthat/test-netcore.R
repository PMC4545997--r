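test_that("global network loading validates and counts correctly", {
  edges <- write_tmp(c("reaction_id\tsubstrate\tproduct",
                       "r1\ta\tb", "r2\tb\tc"))
  diet <- write_tmp(c("compound_id", "a"))
  net <- load_global_network(edges, diet)
  expect_equal(nrow(net$compounds), 3L)
  expect_equal(nrow(net$reactions), 2L)
  expect_equal(net$dietary, "a")

  loop <- write_tmp(c("reaction_id\tsubstrate\tproduct", "r1\ta\ta"))
  expect_error(load_global_network(loop, diet), "self-loop")

  dup <- write_tmp(c("reaction_id\tsubstrate\tproduct",
                     "r1\ta\tb", "r2\ta\tb"))
  expect_warning(net2 <- load_global_network(dup, diet), "duplicate")
  expect_equal(nrow(net2$reactions), 1L)

  comp <- write_tmp(c("compound_id", "a", "b"))
  miss <- write_tmp(c("reaction_id\tsubstrate\tproduct", "r1\ta\tz"))
  expect_error(load_global_network(miss, diet, comp), "not in compound table")
})

test_that("network constructor enforces invariants", {
  expect_error(caro_network(c("a", "a")), "duplicate")
  expect_error(caro_network("a", data.frame(substrate = "a", product = "a")),
               "self-loop")
  expect_error(caro_network(c("a", "b"),
                            data.frame(substrate = c("a", "a"),
                                       product = c("b", "b"))), "parallel")
  expect_error(caro_network("a", dietary = "z"), "dietary")
})

test_that("distance from diet is a shortest directed path in reactions", {
  net <- chain_network(c("D", "A", "B"))
  d <- distance_from_diet(net)
  expect_equal(unname(d[c("D", "A", "B")]), c(0, 1, 2))
  # unreachable compound
  net2 <- caro_network(c("D", "A", "B", "X"),
                       data.frame(substrate = c("D", "A"),
                                  product = c("A", "B")), dietary = "D")
  expect_equal(unname(distance_from_diet(net2, "X")), Inf)
  expect_error(distance_from_diet(net2, "zz"), "unknown")
})

test_that("distance from diet never increases when reactions are added", {
  for (s in 1:20) {
    net <- random_network(8, 10, n_diet = 2L, seed = s)
    d1 <- distance_from_diet(net)
    # add one more edge not already present
    all_pairs <- expand.grid(a = net$compounds$id, b = net$compounds$id,
                             stringsAsFactors = FALSE)
    key <- paste(net$reactions$substrate, net$reactions$product)
    all_pairs <- all_pairs[all_pairs$a != all_pairs$b &
                             !paste(all_pairs$a, all_pairs$b) %in% key, ]
    pick <- all_pairs[((s * 7) %% nrow(all_pairs)) + 1L, ]
    net2 <- caro_network(net$compounds,
                         rbind(net$reactions[c("substrate", "product")],
                               data.frame(substrate = pick$a, product = pick$b)),
                         net$dietary)
    expect_true(all(distance_from_diet(net2) <= d1))
  }
})

test_that("longest elongation matches hand examples and direct deposition", {
  expect_equal(longest_elongation(chain_network(c("D", "A", "B", "C"))), 3L)
  # direct (non-metabolized) deposition: expressed set = dietary set
  direct <- species_network("dd", "minimum", "L", NULL,
                            roles = list(L = c("dietary", "expressed")))
  expect_equal(longest_elongation(direct), 0L)
  nothing <- species_network("ne", "minimum", "L", NULL,
                             roles = list(L = "dietary"))
  expect_error(longest_elongation(nothing), "nothing expressed")
})

test_that("longest elongation equals the exhaustive simple-path oracle", {
  for (s in 1:40) {
    net <- random_dag_species(sample(5:12, 1), extra = sample(1:5, 1),
                              seed = s)
    expect_equal(longest_elongation(net),
                 oracle_longest_path(net, net$dietary,
                                     role_compounds(net, "expressed")),
                 info = paste("seed", s))
  }
})

test_that("average path length over reachable ordered pairs", {
  chain <- chain_network(c("D", "A", "B"))
  apl <- avg_path_length(chain)
  expect_equal(as.numeric(apl), 4 / 3)
  expect_equal(attr(apl, "n_excluded"), 3L)  # B->*, A->D unreachable
  single <- caro_network(c("a", "b"),
                         data.frame(substrate = "a", product = "b"))
  expect_equal(as.numeric(avg_path_length(single)), 1)
  clique <- caro_network(c("a", "b", "c"),
                         data.frame(substrate = c("a", "a", "b", "b", "c", "c"),
                                    product = c("b", "c", "a", "c", "a", "b")))
  expect_equal(as.numeric(avg_path_length(clique)), 1)
  empty <- caro_network(c("a", "b"))
  expect_error(avg_path_length(empty), "reachable")
})

test_that("modularity matches the hand-evaluated two-clique partition", {
  # two 4-cliques joined by one edge; modularity of the 2-clique split:
  # per clique e_c/m - (d_c/2m)^2 = 6/13 - (13/26)^2, twice
  ids <- c(paste0("a", 1:4), paste0("b", 1:4))
  cl <- function(v) t(combn(v, 2))
  e <- rbind(cl(ids[1:4]), cl(ids[5:8]), c("a1", "b1"))
  net <- caro_network(ids, data.frame(substrate = e[, 1], product = e[, 2]))
  res <- modularity_score(net, seed = 42)
  expect_equal(res$modularity, 2 * (6 / 13 - (13 / 26)^2), tolerance = 1e-10)
  expect_equal(length(unique(res$membership)), 2L)
  # one community on a single edge has modularity 0
  single <- caro_network(c("a", "b"),
                         data.frame(substrate = "a", product = "b"))
  expect_equal(modularity_score(single)$modularity, 0)
  expect_error(modularity_score(caro_network(c("a", "b"))), "edgeless")
})

test_that("modularity is invariant to node relabeling and deterministic", {
  net <- random_network(10, 18, seed = 3)
  m1 <- modularity_score(net, seed = 7)$modularity
  m1b <- modularity_score(net, seed = 7)$modularity
  expect_identical(m1, m1b)
  perm <- rev(net$compounds$id)
  map <- stats::setNames(sprintf("z%02d", seq_along(perm)), perm)
  net2 <- caro_network(unname(map[net$compounds$id]),
                       data.frame(substrate = unname(map[net$reactions$substrate]),
                                  product = unname(map[net$reactions$product])),
                       unname(map[net$dietary]))
  expect_equal(modularity_score(net2, seed = 7)$modularity, m1)
  # optimiser at least matches the trivial one-community partition
  for (s in 11:16) {
    rn <- random_network(10, 14, seed = s)
    expect_gte(modularity_score(rn, seed = 1)$modularity, 0)
  }
})

test_that("connectivity statistics report exact counts and ratio", {
  net <- chain_network(c("D", "A", "B"))
  st <- connectivity_stats(net)
  expect_equal(st$value[st$metric == "reactions_per_compound"], 2 / 3)
  expect_warning(st0 <- connectivity_stats(caro_network(character(0))),
                 "empty")
  expect_equal(st0$value, c(0, 0, 0))
})
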