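test_that("modularity reproduces hand-evaluated fixtures", {
  tri2 <- two_triangles()
  # everything in one community: Q = 0 by construction of the formula
  expect_equal(modularity_q(tri2, rep(1, 6)), 0)
  # the correct two-triangle split: e_c = 1/2 and a_c = 1/2 each -> Q = 1/2
  expect_equal(modularity_q(tri2, c(1, 1, 1, 2, 2, 2)), 0.5)
  # singleton partition of one triangle: -3 * (1/3)^2
  tri <- igraph::induced_subgraph(tri2, 1:3)
  tri <- igraph::set_graph_attr(tri, "maxw", 1)
  expect_equal(modularity_q(tri, 1:3), -1 / 3)
  expect_error(modularity_q(tri2, c(1, 1, 1)), "cover")
})

test_that("modularity agrees with igraph's implementation on random graphs", {
  for (seed in 1:8) {
    net <- random_weighted_graph(12, p = 0.4, seed = seed)
    if (igraph::ecount(net) == 0) next
    set.seed(seed)
    memb <- sample(1:3, 12, replace = TRUE)
    expect_equal(modularity_q(net, memb),
                 igraph::modularity(net, memb, weights = igraph::E(net)$weight),
                 tolerance = 1e-12)
  }
})

test_that("louvain recovers planted structure and reports a consistent Q", {
  tri2 <- two_triangles()
  part <- louvain(tri2, seed = 5)
  expect_equal(part$n_communities, 2)
  expect_equal(part$Q, 0.5)
  expect_length(unique(part$membership[1:3]), 1)
  expect_length(unique(part$membership[4:6]), 1)
  # reported Q always equals a from-scratch recomputation
  expect_equal(part$Q, modularity_q(tri2, part$membership), tolerance = 1e-9)

  full <- igraph::make_full_graph(7)
  igraph::V(full)$name <- paste0("n", 1:7)
  igraph::E(full)$weight <- 1
  expect_equal(louvain(full, seed = 2)$n_communities, 1)

  empty <- igraph::make_empty_graph(3, directed = FALSE)
  expect_error(louvain(empty), "no edges")
})

test_that("louvain is deterministic given the seed", {
  net <- random_weighted_graph(40, p = 0.15, seed = 9)
  p1 <- louvain(net, seed = 31)
  p2 <- louvain(net, seed = 31)
  expect_identical(p1, p2)
})

test_that("Q is non-decreasing across phases and communities relabelled by size", {
  gen <- generate_corpus(seame_like_config(seed = 2, n_utterances = 900L))
  emb <- train_sgns(gen$corpus, embedding_config(dim = 24L, epochs = 3L, seed = 2))
  net <- build_network(rownames(emb), emb)
  part <- louvain(net, seed = 3)
  expect_true(all(diff(part$phase_q) >= -1e-12))
  sizes <- as.integer(table(part$membership))
  expect_true(all(diff(sizes) <= 0))  # community 1 is the largest
  expect_equal(sort(unique(part$membership)), seq_len(part$n_communities))
  expect_equal(part$Q, modularity_q(net, part$membership), tolerance = 1e-9)
})

test_that("louvain attains the exhaustive-search optimum on most tiny graphs", {
  hits <- 0
  trials <- 20
  for (seed in seq_len(trials)) {
    n <- sample(4:7, 1)
    net <- random_weighted_graph(n, p = 0.6, seed = 100 + seed)
    if (igraph::ecount(net) < 2) {
      trials <- trials - 1
      next
    }
    best <- oracle_best_modularity(net)
    got <- louvain(net, seed = seed)$Q
    expect_lte(got, best + 1e-9)  # never exceeds the true optimum
    if (abs(got - best) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.9)
})

test_that("community composition percentages match hand counts", {
  part <- list(membership = c(a = 1, b = 1, c = 1, d = 1, e = 1,
                              f = 2, g = 2, h = 2, i = 2, j = 1,
                              k = 1, l = 1, m = 1, n = 1, o = 1))
  tags <- c(rep("L1", 9), rep("L2", 5), "other")
  names(tags) <- letters[1:15]
  comp <- community_composition(part, tags)
  expect_equal(comp$n, c(11, 4))
  # community 1: a-e, j-o -> 9 L1? hand count: L1 tags are a..i
  c1 <- names(part$membership)[part$membership == 1]
  expect_equal(comp$pct_L1[[1]], 100 * sum(tags[c1] == "L1") / 11)
  expect_equal(rowSums(comp[, grep("^pct_", names(comp))]),
               rep(100, 2), tolerance = 0.1, ignore_attr = TRUE)
  expect_error(community_composition(part, tags[1:3]), "cover")
})

test_that("planted two-language networks yield language-pure communities", {
  # direct planted-partition network: strong within-language similarity
  set.seed(8)
  n_per <- 15
  vecs <- rbind(
    matrix(rnorm(n_per * 10, mean = 0), n_per, 10) + matrix(rep(c(5, rep(0, 9)), each = n_per), n_per),
    matrix(rnorm(n_per * 10, mean = 0), n_per, 10) + matrix(rep(c(0, rep(0, 8), 5), each = n_per), n_per)
  )
  rownames(vecs) <- c(paste0("l1w", 1:n_per), paste0("l2w", 1:n_per))
  net <- build_network(data.frame(form = rownames(vecs),
                                  lang = rep(c("a", "b"), each = n_per)), vecs)
  part <- louvain(net, seed = 1)
  tags <- stats::setNames(rep(c("L1", "L2"), each = n_per), rownames(vecs))
  comp <- community_composition(part, tags)
  top2 <- utils::head(comp, 2)
  purity <- apply(top2[, grep("^pct_", names(top2))], 1, max)
  expect_true(all(purity >= 90))
})
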