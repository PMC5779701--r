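make_weight_matrix <- function(p, edges) {
  W <- matrix(0, p, p)
  for (e in edges) W[e[1], e[2]] <- W[e[2], e[1]] <- e[3]
  colnames(W) <- rownames(W) <- paste0("n", seq_len(p))
  W
}

test_that("strength sums absolute incident weights", {
  # star: hub with 3 edges of |w| = 0.2
  W <- make_weight_matrix(4, list(c(1, 2, 0.2), c(1, 3, -0.2), c(1, 4, 0.2)))
  s <- node_strength(W)
  expect_equal(unname(s), c(0.6, 0.2, 0.2, 0.2))
  # isolated node
  W2 <- make_weight_matrix(3, list(c(1, 2, 0.5)))
  expect_equal(unname(node_strength(W2))[3], 0)
})

test_that("path and triangle structures give the expected shortest-path metrics", {
  # path A - B - C with equal weights: only B is intermediate
  Wp <- make_weight_matrix(3, list(c(1, 2, 0.5), c(2, 3, 0.5)))
  sp <- shortest_path_metrics(Wp)
  expect_gt(sp$betweenness[2], 0)
  expect_equal(sp$betweenness[c(1, 3)], c(0, 0))
  expect_equal(sp$betweenness[2], 2)   # one unordered pair, both directions
  # complete triangle, equal weights: no intermediates, equal closeness
  Wt <- make_weight_matrix(3, list(c(1, 2, 0.4), c(2, 3, 0.4), c(1, 3, 0.4)))
  st <- shortest_path_metrics(Wt)
  expect_equal(st$betweenness, rep(0, 3))
  expect_equal(st$closeness, rep(st$closeness[1], 3))
  expect_equal(st$closeness[1], 1 / (2 / 0.4))
})

test_that("weighted betweenness and closeness match exhaustive path enumeration", {
  set.seed(30)
  for (rep in 1:3) {
    W <- matrix(0, 6, 6)
    up <- which(upper.tri(W))
    present <- runif(length(up)) < 0.55
    W[up[present]] <- runif(sum(present), 0.1, 0.6) *
      sample(c(-1, 1), sum(present), replace = TRUE)
    W <- W + t(W)
    colnames(W) <- rownames(W) <- paste0("v", 1:6)
    got <- shortest_path_metrics(W)
    want <- brute_force_centrality(W)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-8)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-8)
  }
})

test_that("uniform positive rescaling preserves rankings and scales strength", {
  set.seed(31)
  W <- matrix(0, 5, 5)
  up <- which(upper.tri(W))
  W[up] <- runif(length(up), 0, 0.5) * (runif(length(up)) < 0.7)
  W <- W + t(W)
  a <- shortest_path_metrics(W)
  b <- shortest_path_metrics(3 * W)
  expect_equal(rank(a$betweenness), rank(b$betweenness))
  expect_equal(rank(a$closeness), rank(b$closeness))
  expect_equal(node_strength(3 * W), 3 * node_strength(W))
})

test_that("equal-weight graphs reduce to classic unweighted betweenness", {
  W <- make_weight_matrix(5, list(c(1, 2, 0.3), c(2, 3, 0.3), c(3, 4, 0.3),
                                  c(4, 5, 0.3), c(5, 1, 0.3)))
  sp <- shortest_path_metrics(W)
  g <- igraph::graph_from_adjacency_matrix((W != 0) * 1, mode = "undirected",
                                           diag = FALSE)
  expect_equal(sp$betweenness, 2 * unname(igraph::betweenness(g)))
})

test_that("standardization is the sample z-score across nodes", {
  tab <- data.frame(node = c("a", "b"), strength = c(0.2, 0.6),
                    betweenness = c(0, 0), closeness = c(0.1, 0.2))
  expect_warning(z <- standardize_centrality(tab), "zero spread")
  expect_equal(z$z_strength, c(-1, 1) / sqrt(2), tolerance = 1e-9)
  expect_equal(z$z_betweenness, c(0, 0))
  # full table on a network: z columns have mean 0, sd 1
  d <- make_test_wave(p = 5, n = 300, seed = 33)
  ct <- centrality_table(estimate_network(d))
  expect_equal(mean(ct$z_strength), 0, tolerance = 1e-12)
  expect_equal(sd(ct$z_strength), 1, tolerance = 1e-12)
})

test_that("centrality can be restricted to a node subset before standardization", {
  d <- make_test_wave(p = 5, n = 300, seed = 34)
  net <- estimate_network(d)
  sub <- centrality_table(net, nodes = paste0("item", 1:3))
  expect_equal(nrow(sub), 3)
  expect_equal(mean(sub$z_strength), 0, tolerance = 1e-12)
  expect_error(centrality_table(net, nodes = "nope"), "unknown nodes")
})
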