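no_dupes_or_loops <- function(g) {
  e <- igraph::as_edgelist(g, names = FALSE)
  expect_false(any(e[, 1] == e[, 2]))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_false(any(duplicated(key)))
  # degree-sum identity
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
}

test_that("random networks have binomial edge counts and degenerate limits", {
  expect_equal(igraph::ecount(net_random(10, density = 0, seed = 1)), 0)
  expect_equal(igraph::ecount(net_random(10, density = 1, seed = 1)), 45)
  g <- net_random(500, density = 0.1, seed = 42)
  ci <- qbinom(c(0.005, 0.995), choose(500, 2), 0.1)
  expect_gte(igraph::ecount(g), ci[1])
  expect_lte(igraph::ecount(g), ci[2])
  no_dupes_or_loops(g)
  expect_error(net_random(10, density = 1.5), "density")
})

test_that("small-world networks keep exactly 4N edges under rewiring", {
  g0 <- net_small_world(150, rewire_p = 0, seed = 1)
  expect_true(all(igraph::degree(g0) == 8))
  expect_equal(igraph::ecount(g0), 600)
  # ring-lattice mean local clustering: 3(K-2)/(4(K-1)) with K = 8
  cc <- igraph::transitivity(g0, type = "localaverage")
  expect_equal(cc, 3 * 6 / (4 * 7), tolerance = 1e-10)
  for (p in c(0.1, 0.5, 1)) {
    g <- net_small_world(150, rewire_p = p, seed = p * 100)
    expect_equal(igraph::ecount(g), 600)
    expect_equal(igraph::vcount(g), 150)
    no_dupes_or_loops(g)
  }
  expect_error(net_small_world(8, neighbors_per_side = 4), "ring lattice")
})

test_that("scale-free networks have the closed-form edge count and heavy tails", {
  # no growth: just the seed clique
  g <- net_scale_free(5, m_attach = 4, seed = 1)
  expect_equal(igraph::ecount(g), 10)
  for (n in c(50, 200)) {
    g <- net_scale_free(n, m_attach = 4, seed = n)
    expect_equal(igraph::ecount(g), choose(5, 2) + 4 * (n - 5))
    no_dupes_or_loops(g)
  }
  # hubs: max degree exceeds 3x mean degree far more often than in a
  # density-matched random graph
  hub <- function(g) max(igraph::degree(g)) > 3 * mean(igraph::degree(g))
  n_ba <- sum(sapply(1:100, function(s) hub(net_scale_free(500, 4, seed = s))))
  n_er <- sum(sapply(1:100, function(s) hub(net_random(500, 0.016, seed = s))))
  expect_gte(n_ba, 95)
  expect_lte(n_er, 50)
  expect_error(net_scale_free(4, m_attach = 4), "m_attach")
})

test_that("generators are reproducible from their seed", {
  for (gen in list(function(s) net_random(80, 0.1, seed = s),
                   function(s) net_small_world(80, 4, 0.1, seed = s),
                   function(s) net_scale_free(80, 4, seed = s))) {
    e1 <- igraph::as_edgelist(gen(123))
    e2 <- igraph::as_edgelist(gen(123))
    e3 <- igraph::as_edgelist(gen(124))
    expect_identical(e1, e2)
    expect_false(identical(e1, e3))
  }
})

test_that("small-world networks combine high clustering with short paths", {
  cc_ws <- cc_er <- pl_ws <- pl_er <- numeric(20)
  for (s in 1:20) {
    ws <- net_small_world(150, 4, 0.1, seed = s)
    er <- net_random(150, 8 / 149, seed = s)  # matched mean degree 8
    cc_ws[s] <- igraph::transitivity(ws, type = "localaverage")
    cc_er[s] <- igraph::transitivity(er, type = "localaverage")
    pl_ws[s] <- igraph::mean_distance(ws)
    pl_er[s] <- igraph::mean_distance(er)
  }
  expect_gt(mean(cc_ws), 3 * mean(cc_er))
  expect_lt(mean(pl_ws), 2 * mean(pl_er))
})

test_that("centrality ranking is by degree with ascending-id tie-break", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  expect_equal(rank_centrality(star)[1], 1)
  ring <- net_small_world(20, 4, 0, seed = 1)  # all degrees equal
  expect_equal(rank_centrality(ring), 1:20)
  ba <- net_scale_free(200, 4, seed = 9)
  deg <- tabulate(as.vector(igraph::as_edgelist(ba, names = FALSE)), 200)
  expect_equal(rank_centrality(ba)[1], which.max(deg))
})

test_that("role assignment honors the quota and influencer placement", {
  g <- net_scale_free(150, 4, seed = 2)
  expect_length(assign_bias_roles(g, 0, seed = 1)$biased, 0)
  expect_equal(assign_bias_roles(g, 1, seed = 1)$biased, 1:150)
  expect_equal(assign_bias_roles(g, 1, "influencers", seed = 1)$biased, 1:150)
  ra <- assign_bias_roles(g, 0.30, "influencers", top_fraction = 0.10, seed = 3)
  expect_length(ra$biased, 45)
  top15 <- rank_centrality(g)[1:15]
  expect_true(all(top15 %in% ra$biased))
  # below the influencer fraction, all biased agents are top-central
  ra2 <- assign_bias_roles(g, 0.05, "influencers", seed = 3)
  expect_equal(sort(ra2$biased), sort(rank_centrality(g)[1:round(0.05 * 150)]))
  rnd <- assign_bias_roles(g, 0.30, "random", seed = 4)
  expect_length(rnd$biased, 45)
})

test_that("Louvain recovers planted structure and separates disjoint cliques", {
  cl2 <- igraph::disjoint_union(igraph::make_full_graph(5),
                                igraph::make_full_graph(5))
  part <- detect_communities(cl2, seed = 1)
  expect_equal(part$n_communities, 2)
  expect_equal(length(unique(part$membership[1:5])), 1)
  expect_equal(length(unique(part$membership[6:10])), 1)
  # planted partition: 4 blocks of 20, p_in = 0.5, p_out = 0.02
  set.seed(99)
  n <- 80; block <- rep(1:4, each = 20)
  adj <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (block[i] == block[j]) 0.5 else 0.02
    adj[i, j] <- adj[j, i] <- rbinom(1, 1, p)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  part <- detect_communities(g, seed = 5)
  expect_gt(rand_agreement(part$membership, block), 0.9)
  # seeded determinism
  expect_identical(detect_communities(g, seed = 5)$membership,
                   part$membership)
})

test_that("edge-list round trip preserves the graph", {
  g <- net_scale_free(40, 4, seed = 6)
  path <- tempfile(fileext = ".edges")
  net_write_edgelist(g, path)
  g2 <- net_read_edgelist(path, n = 40)
  expect_equal(igraph::vcount(g2), 40)
  canon <- function(g) {
    e <- igraph::as_edgelist(g, names = FALSE)
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e[order(e[, 1], e[, 2]), ]
  }
  expect_equal(canon(g), canon(g2))
  gml <- tempfile(fileext = ".graphml")
  net_write_graphml(g, gml)
  expect_true(file.exists(gml) && file.size(gml) > 0)
})
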