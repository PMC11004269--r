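test_that("symmetric graphs hit exact topology anchors", {
  k5 <- igraph::make_full_graph(5)
  topo <- topology_summary(k5)
  expect_equal(topo$edge_density, 1)
  expect_equal(topo$average_degree, 4)
  expect_equal(topo$average_path_length, 1)
  expect_equal(topo$degree_centralization, 0)
  expect_equal(topo$betweenness_centralization, 0)
  expect_equal(topo$closeness_centralization, 0)

  star <- igraph::make_star(5, mode = "undirected")
  topo <- topology_summary(star)
  expect_equal(topo$degree_centralization, 1)
  # ordered pairs: 8 hub-leaf at distance 1, 12 leaf-leaf at distance 2
  expect_equal(topo$average_path_length, (8 * 1 + 12 * 2) / 20)
  expect_equal(topo$closeness_centralization, 1)
  expect_equal(topo$betweenness_centralization, 1)
})

test_that("topology panel matches a brute-force implementation on random graphs", {
  brute <- function(g) {
    n <- igraph::vcount(g)
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    # all-pairs BFS
    d <- matrix(Inf, n, n); diag(d) <- 0
    for (s in seq_len(n)) {
      frontier <- s; dist <- 0
      while (length(frontier)) {
        dist <- dist + 1
        nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
        nxt <- nxt[d[s, nxt] == Inf & nxt != s]
        d[s, nxt] <- dist
        frontier <- nxt
      }
    }
    finite <- is.finite(d) & d > 0
    apl <- mean(d[finite])
    deg <- rowSums(adj)
    dc <- sum(max(deg) - deg) / ((n - 1) * (n - 2))
    clo <- vapply(seq_len(n), function(i) {
      reach <- which(is.finite(d[i, ]) & seq_len(n) != i)
      if (!length(reach)) return(0)
      length(reach) / sum(d[i, reach])
    }, numeric(1))
    cc <- sum(max(clo) - clo) / ((n - 1) * (n - 2) / (2 * n - 3))
    list(apl = apl, dc = dc, cc = cc)
  }
  with_seed(51, {
    for (i in 1:6) {
      g <- igraph::sample_gnp(sample(6:12, 1), runif(1, 0.25, 0.7))
      if (igraph::ecount(g) == 0) next
      topo <- topology_summary(g)
      ref <- brute(g)
      expect_equal(topo$average_path_length, ref$apl, tolerance = 1e-12)
      expect_equal(topo$degree_centralization, ref$dc, tolerance = 1e-12)
      expect_equal(topo$closeness_centralization, ref$cc, tolerance = 1e-12)
    }
  })
})

test_that("count identities hold exactly on an inferred network", {
  sim <- simulate_counts(small_design(seed = 13, n_background = 30))
  kept <- filter_taxa(sim$table)
  net <- build_network(spearman_edges(kept, rho2_threshold = 0.49),
                       sim$taxonomy)
  topo <- topology_summary(net)
  expect_identical(topo$num_pos_edges + topo$num_neg_edges, topo$edges)
  expect_equal(topo$positive_pct, 100 * topo$num_pos_edges / topo$edges)
  expect_identical(topo$bacteria_nodes + topo$fungus_nodes, topo$nodes)
  expect_equal(topo$edge_density,
               2 * topo$edges / (topo$nodes * (topo$nodes - 1)))
  expect_equal(topo$average_degree, 2 * topo$edges / topo$nodes)
})

test_that("natural connectivity matches closed forms and an independent eigensolver", {
  expect_equal(natural_connectivity(igraph::make_empty_graph(7, directed = FALSE)), 0)
  k3 <- igraph::make_full_graph(3)
  expect_equal(natural_connectivity(k3),
               log((exp(2) + 2 * exp(-1)) / 3), tolerance = 1e-9)
  expect_equal(natural_connectivity(igraph::make_full_graph(10)),
               nc_complete(10), tolerance = 1e-9)

  with_seed(52, {
    for (i in 1:5) {
      g <- igraph::sample_gnp(15, 0.3)
      a <- as.matrix(igraph::as_adjacency_matrix(g))
      ref <- log(sum(diag(as.matrix(Matrix::expm(a)))) / nrow(a))
      expect_equal(natural_connectivity(g), ref, tolerance = 1e-9)
    }
  })
})

test_that("natural connectivity is monotone under edge addition", {
  with_seed(53, {
    for (i in 1:5) {
      g <- igraph::sample_gnp(10, 0.3)
      nc0 <- natural_connectivity(g)
      missing <- which(as.matrix(igraph::as_adjacency_matrix(g)) == 0 &
                         upper.tri(matrix(0, 10, 10)), arr.ind = TRUE)
      if (nrow(missing) == 0) next
      pick <- missing[sample(nrow(missing), 1), ]
      g2 <- igraph::add_edges(g, pick)
      expect_gte(natural_connectivity(g2), nc0 - 1e-12)
    }
  })
})

test_that("robustness has exact degenerate and complete-graph behaviour", {
  k10 <- igraph::make_full_graph(10)
  expect_equal(robustness(k10, fraction = 0, n_reps = 5)$robustness_mean, 1)

  res <- robustness(k10, fraction = 0.5, n_reps = 20, seed = 2)
  expect_equal(res$robustness_mean, nc_complete(5) / nc_complete(10),
               tolerance = 1e-12)
  expect_equal(res$robustness_se, 0)

  expect_error(robustness(k10, fraction = 1.2), "fraction")
  edgeless <- igraph::make_empty_graph(5, directed = FALSE)
  expect_error(robustness(edgeless, fraction = 0.4, n_reps = 3), "undefined")
})

test_that("robustness is seed-reproducible and seed-consistent", {
  with_seed(54, g <- igraph::sample_gnp(60, 0.15))
  r1 <- robustness(g, fraction = 0.5, n_reps = 40, seed = 5)
  r2 <- robustness(g, fraction = 0.5, n_reps = 40, seed = 5)
  expect_identical(r1$ratios, r2$ratios)
  r3 <- robustness(g, fraction = 0.5, n_reps = 40, seed = 6)
  expect_false(identical(r1$ratios, r3$ratios))
  pooled_se <- sqrt(r1$robustness_se^2 + r3$robustness_se^2)
  expect_lt(abs(r1$robustness_mean - r3$robustness_mean), 3 * pooled_se)
})

test_that("the decay curve starts at the full value and matches complete-graph closed forms", {
  flat <- connectivity_decay_curve(igraph::make_empty_graph(6, directed = FALSE),
                                   step = 2, n_reps = 3, seed = 1)
  expect_true(all(flat$natural_connectivity == 0))

  k20 <- igraph::make_full_graph(20)
  curve <- connectivity_decay_curve(k20, step = 5, n_reps = 4, seed = 1)
  expect_equal(curve$nodes_removed, c(0, 5, 10, 15))
  expect_equal(curve$natural_connectivity,
               vapply(c(20, 15, 10, 5), nc_complete, numeric(1)),
               tolerance = 1e-12)
  expect_equal(curve$se, rep(0, 4))
  expect_equal(curve$natural_connectivity[1], natural_connectivity(k20))
})

test_that("decay is monotone in expectation on a planted modular network", {
  sim <- simulate_counts(small_design(seed = 14, n_background = 20))
  net <- build_network(spearman_edges(filter_taxa(sim$table),
                                      rho2_threshold = 0.49),
                       sim$taxonomy)
  curve <- connectivity_decay_curve(net, step = 25, n_reps = 8, seed = 3)
  trend <- cor(curve$nodes_removed, curve$natural_connectivity,
               method = "spearman")
  expect_lt(trend, 0)
})
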