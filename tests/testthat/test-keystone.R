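test_that("module detection separates two bridged cliques and is deterministic", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("n", 1:10)
  m1 <- detect_modules(g, seed = 3)
  expect_equal(length(unique(m1$membership)), 2)
  expect_equal(length(unique(m1$membership[1:5])), 1)
  expect_equal(length(unique(m1$membership[6:10])), 1)
  expect_identical(m1$membership, detect_modules(g, seed = 3)$membership)
  expect_identical(detect_modules(g, method = "louvain", seed = 9)$membership,
                   detect_modules(g, method = "louvain", seed = 9)$membership)
  expect_error(detect_modules(igraph::make_empty_graph(3, directed = FALSE)),
               "edge")
})

test_that("Zi-Pi anchors: within-module links give Pi 0, an even split gives 0.5", {
  # node h: 4 links split evenly between two modules -> Pi = 1 - 2*(1/2)^2
  g <- toy_graph(c("h","a1", "h","a2", "h","b1", "h","b2",
                   "a1","a2", "b1","b2"))
  mem <- c(h = 1, a1 = 1, a2 = 1, b1 = 2, b2 = 2)
  zp <- zi_pi(g, mem)
  expect_equal(zp$pi[zp$node == "h"], 0.5)
  expect_equal(zp$pi[zp$node == "a1"], 0)   # both links inside module 1
  # Zi sums to zero inside any module with spread
  for (m in unique(zp$module)) {
    zi_m <- zp$zi[zp$module == m]
    if (any(zi_m != 0)) expect_equal(sum(zi_m), 0, tolerance = 1e-12)
  }
})

test_that("Zi-Pi equals a direct per-node summation on random modular graphs", {
  with_seed(61, {
    for (rep in 1:4) {
      g <- igraph::sample_gnp(30, 0.25)
      igraph::V(g)$name <- paste0("n", 1:30)
      mem <- setNames(sample(1:4, 30, replace = TRUE), igraph::V(g)$name)
      zp <- suppressWarnings(zi_pi(g, mem))
      adj <- as.matrix(igraph::as_adjacency_matrix(g))
      for (i in sample(30, 10)) {
        ki <- sum(adj[i, ])
        k_is <- vapply(1:4, function(s) sum(adj[i, mem == s]), numeric(1))
        pi_ref <- if (ki == 0) 0 else 1 - sum((k_is / ki)^2)
        expect_equal(zp$pi[i], pi_ref, tolerance = 1e-12)
        own <- mem[i]
        in_mod <- which(mem == own)
        k_own <- vapply(in_mod, function(j) sum(adj[j, mem == own]), numeric(1))
        zi_ref <- if (length(in_mod) < 2 || sd(k_own) == 0) 0 else
          (sum(adj[i, mem == own]) - mean(k_own)) / sd(k_own)
        expect_equal(zp$zi[i], zi_ref, tolerance = 1e-12)
      }
    }
  })
})

test_that("Zi-Pi is invariant under module relabeling and warns on isolated nodes", {
  g <- toy_graph(c("a","b", "b","c", "c","a"), n = 4)
  igraph::V(g)$name <- c("a", "b", "c", "lonely")
  mem <- c(a = 1, b = 1, c = 2, lonely = 2)
  expect_warning(zp1 <- zi_pi(g, mem), "isolated")
  relabeled <- c(a = 9, b = 9, c = 4, lonely = 4)
  expect_warning(zp2 <- zi_pi(g, relabeled), "isolated")
  expect_equal(zp1$zi, zp2$zi)
  expect_equal(zp1$pi, zp2$pi)
  expect_equal(zp1$pi[zp1$node == "lonely"], 0)
})

test_that("Pi is bounded by 1 - 1/m for m modules", {
  with_seed(62, {
    for (rep in 1:5) {
      g <- igraph::sample_gnp(20, 0.4)
      igraph::V(g)$name <- paste0("n", 1:20)
      m <- sample(2:5, 1)
      mem <- setNames(sample(seq_len(m), 20, replace = TRUE),
                      igraph::V(g)$name)
      zp <- suppressWarnings(zi_pi(g, mem))
      expect_true(all(zp$pi <= 1 - 1 / m + 1e-12))
    }
  })
})

test_that("role classification uses strict thresholds and partitions all nodes", {
  df <- data.frame(node = c("mh", "co", "bo", "nh", "pe"),
                   zi = c(3.0, 0.0, 2.5, 2.6, 1.0),
                   pi = c(0.1, 0.9, 0.62, 0.70, 0.3))
  out <- classify_nodes(df)
  expect_equal(as.character(out$role),
               c("module_hub", "connector", "peripheral", "network_hub",
                 "peripheral"))
  with_seed(63, {
    rnd <- data.frame(node = 1:200, zi = rnorm(200, 1, 2),
                      pi = runif(200, 0, 0.9))
    out <- classify_nodes(rnd)
    expect_false(anyNA(out$role))
    expect_equal(sum(table(out$role)), 200)
  })
})

test_that("keystone abundance pools counts at the requested rank per treatment", {
  d <- small_design(seed = 15, n_background = 10)
  sim <- simulate_counts(d)
  md <- simulate_env_and_traits(d)

  roles <- data.frame(node = c("ASV_F001", "ASV_F002", "ASV_B0001"),
                      zi = c(3, 3, 1), pi = c(0.1, 0.1, 0.1))
  roles <- classify_nodes(roles)
  tab <- keystone_abundance(roles, sim$table, sim$taxonomy, md)
  expect_true(all(unlist(tab[, -1]) >= 0))
  # column totals equal the pooled keystone proportion per treatment
  key <- c("ASV_F001", "ASV_F002")
  for (tr in unique(md$treatment)) {
    ids <- md$sample_id[md$treatment == tr]
    manual <- sum(sim$table[key, ids]) / sum(sim$table[, ids])
    expect_equal(sum(tab[[tr]]), manual, tolerance = 1e-12)
  }
  # hubs-only selection drops the connector-less peripheral taxa the same way
  none <- keystone_abundance(classify_nodes(
    data.frame(node = "ASV_B0001", zi = 0, pi = 0)),
    sim$table, sim$taxonomy, md)
  expect_equal(nrow(none), 0)
})

test_that("the ARI helper agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  with_seed(64, {
    for (rep in 1:10) {
      a <- sample(1:4, 40, replace = TRUE)
      b <- sample(1:3, 40, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
    expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  })
})

test_that("planted modules are recovered from the inferred network", {
  ari <- vapply(c(16, 17), function(s) {
    sim <- simulate_counts(small_design(seed = s))
    net <- build_network(spearman_edges(filter_taxa(sim$table),
                                        rho2_threshold = 0.49),
                         sim$taxonomy)
    found <- detect_modules(net)
    truth <- sim$truth$module_of[names(found$membership)]
    adjusted_rand_index(found$membership, truth)
  }, numeric(1))
  expect_true(all(ari >= 0.8))
})

test_that("planted hubs concentrate in the top decile of within-module Zi", {
  tot <- 0; top <- 0
  for (s in 1:5) {
    sim <- simulate_counts(small_design(seed = 70 + s, latent = 0.90))
    kept <- filter_taxa(sim$table)
    e <- spearman_edges(kept)
    net <- build_network(e, sim$taxonomy, include_isolated = TRUE,
                         taxa = rownames(kept))
    truth <- sim$truth$module_of
    roles <- suppressWarnings(zi_pi(net, truth[igraph::V(net)$name]))
    tm <- truth[roles$node]
    for (h in intersect(sim$truth$hub_ids, roles$node)) {
      zs <- roles$zi[tm == tm[[which(roles$node == h)]]]
      tot <- tot + 1
      top <- top + (mean(zs <= roles$zi[roles$node == h]) >= 0.9)
    }
  }
  expect_gte(top / tot, 0.8)
})
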