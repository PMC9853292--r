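test_that("two disconnected 4-cliques give the exact 2-module partition, Q = 0.5", {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  igraph::V(g)$name <- as.character(1:8)
  part <- detect_modules(g)
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  mem <- part$membership$module
  expect_equal(length(unique(mem)), 2)
  expect_equal(length(unique(mem[1:4])), 1)
  expect_equal(length(unique(mem[5:8])), 1)
  expect_false(mem[1] == mem[5])
  # Q agrees with the closed-form oracle
  expect_equal(oracle_modularity(g, mem), 0.5, tolerance = 1e-12)
})

test_that("a single clique is one module with Q = 0; edgeless graphs are singletons", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- as.character(1:5)
  part <- detect_modules(k5)
  expect_equal(max(part$membership$module), 1)
  expect_equal(part$modularity, 0)

  e <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(e)$name <- c("a", "b", "c")
  pe <- detect_modules(e)
  expect_equal(pe$membership$module, 1:3)
  expect_equal(pe$modularity, 0)
})

test_that("fast-greedy Q is optimal on small separable fixtures", {
  # exhaustive search over all partitions of <= 8 nodes
  fixtures <- list(
    igraph::disjoint_union(igraph::make_full_graph(3),
                           igraph::make_full_graph(3)),
    igraph::disjoint_union(igraph::make_full_graph(4),
                           igraph::make_full_graph(3))
  )
  for (g in fixtures) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    part <- detect_modules(g)
    best <- max(vapply(all_partitions(igraph::vcount(g)),
                       function(p) oracle_modularity(g, p), numeric(1)))
    expect_equal(part$modularity, best, tolerance = 1e-12)
  }
})

test_that("detect_modules is deterministic and relabels by size", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(3))
  igraph::V(g)$name <- as.character(1:8)
  p1 <- detect_modules(g)
  p2 <- detect_modules(g)
  expect_identical(p1$membership, p2$membership)
  # module 1 is the larger clique
  expect_equal(sum(p1$membership$module == 1), 5)
})

test_that("Zi/Pi match hand-derived values on engineered nodes", {
  # node 3 has all links inside its module -> Pi = 0
  # node 7 splits its links equally between two modules -> Pi = 0.5
  g <- toy_graph(c(1, 2, 1, 3, 2, 3,   # module 1: triangle
                   4, 5, 4, 6, 5, 6,   # module 2: triangle
                   7, 1, 7, 2, 7, 4, 7, 5))  # node 7: 2 links each side
  part <- structure(list(membership = tibble::tibble(
    node = as.character(1:7),
    module = c(1, 1, 1, 2, 2, 2, 1))), class = "module_partition")
  roles <- zi_pi(g, part)
  expect_equal(roles$pi[roles$node == "3"], 0)
  expect_equal(roles$pi[roles$node == "7"], 0.5)
  # cutoff semantics: (zi, pi) = (0.3, 0.7) is a network hub
  expect_equal(oracle_role(0.3, 0.7), "network hub")
})

test_that("Zi/Pi equal the brute-force recomputation on a planted 3-module graph", {
  g <- withr::with_seed(31, {
    igraph::sample_sbm(30, pref.matrix = matrix(c(.8, .1, .05,
                                                  .1, .8, .1,
                                                  .05, .1, .8), 3),
                       block.sizes = c(10, 10, 10))
  })
  igraph::V(g)$name <- as.character(1:30)
  mod <- rep(1:3, each = 10)
  part <- structure(list(membership = tibble::tibble(
    node = as.character(1:30), module = mod)), class = "module_partition")
  roles <- zi_pi(g, part)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  oracle <- oracle_zi_pi(adj, mod)
  expect_equal(roles$zi, oracle$zi, tolerance = 1e-12)
  expect_equal(roles$pi, oracle$pi, tolerance = 1e-12)
  expect_equal(roles$role,
               mapply(oracle_role, oracle$zi, oracle$pi))
  # Zi standardisation: mean 0, sd 1 within each module where defined
  for (m in 1:3) {
    z <- roles$zi[roles$module == m]
    if (sd(roles$within_degree[roles$module == m]) > 0) {
      expect_equal(mean(z), 0, tolerance = 1e-10)
      expect_equal(sd(z), 1, tolerance = 1e-10)
    }
  }
})

test_that("module eigengene of identical profiles explains all variance", {
  prof <- c(10L, 30L, 20L, 40L)
  # filler OTU outside the module keeps the compositional closure from
  # flattening the identical member profiles
  m <- rbind(a = prof, b = prof, c = prof, filler = c(40L, 10L, 35L, 5L))
  colnames(m) <- paste0("S", 1:4)
  tbl <- count_table(m)
  part <- tibble::tibble(node = c("a", "b", "c"), module = 1)
  eg <- module_eigengene(tbl, part, 1)
  expect_equal(eg$explained_variance, 1)
  # eigengene proportional to the common standardised profile
  z <- as.numeric(scale(rel_abund_oracle(tbl)["a", ]))
  expect_equal(abs(cor(eg$eigengene, z)), 1)
  expect_gt(cor(eg$eigengene, z), 0)  # sign convention
  expect_equal(sum(eg$eigengene^2), 1)  # unit norm
})

test_that("eigengene agrees with an independent SVD oracle", {
  tbl <- toy_counts(2, 4, seed = 17)
  part <- tibble::tibble(node = tbl$otu_id, module = 1)
  eg <- module_eigengene(tbl, part, 1)
  x <- t(scale(t(rel_abund_oracle(tbl))))
  ev <- eigen(crossprod(x))
  v1 <- ev$vectors[, 1]
  if (cor(v1, colMeans(x)) < 0) v1 <- -v1
  expect_equal(unname(eg$eigengene), v1, tolerance = 1e-10)
  expect_equal(eg$explained_variance, ev$values[1] / sum(ev$values),
               tolerance = 1e-10)
})

test_that("sign convention holds across random module fixtures", {
  for (seed in 1:25) {
    tbl <- toy_counts(5, 7, seed = 100 + seed)
    part <- tibble::tibble(node = tbl$otu_id, module = 1)
    eg <- module_eigengene(tbl, part, 1)
    x <- t(scale(t(rel_abund_oracle(tbl))))
    expect_gte(cor(eg$eigengene, colMeans(x)), 0)
  }
})

test_that("constant OTU profiles are excluded with a warning", {
  m <- rbind(b = c(1L, 5L, 3L, 9L),
             c = c(2L, 6L, 4L, 10L),
             filler = c(9L, 1L, 5L, 3L))
  # 'a' is always half the column total, hence constant after closure
  m <- rbind(a = as.integer(colSums(m)), m)
  colnames(m) <- paste0("S", 1:4)
  tbl <- count_table(m)
  part <- tibble::tibble(node = c("a", "b", "c"), module = 1)
  expect_warning(eg <- module_eigengene(tbl, part, 1), "constant")
  expect_equal(eg$n_otus, 2)
})

test_that("eigengene-trait correlations recover exact and null relationships", {
  tbl <- toy_counts(6, 10, seed = 23)
  part <- tibble::tibble(node = tbl$otu_id,
                         module = rep(1:2, each = 3))
  pt <- structure(list(membership = part), class = "module_partition")
  egs <- module_eigengenes(tbl, pt)
  md <- tibble::tibble(sample_id = rownames(egs$eigengenes),
                       mirror = egs$eigengenes[, "1"],
                       flat = rep(1, 10))
  out <- eigengene_trait_correlation(egs, md, traits = c("mirror", "flat"))
  expect_equal(out$r[out$module == 1 & out$trait == "mirror"], 1,
               tolerance = 1e-12)
  expect_true(is.na(out$r[out$trait == "flat"][1]))
  expect_equal(out$stars[out$module == 1 & out$trait == "mirror"], "***")
})

test_that("star thresholds follow the 0.05/0.01/0.001 convention", {
  expect_equal(imena:::significance_stars(c(0.04, 0.009, 0.0009, 0.2, NA)),
               c("*", "**", "***", "", ""))
})

test_that("trait correlation matches the brute-force covariance formula", {
  tbl <- toy_counts(4, 6, seed = 29)
  part <- structure(list(membership = tibble::tibble(
    node = tbl$otu_id, module = 1)), class = "module_partition")
  egs <- module_eigengenes(tbl, part)
  withr::with_seed(9, y <- rnorm(6))
  md <- tibble::tibble(sample_id = rownames(egs$eigengenes), y = y)
  out <- eigengene_trait_correlation(egs, md, traits = "y")
  e <- egs$eigengenes[, 1]
  r_hand <- sum((e - mean(e)) * (y - mean(y))) /
    sqrt(sum((e - mean(e))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
})

test_that("guild subnetworks take the guild plus first neighbours", {
  g <- toy_graph(c(1, 2, 1, 3, 3, 4))
  igraph::V(g)$guild <- c("methanogen", "none", "none", "none")
  sub <- guild_subnetwork(g, "methanogen")
  expect_setequal(igraph::V(sub)$name, c("1", "2", "3"))
  expect_equal(igraph::ecount(sub), 2)

  # isolated guild node: subnetwork is just that node
  g2 <- igraph::add_vertices(g, 1, name = "5", guild = "methanotroph")
  sub2 <- guild_subnetwork(g2, "methanotroph")
  expect_equal(igraph::V(sub2)$name, "5")

  expect_warning(empty <- guild_subnetwork(g, "methanotroph"), "no nodes")
  expect_equal(igraph::vcount(empty), 0)

  # union over guilds is a subgraph of the full network
  both <- union(igraph::V(sub)$name, igraph::V(sub2)$name)
  expect_true(all(both %in% igraph::V(g2)$name))
})
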