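test_that("generate_truth lays out kingdoms, modules and guilds as asked", {
  truth <- generate_truth(n_otus = c(prokaryote = 120, fungus = 40,
                                     cercozoa = 40),
                          n_modules = 4, seed = 5)
  expect_equal(nrow(truth$otus), 200)
  expect_equal(as.integer(table(truth$otus$kingdom)[c("prokaryote", "fungus",
                                                  "cercozoa")]),
               c(120L, 40L, 40L))
  sizes <- table(truth$otus$module[truth$otus$module > 0])
  expect_length(sizes, 4)
  expect_true(all(sizes >= 3))
  # guilds only in the prokaryote pool
  g <- truth$otus[truth$otus$guild != "none", ]
  expect_true(all(g$kingdom == "prokaryote"))
  expect_true(any(truth$otus$guild == "methanogen"))
  expect_true(any(truth$otus$guild == "methanotroph"))
})

test_that("zero within-module correlation gives an identity latent matrix", {
  truth <- generate_truth(rho_within = 0, seed = 1)
  expect_equal(unname(truth$latent_correlation), diag(nrow(truth$otus)))
})

test_that("truth generation and count simulation are seed-deterministic", {
  t1 <- generate_truth(seed = 9)
  t2 <- generate_truth(seed = 9)
  expect_identical(t1$otus, t2$otus)
  c1 <- simulate_counts(t1, n_samples = 6, depth = 500, seed = 3)
  c2 <- simulate_counts(t2, n_samples = 6, depth = 500, seed = 3)
  expect_identical(c1, c2)
  c3 <- simulate_counts(t1, n_samples = 6, depth = 500, seed = 4)
  expect_false(identical(c1, c3))
})

test_that("infeasible block sizes are rejected", {
  expect_error(generate_truth(n_otus = c(prokaryote = 10), n_modules = 4,
                              module_fraction = 0.4),
               "infeasible block sizes")
})

test_that("simulated counts are compositional at the stated depths", {
  truth <- generate_truth(seed = 2)
  counts <- simulate_counts(truth, n_samples = 8,
                            depth = c(prokaryote = 2000, fungus = 800,
                                      cercozoa = 700),
                            seed = 2)
  m <- otu_matrix(counts)
  for (k in c("prokaryote", "fungus", "cercozoa")) {
    sums <- colSums(m[counts$kingdom == k, ])
    expect_true(all(sums == c(prokaryote = 2000, fungus = 800,
                              cercozoa = 700)[[k]]))
  }
  expect_warning(simulate_counts(truth, n_samples = 4, depth = 50, seed = 1),
                 "sparse")
})

test_that("planted modules induce recoverable rank correlations", {
  # Monte-Carlo check at large n: within-module Spearman far exceeds
  # between-module Spearman
  truth <- generate_truth(n_otus = c(prokaryote = 40, fungus = 10,
                                     cercozoa = 10),
                          n_modules = 2, rho_within = 0.9, seed = 6)
  counts <- simulate_counts(truth, n_samples = 500, depth = 5000, seed = 6)
  rho <- spearman_matrix(counts)$rho
  mod <- truth$otus$module[match(rownames(otu_matrix(counts)),
                                 truth$otus$otu_id)]
  same <- outer(mod, mod, "==") & outer(mod, mod, "*") > 0
  diff_mod <- outer(mod, mod, "!=")
  ut <- upper.tri(rho)
  expect_gt(mean(rho[same & ut]) - mean(rho[diff_mod & ut]), 0.5)
})

test_that("planted-structure recoverability at rho 0.9, n = 200", {
  truth <- generate_truth(n_otus = c(prokaryote = 30, fungus = 10,
                                     cercozoa = 10),
                          n_modules = 2, rho_within = 0.9, seed = 8)
  counts <- simulate_counts(truth, n_samples = 200, depth = 5000, seed = 8)
  rho <- spearman_matrix(counts)$rho
  ids <- rownames(otu_matrix(counts))
  for (m in 1:2) {
    members <- truth$otus$otu_id[truth$otus$module == m]
    sub <- rho[members, members]
    expect_true(all(sub[upper.tri(sub)] > 0.5))
  }
})

test_that("metadata linkage: noise-free flux equals the planted eigengene", {
  truth <- generate_truth(flux_link = list(module = 1, beta = 1, sigma = 0),
                          seed = 3)
  counts <- simulate_counts(truth, n_samples = 10, depth = 3000, seed = 3)
  md <- simulate_metadata(truth, counts, group_sizes = c(IL = 3, IM = 4,
                                                         IH = 3), seed = 3)
  part <- truth$otus[truth$otus$module > 0, c("otu_id", "module")]
  eg <- module_eigengene(counts, part, 1)
  expect_equal(md$ch4_flux, unname(eg$eigengene[md$sample_id]))
  expect_equal(nrow(md), 10)
  expect_equal(as.integer(table(md$group)[c("IL", "IM", "IH")]), c(3L, 4L, 3L))
})

test_that("beta = 0 decouples flux from the eigengene", {
  hits <- 0
  for (seed in 1:10) {
    truth <- generate_truth(flux_link = list(module = 1, beta = 0, sigma = 1),
                            seed = seed)
    counts <- simulate_counts(truth, n_samples = 30, depth = 3000,
                              seed = seed)
    md <- simulate_metadata(truth, counts,
                            group_sizes = c(IL = 10, IM = 10, IH = 10),
                            seed = seed)
    part <- truth$otus[truth$otus$module > 0, c("otu_id", "module")]
    eg <- module_eigengene(counts, part, 1)
    r <- cor(md$ch4_flux, unname(eg$eigengene[md$sample_id]))
    if (abs(r) < 0.4) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("group sizes must sum to the sample count; default mirrors 7/12/8", {
  truth <- generate_truth(seed = 1)
  counts <- simulate_counts(truth, n_samples = 27, depth = 1000, seed = 1)
  md <- simulate_metadata(truth, counts, seed = 1)
  expect_equal(as.integer(table(md$group)[c("IL", "IM", "IH")]), c(7L, 12L, 8L))
  expect_error(simulate_metadata(truth, counts,
                                 group_sizes = c(IL = 5, IM = 5, IH = 5)),
               "sum")
})

test_that("simulate_metadata is deterministic under its seed", {
  truth <- generate_truth(seed = 4)
  counts <- simulate_counts(truth, n_samples = 27, depth = 1000, seed = 4)
  m1 <- simulate_metadata(truth, counts, seed = 7)
  m2 <- simulate_metadata(truth, counts, seed = 7)
  expect_identical(m1, m2)
})
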