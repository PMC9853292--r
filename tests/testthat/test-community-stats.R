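test_that("Jaccard distance matches set arithmetic", {
  m <- rbind(o1 = c(1L, 0L, 5L), o2 = c(2L, 3L, 0L), o3 = c(4L, 1L, 0L),
             o4 = c(0L, 7L, 0L))
  colnames(m) <- c("A", "B", "C")
  # A = {1,2,3}, B = {2,3,4} -> 1 - 2/4 = 0.5
  d <- as.matrix(jaccard_distance(count_table(m)))
  expect_equal(d["A", "B"], 0.5)
  expect_equal(d["A", "A"], 0)
  # disjoint sets -> 1
  expect_equal(d["B", "C"], 1)
  # identical samples -> 0
  m2 <- cbind(m, D = m[, "A"])
  d2 <- as.matrix(jaccard_distance(count_table(m2)))
  expect_equal(d2["A", "D"], 0)
  expect_true(all(d2 >= 0 & d2 <= 1))
  expect_equal(d2, t(d2))
})

test_that("empty samples sit at distance 1 from everything non-empty", {
  m <- rbind(o1 = c(1L, 0L, 0L), o2 = c(2L, 0L, 0L))
  colnames(m) <- c("A", "B", "C")
  expect_warning(d <- jaccard_distance(count_table(m)), "empty")
  dm <- as.matrix(d)
  expect_equal(dm["A", "B"], 1)
  expect_equal(dm["B", "C"], 0)  # two empty samples are identical
})

test_that("Mantel r and exhaustive p match the enumeration oracle", {
  withr::with_seed(5, {
    x <- matrix(rnorm(8), 4)
    y <- matrix(rnorm(8), 4)
  })
  dx <- dist(x); dy <- dist(y)
  mt <- mantel_test(dx, dy, permutations = 999)
  orc <- oracle_mantel_exhaustive(as.matrix(dx), as.matrix(dy))
  expect_true(mt$exact)
  expect_equal(mt$r, orc$r, tolerance = 1e-12)
  expect_equal(mt$p_value, orc$p, tolerance = 1e-12)
})

test_that("Mantel basics: identity gives r = 1; sampling is seeded", {
  withr::with_seed(6, x <- matrix(rnorm(20), 10))
  dx <- dist(x)
  mt <- mantel_test(dx, dx, permutations = 99, seed = 3)
  expect_equal(mt$r, 1)
  expect_false(mt$exact)
  mt2 <- mantel_test(dx, dx, permutations = 99, seed = 3)
  expect_identical(mt$p_value, mt2$p_value)
  expect_gt(mt$p_value, 0)
  expect_lte(mt$p_value, 1)
  expect_error(mantel_test(dist(x[1:3, ]), dist(x[1:3, ])), ">= 4")
})

test_that("Mantel r agrees with the vegan implementation", {
  withr::with_seed(8, {
    x <- matrix(rnorm(30), 10)
    y <- matrix(rnorm(30), 10)
  })
  mt <- mantel_test(dist(x), dist(y), permutations = 99, seed = 1)
  vg <- vegan::mantel(dist(x), dist(y), permutations = 99)
  expect_equal(mt$r, unname(vg$statistic), tolerance = 1e-12)
})

test_that("Mantel r is invariant to a common relabelling of both matrices", {
  withr::with_seed(9, {
    x <- matrix(rnorm(24), 8)
    y <- matrix(rnorm(24), 8)
  })
  mx <- as.matrix(dist(x)); my <- as.matrix(dist(y))
  rownames(mx) <- colnames(mx) <- rownames(my) <- colnames(my) <-
    paste0("S", 1:8)
  r1 <- mantel_test(mx, my, permutations = 9, seed = 1)$r
  ord <- c(3, 1, 8, 5, 2, 7, 4, 6)
  r2 <- mantel_test(mx[ord, ord], my[ord, ord], permutations = 9, seed = 1)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("trait distances are Euclidean on the standardised trait", {
  md <- tibble::tibble(sample_id = c("a", "b", "c"), TN = c(1, 2, 4))
  d <- as.matrix(trait_distance(md, "TN"))
  z <- as.numeric(scale(c(1, 2, 4)))
  expect_equal(d["a", "b"], abs(z[1] - z[2]))
  expect_error(trait_distance(md, "missing_trait"), "not in metadata")
})

test_that("PCA recovers a known principal axis and handles duplicates", {
  # rank-1 composition (equal column totals, two identical OTUs): PC1
  # carries all the variance and loads equally on the collinear pair
  a <- c(2L, 4L, 6L, 8L)
  m <- rbind(a = a, b = a, c = 16L - 2L * a)
  colnames(m) <- paste0("S", 1:4)
  ord <- pca_ordination(count_table(m))
  expect_equal(sum(ord$explained_variance), 1)
  expect_equal(ord$explained_variance[1], 1)
  pc <- prcomp(t(sweep(m, 2, colSums(m), "/")), center = TRUE)
  expect_equal(abs(pc$rotation["a", 1]), abs(pc$rotation["b", 1]))
  expect_equal(abs(pc$rotation["c", 1]), 2 * abs(pc$rotation["a", 1]))

  # duplicated samples -> identical scores
  tbl <- toy_counts(5, 4, seed = 44)
  m2 <- otu_matrix(tbl)
  m2 <- cbind(m2, S05 = m2[, 1])
  ord2 <- pca_ordination(count_table(m2))
  expect_equal(unlist(ord2$scores[1, -1]), unlist(ord2$scores[5, -1]))
})

test_that("dissimilarity tests separate disjoint groups and respect seeds", {
  m <- cbind(matrix(c(5L, 6L, 7L, 0L, 0L, 0L), 6, 3),
             matrix(c(0L, 0L, 0L, 4L, 8L, 2L), 6, 3))
  rownames(m) <- paste0("o", 1:6)
  colnames(m) <- paste0("S", 1:6)
  d <- jaccard_distance(count_table(m))
  g <- rep(c("A", "B"), each = 3)
  out <- dissimilarity_tests(d, g, permutations = 99, seed = 1)
  expect_equal(out$statistic[out$statistic_name == "R"], 1)  # ANOSIM R
  expect_true(all(out$p_value > 0, na.rm = TRUE))
  out2 <- dissimilarity_tests(d, g, permutations = 99, seed = 1)
  expect_identical(out, out2)
  expect_warning(dissimilarity_tests(d, c("A", "A", "A", "B", "B", "C"),
                                     permutations = 9, seed = 1),
                 "singleton")
})

test_that("one-way ANOVA matches the hand-computed F on a 2x3 toy", {
  v <- c(1, 2, 3, 7, 8, 9)
  g <- rep(c("a", "b"), each = 3)
  out <- group_anova(v, g)
  # SSB = 54, SSW = 4, F = 54 / (4/4) = 54
  expect_equal(out$f_statistic, 54, tolerance = 1e-12)
  expect_equal(out$df_between, 1)
  expect_equal(out$df_within, 4)

  # identical group means -> F = 0
  out0 <- group_anova(c(1, 3, 1, 3), c("a", "a", "b", "b"))
  expect_equal(out0$f_statistic, 0)
})

test_that("flux regression reports R2, slope and p", {
  x <- 1:10
  y <- 3 + 2 * x
  out <- suppressWarnings(flux_regression(x, y))  # perfect-fit lm warning
  expect_equal(out$r_squared, 1)
  expect_equal(out$slope, 2)
  withr::with_seed(2, y2 <- y + rnorm(10, 0, 3))
  out2 <- flux_regression(x, y2)
  sm <- summary(lm(y2 ~ x))
  expect_equal(out2$r_squared, sm$r.squared)
  expect_equal(out2$p_value, sm$coefficients[2, 4])
})
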