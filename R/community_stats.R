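# Community-level statistics: Jaccard distances, Mantel tests, PCA,
# dissimilarity tests, ANOVA and regression.

#' Jaccard distance between samples
#'
#' Presence/absence Jaccard: `d = 1 - |A ∩ B| / |A ∪ B|` over the OTU sets of
#' each sample pair. Computed on the (typically rarefied) count table. A
#' sample with no OTUs is at distance 1 from every non-empty sample (flagged
#' with a warning) and 0 from another empty one.
#'
#' @param table A count table tibble.
#' @return A `dist` object over samples with attribute `metric = "jaccard"`.
#' @export
jaccard_distance <- function(table) {
  validate_count_table(table)
  pa <- t(otu_matrix(table) > 0)  # samples x OTUs
  empty <- rowSums(pa) == 0
  if (any(empty)) {
    warning("empty sample(s): ", paste(rownames(pa)[empty], collapse = ", "),
            call. = FALSE)
  }
  d <- suppressWarnings(vegan::vegdist(pa, method = "jaccard", binary = TRUE))
  m <- as.matrix(d)
  if (any(empty)) {
    m[empty, ] <- 1
    m[, empty] <- 1
    m[empty, empty] <- 0
    diag(m) <- 0
    d <- stats::as.dist(m)
  }
  attr(d, "metric") <- "jaccard"
  d
}

#' Euclidean distance on one standardised trait
#'
#' The per-variable distance used by trait-vs-community Mantel tables:
#' standardise the trait to mean 0, sd 1, then take Euclidean distances.
#'
#' @param metadata Metadata tibble.
#' @param trait Trait column name.
#' @return A `dist` object labelled by `sample_id`.
#' @export
trait_distance <- function(metadata, trait) {
  x <- metadata[[trait]]
  if (is.null(x)) stop("trait not in metadata: ", trait, call. = FALSE)
  z <- as.numeric(scale(x))
  d <- dist(matrix(z, dimnames = list(metadata$sample_id, NULL)))
  attr(d, "metric") <- paste0("euclidean(", trait, ")")
  d
}

#' Mantel test between two distance matrices
#'
#' `r` is the Pearson correlation of the lower-triangle entries; the p-value
#' is one-sided (upper tail, the Mantel convention) with the add-one rule
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + B)`, permuting one matrix's
#' row/column labels jointly. When the number of non-identity permutations
#' `n! - 1` does not exceed `permutations`, the test enumerates all of them
#' and the p-value is exact.
#'
#' @param dx,dy `dist` objects (or square matrices) over the same samples.
#' @param permutations Number of label permutations.
#' @param seed Integer seed (used only when sampling permutations).
#' @return An object of class `mantel_test`: list with `r`, `p_value`,
#'   `permutations`, `exact`.
#' @export
mantel_test <- function(dx, dy, permutations = 999, seed = 1) {
  mx <- as.matrix(dx)
  my <- as.matrix(dy)
  n <- nrow(mx)
  if (n < 4) stop("Mantel test needs >= 4 samples", call. = FALSE)
  if (!all(dim(my) == n)) stop("distance matrices differ in size", call. = FALSE)
  if (!is.null(rownames(mx)) && !is.null(rownames(my))) {
    if (!setequal(rownames(mx), rownames(my))) {
      stop("distance matrices cover different samples", call. = FALSE)
    }
    my <- my[rownames(mx), rownames(mx)]
  }
  lt <- lower.tri(mx)
  if (sd(mx[lt]) == 0 || sd(my[lt]) == 0) {
    warning("constant distance matrix; Mantel r undefined", call. = FALSE)
    return(structure(list(r = NA_real_, p_value = NA_real_,
                          permutations = permutations, exact = FALSE),
                     class = "mantel_test"))
  }
  r_obs <- cor(mx[lt], my[lt])
  perm_r <- function(ord) {
    mp <- my[ord, ord]
    cor(mx[lt], mp[lt])
  }
  n_all <- factorial(n) - 1
  if (n_all <= permutations) {
    perms <- perm_enumerate(n)
    rs <- vapply(perms, perm_r, numeric(1))
    exact <- TRUE
    b <- n_all
  } else {
    rs <- with_seed_if(seed, {
      vapply(seq_len(permutations), function(i) perm_r(sample.int(n)),
             numeric(1))
    })
    exact <- FALSE
    b <- permutations
  }
  p <- (1 + sum(rs >= r_obs)) / (1 + b)
  structure(list(r = r_obs, p_value = p, permutations = b, exact = exact),
            class = "mantel_test")
}

# all permutations of 1..n except the identity
perm_enumerate <- function(n) {
  perms <- list(seq_len(1))
  for (k in 2:n) {
    perms <- unlist(lapply(perms, function(p) {
      lapply(seq_len(k), function(pos) append(p, k, after = pos - 1))
    }), recursive = FALSE)
  }
  Filter(function(p) !all(p == seq_len(n)), perms)
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, p = %.4g (%s%d permutations)\n",
              x$r, x$p_value, if (x$exact) "exact, " else "", x$permutations))
  invisible(x)
}

#' Mantel table of community structure against traits
#'
#' One Mantel test per trait: community (Jaccard) distance against the
#' standardised-Euclidean distance of each environmental variable and the
#' CH4 flux -- the layout of a community-by-variable Mantel summary table.
#'
#' @param dm Community `dist` (e.g. [jaccard_distance()]).
#' @param metadata Metadata tibble.
#' @param traits Trait columns; defaults to the environmental traits plus
#'   `ch4_flux`.
#' @param permutations,seed Passed to [mantel_test()].
#' @return Tibble with `trait`, `r`, `p_value`, `stars`.
#' @export
mantel_table <- function(dm, metadata, traits = c(env_traits(), "ch4_flux"),
                         permutations = 999, seed = 1) {
  ids <- rownames(as.matrix(dm))
  md <- metadata[match(ids, metadata$sample_id), ]
  purrr::map_dfr(traits, function(tr) {
    mt <- mantel_test(dm, trait_distance(md, tr),
                      permutations = permutations, seed = seed)
    tibble::tibble(trait = tr, r = mt$r, p_value = mt$p_value,
                   stars = significance_stars(mt$p_value))
  })
}

#' Principal component analysis of community structure
#'
#' PCA of centred relative abundances (samples as observations). Duplicated
#' samples receive identical scores.
#'
#' @param table A count table tibble with >= 3 samples.
#' @param n_axes Number of axes to return scores for.
#' @return An object of class `pca_ordination`: list with `scores` (tibble
#'   `sample_id`, `PC1`, `PC2`, ...), `explained_variance` (fractions over
#'   all axes, summing to 1).
#' @export
pca_ordination <- function(table, n_axes = 2) {
  validate_count_table(table)
  x <- t(rel_abundance(otu_matrix(table)))  # samples x OTUs
  if (nrow(x) < 3) stop("PCA needs >= 3 samples", call. = FALSE)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_axes, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)), scores)
  structure(list(scores = scores, explained_variance = ev),
            class = "pca_ordination")
}

#' @export
print.pca_ordination <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples; PC1",
      sprintf("%.1f%%,", 100 * x$explained_variance[1]), "PC2",
      sprintf("%.1f%%\n", 100 * x$explained_variance[2]))
  invisible(x)
}

#' Multiple dissimilarity tests among groups
#'
#' MRPP (delta and chance-corrected A), ANOSIM (R) and PERMANOVA (pseudo-F),
#' each with a permutation p-value, on one distance matrix and a group
#' factor. Singleton groups are excluded with a warning.
#'
#' @param dm A `dist` object.
#' @param groups Group labels aligned with the distance matrix.
#' @param permutations Number of permutations per test.
#' @param seed Integer seed (permutation tests are reproducible under it).
#' @return Tibble with `test`, `statistic_name`, `statistic`, `p_value`.
#' @export
dissimilarity_tests <- function(dm, groups, permutations = 999, seed = 1) {
  m <- as.matrix(dm)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  sizes <- table(groups)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warning("excluding singleton group(s): ", paste(drop, collapse = ", "),
            call. = FALSE)
    keep <- !groups %in% drop
    m <- m[keep, keep]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) {
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  }
  d <- stats::as.dist(m)
  g <- factor(groups)
  with_seed_if(seed, {
    mr <- vegan::mrpp(d, g, permutations = permutations)
    an <- vegan::anosim(d, g, permutations = permutations)
    ad <- vegan::adonis2(d ~ g, permutations = permutations)
  })
  tibble::tibble(
    test = c("MRPP", "MRPP", "ANOSIM", "PERMANOVA"),
    statistic_name = c("delta", "A", "R", "pseudo-F"),
    statistic = c(mr$delta, mr$A, unname(an$statistic), ad$F[1]),
    p_value = c(mr$Pvalue, NA_real_, an$signif, ad$`Pr(>F)`[1])
  )
}

#' One-way ANOVA of a variable across groups
#'
#' Classical one-way ANOVA F and p. Degenerate input (all groups identical,
#' zero variance everywhere) reports F = 0.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @return One-row tibble with `f_statistic`, `p_value`, `df_between`,
#'   `df_within`.
#' @export
group_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  fit <- aov(values ~ g)
  tab <- anova(fit)
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (is.na(f) && var(values) == 0) {
    f <- 0
    p <- 1
  }
  tibble::tibble(f_statistic = f, p_value = p,
                 df_between = tab$Df[1], df_within = tab$Df[2])
}

#' Ordinary least-squares regression of flux against a covariate
#'
#' Simple linear regression reporting R-squared, the slope, and the slope's
#' two-sided t-test p -- the form used to relate CH4 flux to functional gene
#' copy numbers.
#'
#' @param x Predictor (e.g. gene copies).
#' @param y Response (e.g. CH4 flux).
#' @return One-row tibble with `r_squared`, `slope`, `intercept`, `p_value`,
#'   `n`.
#' @export
flux_regression <- function(x, y) {
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) stop("need >= 3 complete observations", call. = FALSE)
  fit <- lm(y[ok] ~ x[ok])
  sm <- summary(fit)
  tibble::tibble(r_squared = sm$r.squared,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 p_value = sm$coefficients[2, 4],
                 n = sum(ok))
}
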