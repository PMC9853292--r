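# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain brute-force code, separate from the implementation paths they
# check.

# small deterministic count table: n_otu x n_sample, seeded Poisson counts
toy_counts <- function(n_otu = 6, n_sample = 8, seed = 11, kingdom = "prokaryote") {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_otu * n_sample, lambda = 40), n_otu, n_sample)
  })
  rownames(m) <- sprintf("OTU%02d", seq_len(n_otu))
  colnames(m) <- sprintf("S%02d", seq_len(n_sample))
  count_table(m, taxonomy = sprintf("Bacteria;P;C;O%02d;F;G", seq_len(n_otu)),
              kingdom = kingdom)
}

# brute-force Spearman: Pearson correlation of average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force Zi/Pi from an adjacency matrix and a module vector
oracle_zi_pi <- function(adj, mod) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  zi <- numeric(n); pi <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(mod == mod[i])
    k_within <- vapply(same, function(j) sum(adj[j, mod == mod[j]]),
                       numeric(1))
    s <- sd(k_within)
    ki_within <- sum(adj[i, mod == mod[i]])
    zi[i] <- if (is.na(s) || s == 0) 0 else (ki_within - mean(k_within)) / s
    if (deg[i] == 0) {
      pi[i] <- 0
    } else {
      k_t <- vapply(unique(mod), function(t) sum(adj[i, mod == t]),
                    numeric(1))
      pi[i] <- 1 - sum((k_t / deg[i])^2)
    }
  }
  list(zi = zi, pi = pi)
}

oracle_role <- function(zi, pi, zc = 0.25, pc = 0.62) {
  if (zi > zc && pi > pc) "network hub"
  else if (zi > zc) "module hub"
  else if (pi > pc) "connector"
  else "peripheral"
}

# modularity of a partition, straight from Q = sum_c (e_c/m - (d_c/2m)^2)
oracle_modularity <- function(g, mem) {
  m <- igraph::ecount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  q <- 0
  for (cc in unique(mem)) {
    nodes <- which(mem == cc)
    e_c <- sum(el[, 1] %in% nodes & el[, 2] %in% nodes)
    d_c <- sum(deg[nodes])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# all set partitions of 1..n (restricted growth strings), for exhaustive
# modularity search on tiny graphs
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) grow(c(prefix, v), max(maxv, v))
  }
  grow(1L, 1L)
  out
}

# exhaustive Mantel: upper-tail p over all n! label permutations of one
# matrix (identity included in the reference set)
oracle_mantel_exhaustive <- function(mx, my) {
  n <- nrow(mx)
  lt <- lower.tri(mx)
  r_obs <- cor(mx[lt], my[lt])
  perms <- gtools_permutations(n)
  rs <- apply(perms, 1, function(ord) {
    mp <- my[ord, ord]
    cor(mx[lt], mp[lt])
  })
  list(r = r_obs, p = sum(rs >= r_obs) / nrow(perms))
}

# all permutations of 1..n as a matrix (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# latent-block multi-kingdom correlation matrix fixture for RMT tests:
# Spearman matrix of data drawn from k blocks of `block` variables at
# within-block correlation rho
block_spearman <- function(n_samples = 200, block = 20, k = 3, rho = 0.9,
                           seed = 1) {
  withr::with_seed(seed, {
    p <- block * k
    sigma <- diag(p)
    for (b in seq_len(k)) {
      idx <- ((b - 1) * block + 1):(b * block)
      sigma[idx, idx] <- rho
      diag(sigma)[idx] <- 1
    }
    x <- MASS::mvrnorm(n_samples, mu = rep(0, p), Sigma = sigma)
    structure(list(ids = sprintf("V%03d", seq_len(p)),
                   rho = cor(x, method = "spearman"),
                   n_samples = n_samples),
              class = "men_corr")
  })
}

block_membership <- function(block = 20, k = 3) rep(seq_len(k), each = block)

# independent relative-abundance computation (column closure)
rel_abund_oracle <- function(tbl) {
  m <- otu_matrix(tbl)
  sweep(m, 2, colSums(m), "/")
}

# igraph helpers
toy_graph <- function(edges, n = NULL) {
  g <- if (is.null(n)) igraph::make_graph(edges, directed = FALSE)
       else igraph::make_graph(edges, directed = FALSE, n = n)
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}

# count table with a log-normal abundance spread, so presence/absence varies
# across samples (Jaccard-friendly)
sparse_counts <- function(n_otu = 40, n_sample = 15, seed = 1) {
  withr::with_seed(seed, {
    lam <- exp(rnorm(n_otu, 1, 1.2))
    m <- matrix(rpois(n_otu * n_sample, rep(lam, n_sample)), n_otu, n_sample)
  })
  rownames(m) <- sprintf("OTU%02d", seq_len(n_otu))
  colnames(m) <- sprintf("S%02d", seq_len(n_sample))
  count_table(m)
}
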