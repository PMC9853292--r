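# Global network properties, vulnerability, robustness.

#' Global efficiency of a graph
#'
#' `E = (1 / (N (N - 1))) * sum_{i != j} 1 / d_ij` over unweighted shortest
#' paths, with `1 / Inf = 0` for disconnected pairs. A complete graph has
#' efficiency exactly 1.
#'
#' @param net An igraph object.
#' @return A number in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) return(0)
  d <- igraph::distances(net, weights = NA)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Global topological properties of an association network
#'
#' Node/edge counts, average degree, average local clustering coefficient
#' (nodes of degree < 2 contribute 0), average path distance over connected
#' pairs (GD), density, fast-greedy modularity Q, vulnerability, and the
#' connectance (density) of the largest connected component.
#'
#' @param net An igraph association network.
#' @return One-row tibble.
#' @export
global_properties <- function(net) {
  stopifnot(igraph::vcount(net) > 0)
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  cc_local <- igraph::transitivity(net, type = "local", isolates = "zero")
  cc_local[is.na(cc_local)] <- 0
  gd <- if (e > 0) igraph::mean_distance(net, weights = NA, directed = FALSE,
                                         unconnected = TRUE) else NA_real_
  part <- detect_modules(net)
  comp <- igraph::components(net)
  big <- igraph::induced_subgraph(net, which(comp$membership ==
                                               which.max(comp$csize)))
  tibble::tibble(
    n_nodes = n,
    n_edges = e,
    avg_degree = 2 * e / n,
    avg_clustering = mean(cc_local),
    avg_path_distance = gd,
    density = igraph::edge_density(net),
    modularity = part$modularity,
    vulnerability = if (n >= 3) vulnerability(net) else NA_real_,
    connectance_largest_component = igraph::edge_density(big)
  )
}

#' Network vulnerability
#'
#' `V = max_i (E - E_i) / E`, where `E` is the global efficiency of the graph
#' and `E_i` the efficiency after removing node `i` (recomputed on the
#' remaining `N - 1` nodes). The maximum is over all single-node removals, so
#' V measures the worst-case relative efficiency loss: 0 for a complete
#' graph, 1 when removing a hub disconnects everything.
#'
#' @param net An igraph object with >= 3 nodes.
#' @return A single number.
#' @export
vulnerability <- function(net) {
  n <- igraph::vcount(net)
  if (n < 3) stop("vulnerability needs >= 3 nodes", call. = FALSE)
  e0 <- global_efficiency(net)
  if (e0 == 0) stop("vulnerability undefined for edgeless graph", call. = FALSE)
  ei <- vapply(seq_len(n), function(i) {
    global_efficiency(igraph::delete_vertices(net, i))
  }, numeric(1))
  max((e0 - ei) / e0)
}

#' Network robustness under node removal
#'
#' Per replicate, removes `floor(f * N)` nodes -- uniformly at random, or
#' module/network hubs first (`target_hubs`) with random fill -- then
#' iteratively removes survivors left with no links (secondary extinction).
#' Robustness is the proportion of the initial nodes remaining.
#'
#' @param net An igraph association network.
#' @param removal_fraction Fraction `f` of nodes removed initially.
#' @param strategy `"random"` or `"target_hubs"`.
#' @param replicates Number of removal replicates.
#' @param seed Integer seed.
#' @param roles Optional node role tibble from [zi_pi()]; computed internally
#'   (fast-greedy modules) when `strategy = "target_hubs"` and `roles` is
#'   `NULL`. If no hubs exist the strategy falls back to random with a
#'   warning.
#' @return One-row tibble with `strategy`, `removal_fraction`, `replicates`,
#'   `mean`, `sd`.
#' @export
robustness <- function(net, removal_fraction = 0.5,
                       strategy = c("random", "target_hubs"),
                       replicates = 100, seed = 1, roles = NULL) {
  strategy <- match.arg(strategy)
  n <- igraph::vcount(net)
  n_remove <- floor(removal_fraction * n)
  hubs <- character(0)
  if (strategy == "target_hubs") {
    if (is.null(roles)) roles <- zi_pi(net, detect_modules(net))
    hubs <- roles$node[roles$role %in% c("module hub", "network hub")]
    if (length(hubs) == 0) {
      warning("no module/network hubs; falling back to random removal",
              call. = FALSE)
      strategy <- "random"
    }
  }
  names_all <- igraph::V(net)$name %||% as.character(seq_len(n))
  prop <- with_seed_if(seed, {
    vapply(seq_len(replicates), function(r) {
      if (n_remove == 0) return(1)
      if (strategy == "target_hubs") {
        first <- sample(hubs, min(length(hubs), n_remove))
        rest <- setdiff(names_all, first)
        extra <- n_remove - length(first)
        removed <- c(first, if (extra > 0) sample(rest, extra))
      } else {
        removed <- sample(names_all, n_remove)
      }
      g <- igraph::delete_vertices(net, removed)
      repeat {
        iso <- which(igraph::degree(g) == 0)
        if (length(iso) == 0) break
        g <- igraph::delete_vertices(g, iso)
      }
      igraph::vcount(g) / n
    }, numeric(1))
  })
  tibble::tibble(strategy = strategy, removal_fraction = removal_fraction,
                 replicates = replicates, mean = mean(prop), sd = sd(prop))
}
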