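# Module detection, Zi/Pi node roles, module eigengenes, eigengene-trait
# correlation, guild-centred subnetworks.

#' Detect network modules by fast-greedy modularity optimisation
#'
#' Greedy agglomerative merging maximising Newman-Girvan modularity
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` on the unweighted, unsigned graph
#' (community structure ignores edge signs). Modules are relabelled by size,
#' largest first. An edgeless network yields one singleton module per node
#' with Q = 0.
#'
#' @param net An undirected igraph association network.
#' @return An object of class `module_partition`: list with `membership`
#'   (tibble `node`, `module`), `modularity`, `method`.
#' @export
detect_modules <- function(net) {
  nodes <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  if (igraph::ecount(net) == 0) {
    return(structure(list(
      membership = tibble::tibble(node = nodes,
                                  module = seq_along(nodes)),
      modularity = 0,
      method = "fast_greedy"
    ), class = "module_partition"))
  }
  g <- net
  if ("weight" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "weight")
  }
  cl <- igraph::cluster_fast_greedy(g)
  # cut the merge dendrogram at the latest step within numerical tolerance
  # of the maximum modularity (ties resolved towards fewer modules, so a
  # clique is one module despite floating-point jitter in the merge path)
  mods <- cl$modularity
  i_star <- max(which(mods >= max(mods) - 1e-10))
  k <- igraph::vcount(g) - i_star + 1
  mem <- if (k <= 1) rep(1L, igraph::vcount(g)) else igraph::cut_at(cl, no = k)
  # relabel by decreasing module size (ties by first appearance)
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  mem_new <- unname(relabel[as.character(mem)])
  q <- igraph::modularity(g, mem_new)
  structure(list(
    membership = tibble::tibble(node = nodes, module = mem_new),
    modularity = q,
    method = "fast_greedy"
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module partition:", max(x$membership$module), "modules,",
      nrow(x$membership), "nodes, Q =", signif(x$modularity, 4), "\n")
  invisible(x)
}

#' Within-module degree (Zi) and among-module connectivity (Pi)
#'
#' `Zi = (k_is - mean(k_s)) / sd(k_s)` standardises node i's within-module
#' degree against its own module s (Zi = 0 when the sd is 0);
#' `Pi = 1 - sum_t (k_it / k_i)^2` measures how evenly the node's links
#' spread over modules (0 for isolated nodes). Roles follow the usual
#' keystone cutoffs: module hub (Zi > 0.25, Pi <= 0.62), connector
#' (Zi <= 0.25, Pi > 0.62), network hub (Zi > 0.25, Pi > 0.62), else
#' peripheral.
#'
#' @param net An igraph association network.
#' @param partition A `module_partition` covering the network's nodes.
#' @param zi_cutoff,pi_cutoff Role cutoffs.
#' @return Tibble with `node`, `module`, `degree`, `within_degree`, `zi`,
#'   `pi`, `role`.
#' @export
zi_pi <- function(net, partition, zi_cutoff = 0.25, pi_cutoff = 0.62) {
  mem <- partition$membership
  nodes <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  if (!all(nodes %in% mem$node)) {
    stop("partition does not cover all network nodes", call. = FALSE)
  }
  mod <- mem$module[match(nodes, mem$node)]
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE) > 0
  deg <- unname(rowSums(adj))
  # k_it: links of node i into module t
  mods <- sort(unique(mod))
  k_to <- vapply(mods, function(t) rowSums(adj[, mod == t, drop = FALSE]),
                 numeric(length(nodes)))
  k_to <- matrix(k_to, nrow = length(nodes))
  k_within <- k_to[cbind(seq_along(nodes), match(mod, mods))]
  zi <- vapply(seq_along(nodes), function(i) {
    ks <- k_within[mod == mod[i]]
    s <- sd(ks)
    if (is.na(s) || s == 0) 0 else (k_within[i] - mean(ks)) / s
  }, numeric(1))
  pi <- unname(ifelse(deg == 0, 0, 1 - rowSums((k_to / pmax(deg, 1))^2)))
  role <- dplyr::case_when(
    zi > zi_cutoff & pi > pi_cutoff ~ "network hub",
    zi > zi_cutoff ~ "module hub",
    pi > pi_cutoff ~ "connector",
    TRUE ~ "peripheral"
  )
  tibble::tibble(node = nodes, module = mod, degree = as.numeric(deg),
                 within_degree = as.numeric(k_within), zi = zi, pi = pi,
                 role = role)
}

#' Attach module and role attributes to a network
#'
#' Convenience for export: copies module id, Zi, Pi and role onto the graph's
#' vertices so [write_network()] emits them.
#'
#' @param net An igraph association network.
#' @param roles Tibble from [zi_pi()].
#' @return The network with `module`, `zi`, `pi`, `role` vertex attributes.
#' @export
set_node_roles <- function(net, roles) {
  idx <- match(igraph::V(net)$name, roles$node)
  igraph::V(net)$module <- roles$module[idx]
  igraph::V(net)$zi <- roles$zi[idx]
  igraph::V(net)$pi <- roles$pi[idx]
  igraph::V(net)$role <- roles$role[idx]
  net
}

#' Module eigengene by singular value decomposition
#'
#' Standardises each member OTU's relative-abundance profile to mean 0, sd 1
#' across samples, and takes the leading right-singular vector (sample space)
#' of the module matrix as the eigengene -- the first principal component of
#' the standardised module profiles. The sign is flipped if the eigengene
#' correlates negatively with the module's mean standardised profile.
#' Explained variance is `sigma_1^2 / sum(sigma^2)`.
#'
#' @param table A count table tibble.
#' @param partition A `module_partition`, or a data frame with columns
#'   `node`/`otu_id` and `module`.
#' @param module Module id.
#' @return List with `eigengene` (named unit-norm vector over samples),
#'   `explained_variance`, `n_otus`.
#' @export
module_eigengene <- function(table, partition, module) {
  mem <- if (inherits(partition, "module_partition")) partition$membership
         else partition
  names(mem)[names(mem) == "otu_id"] <- "node"
  members <- mem$node[mem$module == module]
  members <- intersect(members, table$otu_id)
  if (length(members) < 2) {
    stop("module ", module, " has fewer than 2 OTUs in the table",
         call. = FALSE)
  }
  m <- rel_abundance(otu_matrix(table))[members, , drop = FALSE]
  keep <- apply(m, 1, sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant OTU profile(s) excluded from module ",
            module, call. = FALSE)
    m <- m[keep, , drop = FALSE]
    if (nrow(m) < 2) stop("module ", module, " collapsed to < 2 usable OTUs",
                          call. = FALSE)
  }
  x <- t(scale(t(m)))  # standardise each OTU profile
  sv <- svd(x)
  e <- sv$v[, 1]
  mp <- colMeans(x)
  s <- if (sd(mp) > 0) cor(e, mp) else 0
  if (is.na(s)) s <- 0
  if (s < 0) {
    e <- -e
  } else if (s == 0 && e[which.max(abs(e))] < 0) {
    # perfectly balanced module (mean profile is flat): fix the sign by the
    # largest-magnitude entry instead
    e <- -e
  }
  names(e) <- colnames(m)
  list(eigengene = e,
       explained_variance = sv$d[1]^2 / sum(sv$d^2),
       n_otus = nrow(m))
}

#' Eigengenes for every module of a partition
#'
#' @param table A count table tibble.
#' @param partition A `module_partition`.
#' @param min_otus Smallest module size carried to eigengene computation.
#' @return An object of class `eigengene_set`: list with `eigengenes`
#'   (sample x module matrix), `variance` (tibble `module`,
#'   `explained_variance`, `n_otus`).
#' @export
module_eigengenes <- function(table, partition, min_otus = 2) {
  mem <- partition$membership
  mem <- mem[mem$node %in% table$otu_id, ]
  keep <- as.integer(names(which(table(mem$module) >= min_otus)))
  if (length(keep) == 0) stop("no module large enough for an eigengene",
                              call. = FALSE)
  res <- lapply(sort(keep), function(m) module_eigengene(table, partition, m))
  eg <- do.call(cbind, lapply(res, `[[`, "eigengene"))
  colnames(eg) <- sort(keep)
  structure(list(
    eigengenes = eg,
    variance = tibble::tibble(
      module = sort(keep),
      explained_variance = vapply(res, `[[`, numeric(1), "explained_variance"),
      n_otus = vapply(res, `[[`, numeric(1), "n_otus"))
  ), class = "eigengene_set")
}

#' @export
print.eigengene_set <- function(x, ...) {
  cat("eigengene set:", ncol(x$eigengenes), "modules x",
      nrow(x$eigengenes), "samples\n")
  invisible(x)
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Pearson correlation between module eigengenes and sample traits
#'
#' For every (module, trait) pair: Pearson r and its two-sided t-test p,
#' significance stars at 0.05/0.01/0.001, and a Benjamini-Hochberg adjusted
#' p column. Constant traits give NA correlations.
#'
#' @param eigengenes An `eigengene_set`.
#' @param metadata Metadata tibble with `sample_id` and the trait columns.
#' @param traits Trait column names; defaults to the environmental traits
#'   plus `ch4_flux`.
#' @return Tibble with `module`, `trait`, `r`, `p_value`, `p_adjusted`,
#'   `stars`.
#' @export
eigengene_trait_correlation <- function(eigengenes, metadata,
                                        traits = c(env_traits(), "ch4_flux")) {
  eg <- eigengenes$eigengenes
  idx <- match(rownames(eg), metadata$sample_id)
  if (anyNA(idx)) {
    stop("eigengene samples missing from metadata: ",
         paste(rownames(eg)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  md <- metadata[idx, ]
  out <- tidyr::expand_grid(module = colnames(eg), trait = traits)
  res <- purrr::pmap_dfr(out, function(module, trait) {
    x <- eg[, module]
    y <- md[[trait]]
    if (is.null(y)) stop("trait not in metadata: ", trait, call. = FALSE)
    if (sd(y, na.rm = TRUE) == 0 || all(is.na(y))) {
      return(tibble::tibble(module = as.integer(module), trait = trait,
                            r = NA_real_, p_value = NA_real_))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(module = as.integer(module), trait = trait,
                   r = unname(ct$estimate), p_value = ct$p.value)
  })
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res$stars <- significance_stars(res$p_value)
  res
}

#' Guild-centred subnetwork
#'
#' Induced subgraph on the nodes of a guild plus their first neighbours,
#' retaining edge signs -- e.g. the methanogen subnetwork with everything the
#' methanogens touch.
#'
#' @param net An igraph association network with a `guild` vertex attribute.
#' @param guild Guild label (`"methanogen"`, `"methanotroph"`).
#' @return An igraph subnetwork (possibly empty, with a warning, when the
#'   guild is absent).
#' @export
guild_subnetwork <- function(net, guild) {
  seeds <- which(igraph::V(net)$guild == guild)
  if (length(seeds) == 0) {
    warning("no nodes with guild '", guild, "'", call. = FALSE)
    return(igraph::induced_subgraph(net, integer(0)))
  }
  nb <- unlist(igraph::adjacent_vertices(net, seeds))
  igraph::induced_subgraph(net, union(seeds, nb))
}
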