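# Spearman correlation matrices and network assembly.

#' Pairwise Spearman correlation matrix of an OTU table
#'
#' Computes all pairwise Spearman rank correlations between OTU relative-
#' abundance profiles (average ranks for ties; ranks are invariant to the
#' per-sample compositional closure). OTUs with zero variance across samples
#' get undefined correlations, which are set to 0 with a warning.
#'
#' @param table A count table tibble with >= 4 samples (prevalence-filtered
#'   upstream).
#' @return An object of class `men_corr`: list with `ids`, `rho` (symmetric,
#'   unit diagonal), `n_samples`.
#' @export
spearman_matrix <- function(table) {
  validate_count_table(table)
  m <- rel_abundance(otu_matrix(table))
  if (ncol(m) < 4) stop("need >= 4 samples for correlation", call. = FALSE)
  zero_var <- apply(m, 1, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(cor(t(m), method = "spearman"))
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance OTU(s); their correlations set to 0",
            call. = FALSE)
    rho[zero_var, ] <- 0
    rho[, zero_var] <- 0
  }
  diag(rho) <- 1
  structure(list(ids = table$otu_id, rho = rho, n_samples = ncol(m)),
            class = "men_corr")
}

#' @export
print.men_corr <- function(x, ...) {
  cat("Spearman correlation matrix:", length(x$ids), "OTUs,",
      x$n_samples, "samples\n")
  invisible(x)
}

#' Build a thresholded association network
#'
#' Draws an undirected edge between every OTU pair with `|rho| >= threshold`,
#' keeping the signed correlation as the edge weight and recording the sign
#' (`"positive"`/`"negative"`). Isolated nodes are dropped; node attributes
#' (kingdom, guild, taxonomy) are copied from the count table.
#'
#' @param corr A `men_corr` object from [spearman_matrix()].
#' @param threshold Correlation cutoff in (0, 1).
#' @param table Optional count table supplying node attributes.
#' @return An igraph association network with graph attribute `threshold`.
#' @export
build_network <- function(corr, threshold, table = NULL) {
  stopifnot(inherits(corr, "men_corr"), threshold > 0, threshold <= 1)
  rho <- corr$rho
  adj <- abs(rho) >= threshold
  diag(adj) <- FALSE
  if (!any(adj)) {
    stop("no edges at threshold ", threshold,
         " (max off-diagonal |rho| = ",
         signif(max(abs(rho[upper.tri(rho)])), 3), ")", call. = FALSE)
  }
  w <- rho
  w[!adj] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- corr$ids
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  igraph::E(g)$sign <- ifelse(igraph::E(g)$weight >= 0, "positive", "negative")
  if (!is.null(table)) {
    idx <- match(igraph::V(g)$name, table$otu_id)
    igraph::V(g)$kingdom <- table$kingdom[idx]
    igraph::V(g)$guild <- table$guild[idx]
    igraph::V(g)$taxonomy <- table$taxonomy[idx]
    igraph::V(g)$category <- ifelse(table$guild[idx] %in%
                                      c("methanogen", "methanotroph"),
                                    table$guild[idx], table$kingdom[idx])
  }
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Build the interdomain (multi-kingdom) association network
#'
#' Concatenates kingdom tables on their shared samples, separates the
#' methane-cycle guilds out of the prokaryote pool (a methanogen or
#' methanotroph OTU is its own node category, never also "prokaryote"), then
#' computes the pooled Spearman matrix and thresholds it.
#'
#' @param tables A list of count table tibbles (or a single combined one)
#'   with guilds annotated.
#' @param threshold Correlation cutoff; 0.85 is the RMT-derived interdomain
#'   default.
#' @return An igraph association network whose `category` vertex attribute
#'   takes values in prokaryote/fungus/cercozoa/methanogen/methanotroph.
#' @export
build_interdomain_network <- function(tables, threshold = 0.85) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  shared <- Reduce(intersect, lapply(tables, sample_ids))
  if (length(shared) < 4) {
    stop("fewer than 4 shared samples across kingdom tables", call. = FALSE)
  }
  if (any(vapply(tables, function(t) length(sample_ids(t)), 1L) >
          length(shared))) {
    warning("sample sets differ across kingdom tables; using their ",
            "intersection (", length(shared), " samples)", call. = FALSE)
  }
  combined <- dplyr::bind_rows(lapply(tables, function(t) {
    t[, c(otu_meta_cols(), shared)]
  }))
  validate_count_table(combined)
  corr <- spearman_matrix(combined)
  build_network(corr, threshold, combined)
}
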