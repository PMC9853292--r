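# Table and network I/O. All tables are UTF-8 TSV with "." decimal marks,
# the lingua franca of amplicon pipelines.

#' Read an OTU count table from TSV
#'
#' Expected layout: first column `otu_id`, one column per sample, then a
#' final `taxonomy` column. Optional `kingdom` and `guild` columns may follow
#' `taxonomy` (they are written by [write_count_table()] so that write/read
#' round-trips are identity).
#'
#' @param path Path to a tab-separated file.
#' @param kingdom Kingdom label assigned to every OTU when the file carries
#'   no `kingdom` column.
#' @return A count table tibble.
#' @export
read_count_table <- function(path, kingdom = "prokaryote") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, name_repair = "minimal")
  if (!"otu_id" %in% names(raw)) names(raw)[1] <- "otu_id"
  if (!"taxonomy" %in% names(raw)) {
    stop("count table file has no 'taxonomy' column: ", path, call. = FALSE)
  }
  if (anyDuplicated(names(raw))) {
    stop("duplicated sample column in ", path, ": ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$otu_id)) {
    stop("duplicated otu_id in ", path, call. = FALSE)
  }
  smp <- setdiff(names(raw), c("otu_id", "taxonomy", "kingdom", "guild"))
  cnt <- suppressWarnings(
    vapply(raw[smp], function(x) as.numeric(x), numeric(nrow(raw)))
  )
  cnt <- matrix(cnt, nrow = nrow(raw), dimnames = list(raw$otu_id, smp))
  if (anyNA(cnt)) {
    bad <- which(is.na(cnt), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count in %s at OTU '%s', sample '%s'",
                 path, raw$otu_id[bad[1]], smp[bad[2]]), call. = FALSE)
  }
  if (any(cnt < 0)) stop("negative counts in ", path, call. = FALSE)
  count_table(cnt,
              taxonomy = raw$taxonomy,
              kingdom = raw$kingdom %||% kingdom,
              guild = raw$guild %||% "none")
}

#' Write a count table to TSV
#'
#' Column order: `otu_id`, sample columns, `taxonomy`, `kingdom`, `guild`.
#'
#' @param table A count table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  validate_count_table(table)
  smp <- sample_ids(table)
  out <- table[, c("otu_id", smp, "taxonomy", "kingdom", "guild")]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' The file is keyed by `sample_id`. All columns other than `sample_id`,
#' `inundation_depth_cm` and `group` are parsed as numeric; a non-numeric
#' cell raises an error naming the sample and column. When `counts` is
#' supplied, sample ids present in the metadata but absent from the count
#' table (or vice versa) are reported as a warning.
#'
#' @param path Path to a tab-separated file.
#' @param counts Optional count table used to cross-check sample ids.
#' @return A metadata tibble.
#' @export
read_sample_metadata <- function(path, counts = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"sample_id" %in% names(raw)) names(raw)[1] <- "sample_id"
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicated sample_id in ", path, call. = FALSE)
  }
  char_cols <- intersect(c("sample_id", "inundation_depth_cm", "group"),
                         names(raw))
  num_cols <- setdiff(names(raw), char_cols)
  for (cl in num_cols) {
    parsed <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(parsed) & !is.na(raw[[cl]]) & raw[[cl]] != "NA")
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in %s: sample '%s', column '%s'",
                   raw[[cl]][bad[1]], path, raw$sample_id[bad[1]], cl),
           call. = FALSE)
    }
    raw[[cl]] <- parsed
  }
  if (!is.null(counts)) {
    extra <- setdiff(raw$sample_id, sample_ids(counts))
    missing <- setdiff(sample_ids(counts), raw$sample_id)
    if (length(extra) + length(missing) > 0) {
      warning("sample ids not shared between metadata and count table: ",
              paste(c(extra, missing), collapse = ", "), call. = FALSE)
    }
  }
  tibble::as_tibble(raw)
}

#' Write a sample metadata table to TSV
#'
#' @param metadata A metadata tibble with a `sample_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  stopifnot("sample_id" %in% names(metadata))
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Read a guild rule file
#'
#' A guild rule set maps taxonomy substrings to functional guilds; the first
#' matching rule wins. The file is a two-column TSV (`pattern`, `guild`).
#'
#' @param path Path to a tab-separated file.
#' @return Tibble with columns `pattern` and `guild`.
#' @export
read_guild_rules <- function(path) {
  rules <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (!all(c("pattern", "guild") %in% names(rules))) {
    stop("guild rule file needs columns 'pattern' and 'guild': ", path,
         call. = FALSE)
  }
  bad <- setdiff(unique(rules$guild), c("methanogen", "methanotroph", "none"))
  if (length(bad) > 0) {
    stop("unknown guild labels in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(rules[, c("pattern", "guild")])
}

#' Node table of an association network
#'
#' @param net An igraph association network (see [build_network()]).
#' @return Tibble with one row per node and all vertex attributes.
#' @export
tidy_nodes <- function(net) {
  at <- igraph::vertex_attr(net)
  tibble::as_tibble(at[lengths(at) == igraph::vcount(net)])
}

#' Edge table of an association network
#'
#' @param net An igraph association network.
#' @return Tibble with columns `source`, `target`, edge attributes.
#' @export
tidy_edges <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  at <- igraph::edge_attr(net)
  dplyr::bind_cols(
    tibble::tibble(source = el[, 1], target = el[, 2]),
    tibble::as_tibble(at[lengths(at) == igraph::ecount(net)])
  )
}

#' Export an association network for Cytoscape and GraphML consumers
#'
#' Writes a Cytoscape-style edge list TSV (`source`, `sign`, `weight`,
#' `target`), a node attribute TSV (`id`, `kingdom`, `guild`, `taxonomy`,
#' `module`, `zi`, `pi`, `role`; absent attributes are written as NA), and a
#' GraphML file carrying the same attributes.
#'
#' @param net An igraph association network.
#' @param edge_path,attr_path,graphml_path Output paths; any may be `NULL`
#'   to skip that file.
#' @return Named list of written paths, invisibly.
#' @export
write_network <- function(net, edge_path = NULL, attr_path = NULL,
                          graphml_path = NULL) {
  if (!is.null(edge_path)) {
    ed <- tidy_edges(net)
    readr::write_tsv(ed[, c("source", "sign", "weight", "target")],
                     edge_path, progress = FALSE)
  }
  if (!is.null(attr_path)) {
    nd <- tidy_nodes(net)
    nd <- dplyr::rename(nd, id = "name")
    for (cl in c("kingdom", "guild", "taxonomy", "module", "zi", "pi", "role")) {
      if (!cl %in% names(nd)) nd[[cl]] <- NA
    }
    readr::write_tsv(nd[, c("id", "kingdom", "guild", "taxonomy",
                            "module", "zi", "pi", "role")],
                     attr_path, progress = FALSE)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(net, graphml_path, format = "graphml")
  }
  invisible(list(edges = edge_path, attributes = attr_path,
                 graphml = graphml_path))
}

#' Re-import a GraphML network written by [write_network()]
#'
#' @param graphml_path Path to a GraphML file.
#' @return An igraph object.
#' @export
read_network <- function(graphml_path) {
  igraph::read_graph(graphml_path, format = "graphml")
}
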