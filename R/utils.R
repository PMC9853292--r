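# Canonical column layout of a count table: per-OTU metadata columns first,
# then one numeric column per sample.
otu_meta_cols <- function() c("otu_id", "taxonomy", "kingdom", "guild")

#' Environmental trait columns of a sample metadata table
#'
#' Names of the per-sample sediment variables carried by the metadata tables
#' this package reads, writes and simulates: total nitrogen and phosphorus
#' (mg/kg), ammonium and nitrate (mg/kg), organic matter (%), pH, salinity
#' (ppt) and dissolved oxygen (vol%).
#'
#' @return Character vector of column names.
#' @export
env_traits <- function() {
  c("TN", "TP", "ammonium", "nitrate", "organic_matter", "pH",
    "salinity", "oxygen")
}

#' Sample columns of a count table
#'
#' @param table A count table tibble (see [count_table()]).
#' @return Character vector of sample identifiers.
#' @export
sample_ids <- function(table) {
  setdiff(names(table), otu_meta_cols())
}

#' Extract the OTU x sample count matrix from a count table
#'
#' @param table A count table tibble.
#' @return Numeric matrix with OTU ids as rownames, sample ids as colnames.
#' @export
otu_matrix <- function(table) {
  smp <- sample_ids(table)
  m <- as.matrix(table[, smp, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$otu_id
  m
}

#' Assemble a count table from its parts
#'
#' A count table is a tibble with one row per OTU: identifier, taxonomy
#' string (semicolon-delimited ranks), kingdom label, guild label, then one
#' integer count column per sample.
#'
#' @param counts Non-negative integer matrix, OTUs in rows, samples in
#'   columns; dimnames are used as otu and sample ids when present.
#' @param taxonomy Per-OTU taxonomy strings.
#' @param kingdom Per-OTU kingdom labels (`"prokaryote"`, `"fungus"`,
#'   `"cercozoa"`), recycled if length 1.
#' @param guild Per-OTU guild labels (`"methanogen"`, `"methanotroph"`,
#'   `"none"`), recycled if length 1.
#' @return A validated count table tibble.
#' @export
count_table <- function(counts, taxonomy = NULL, kingdom = "prokaryote",
                        guild = "none") {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  otu_id <- rownames(counts) %||% sprintf("OTU%04d", seq_len(n))
  smp <- colnames(counts) %||% sprintf("S%02d", seq_len(ncol(counts)))
  taxonomy <- taxonomy %||% rep("Unclassified", n)
  tbl <- tibble::tibble(
    otu_id = otu_id,
    taxonomy = rep_len(taxonomy, n),
    kingdom = rep_len(kingdom, n),
    guild = rep_len(guild, n)
  )
  cnt <- tibble::as_tibble(counts, .name_repair = "minimal")
  names(cnt) <- smp
  out <- dplyr::bind_cols(tbl, cnt)
  validate_count_table(out)
}

#' Validate a count table
#'
#' Checks the invariants: unique OTU and sample ids, non-negative integer
#' counts, metadata columns present.
#'
#' @param table A count table tibble.
#' @return The table, invisibly unchanged, or an error.
#' @export
validate_count_table <- function(table) {
  miss <- setdiff(otu_meta_cols(), names(table))
  if (length(miss) > 0) {
    stop("count table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(table$otu_id)) {
    stop("duplicated otu_id in count table", call. = FALSE)
  }
  smp <- sample_ids(table)
  if (length(smp) == 0) stop("count table has no sample columns", call. = FALSE)
  if (anyDuplicated(smp)) {
    stop("duplicated sample columns in count table", call. = FALSE)
  }
  m <- as.matrix(table[, smp, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in count table", call. = FALSE)
  if (anyNA(m)) stop("missing counts in count table", call. = FALSE)
  if (any(m < 0)) stop("negative counts in count table", call. = FALSE)
  if (any(m != round(m))) stop("non-integer counts in count table", call. = FALSE)
  table
}

# relative abundances per sample (columns sum to 1; all-zero columns stay 0)
rel_abundance <- function(m) {
  cs <- colSums(m)
  cs[cs == 0] <- 1
  sweep(m, 2, cs, "/")
}

# run expr under a temporary RNG seed when seed is non-NULL
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index, used to compare a detected module
#' partition against a planted (ground-truth) one. 1 means identical
#' partitions (up to relabelling); 0 is the chance-level expectation.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
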