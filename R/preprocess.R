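# Rarefaction, prevalence filtering, alpha diversity, guild annotation and
# inundation-group assignment.

#' Rarefy a count table to fixed depth
#'
#' Subsamples each sample's reads without replacement down to `depth`, so
#' every retained sample sums exactly to `depth`. Samples with fewer reads
#' than `depth` are dropped with a warning; OTUs left with all-zero rows are
#' removed. The default depths used for multi-kingdom tables are 50000
#' (prokaryote), 51591 (fungus) and 33548 (cercozoa) reads.
#'
#' @param table A count table tibble.
#' @param depth Target depth: a positive integer, or a vector named by
#'   kingdom when `table` spans several kingdoms.
#' @param seed Integer seed for the subsampling.
#' @return A rarefied count table tibble.
#' @export
rarefy <- function(table, depth, seed = 1) {
  validate_count_table(table)
  if (any(depth <= 0)) stop("rarefaction depth must be positive", call. = FALSE)
  kingdoms <- unique(table$kingdom)
  if (is.null(names(depth))) {
    if (length(depth) != 1 && length(kingdoms) > 1) {
      stop("depth must be a scalar or named by kingdom", call. = FALSE)
    }
    depth <- setNames(rep_len(depth, length(kingdoms)), kingdoms)
  }
  out <- with_seed_if(seed, {
    parts <- lapply(kingdoms, function(k) {
      sub <- table[table$kingdom == k, , drop = FALSE]
      m <- otu_matrix(sub)
      d <- depth[[k]]
      tot <- colSums(m)
      low <- tot < d
      if (any(low)) {
        warning("dropping ", sum(low), " ", k, " sample(s) below depth ", d,
                ": ", paste(colnames(m)[low], collapse = ", "), call. = FALSE)
        m <- m[, !low, drop = FALSE]
      }
      if (ncol(m) == 0) return(sub[0, ])
      for (j in seq_len(ncol(m))) {
        if (sum(m[, j]) == d) next  # already at depth: unchanged
        reads <- rep.int(seq_len(nrow(m)), m[, j])
        kept <- reads[sample.int(length(reads), d)]
        m[, j] <- tabulate(kept, nbins = nrow(m))
      }
      keep_cols <- colnames(m)
      res <- sub[, c(otu_meta_cols(), keep_cols)]
      res[, keep_cols] <- as.data.frame(m)
      res
    })
    dplyr::bind_rows(parts)
  })
  m <- otu_matrix(out)
  out <- out[rowSums(m) > 0, , drop = FALSE]
  out
}

#' Prevalence filter
#'
#' Keeps OTUs present (count > 0) in strictly more than `min_prevalence` of
#' samples -- the "shared by more than 80% of samples" rule, so at the
#' default an OTU seen in exactly 8 of 10 samples is dropped and one seen in
#' 9 of 10 is kept.
#'
#' @param table A count table tibble.
#' @param min_prevalence Prevalence fraction; the retention rule is strict
#'   (`> min_prevalence`).
#' @return The filtered count table (a subset of the input rows).
#' @export
prevalence_filter <- function(table, min_prevalence = 0.8) {
  validate_count_table(table)
  m <- otu_matrix(table)
  prev <- rowMeans(m > 0)
  table[prev > min_prevalence, , drop = FALSE]
}

#' Alpha diversity indices per sample
#'
#' Shannon H (natural log, on relative abundances), Pielou evenness
#' `H / ln(S)` (defined for S > 1), observed richness, and the bias-corrected
#' Chao1 estimator `S + F1(F1 - 1) / (2(F2 + 1))` with `F1` singletons and
#' `F2` doubletons. Computed per kingdom when the table spans several.
#'
#' @param table A count table tibble (typically rarefied).
#' @return Tibble with columns `sample_id`, `kingdom`, `richness`, `shannon`,
#'   `pielou`, `chao1`. All-zero samples get NA indices.
#' @export
alpha_diversity <- function(table) {
  validate_count_table(table)
  parts <- lapply(unique(table$kingdom), function(k) {
    m <- otu_matrix(table[table$kingdom == k, , drop = FALSE])
    purrr::map_dfr(colnames(m), function(s) {
      x <- m[, s]
      tot <- sum(x)
      if (tot == 0) {
        return(tibble::tibble(sample_id = s, kingdom = k, richness = NA_real_,
                              shannon = NA_real_, pielou = NA_real_,
                              chao1 = NA_real_))
      }
      p <- x[x > 0] / tot
      h <- -sum(p * log(p))
      s_obs <- sum(x > 0)
      f1 <- sum(x == 1)
      f2 <- sum(x == 2)
      tibble::tibble(
        sample_id = s, kingdom = k,
        richness = s_obs,
        shannon = h,
        pielou = if (s_obs > 1) h / log(s_obs) else NA_real_,
        chao1 = s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
      )
    })
  })
  dplyr::bind_rows(parts)
}

#' Default taxonomy-to-guild rules for the methane cycle
#'
#' A compact stand-in for a full functional-annotation database: methanogen
#' orders (Methanopyrales, Methanococcales, Methanobacteriales,
#' Methanomicrobiales, Methanosarcinales, Methanocellales,
#' Methanomassiliicoccales) and common methanotroph markers (Methylococcales
#' and relatives). First match wins.
#'
#' @return Tibble with columns `pattern`, `guild`.
#' @export
default_guild_rules <- function() {
  tibble::tibble(
    pattern = c(methanogen_orders(), methanotroph_markers()),
    guild = c(rep("methanogen", length(methanogen_orders())),
              rep("methanotroph", length(methanotroph_markers())))
  )
}

#' Annotate OTU guilds from taxonomy substrings
#'
#' Sets each OTU's guild to the label of the first rule whose pattern occurs
#' in its taxonomy string; unmatched OTUs get `"none"`.
#'
#' @param table A count table tibble (prokaryote taxa carry the methane
#'   guilds).
#' @param rules Guild rule tibble (`pattern`, `guild`); defaults to
#'   [default_guild_rules()].
#' @return The count table with its `guild` column rewritten.
#' @export
annotate_guilds <- function(table, rules = default_guild_rules()) {
  validate_count_table(table)
  if (nrow(rules) == 0) stop("empty guild rule set", call. = FALSE)
  guild <- rep("none", nrow(table))
  assigned <- logical(nrow(table))
  for (i in seq_len(nrow(rules))) {
    hit <- !assigned & grepl(rules$pattern[i], table$taxonomy, fixed = TRUE)
    guild[hit] <- rules$guild[i]
    assigned <- assigned | hit
  }
  table$guild <- guild
  table
}

#' Assign inundation groups from depth
#'
#' Maps inundation depth to the three-level design: control and 0 cm to IL
#' (low), 5/10/20 cm to IM (moderate), 30/40 cm to IH (high).
#'
#' @param metadata Metadata tibble with an `inundation_depth_cm` column
#'   (numeric or `"control"`).
#' @return The metadata with a rewritten `group` column.
#' @export
assign_groups <- function(metadata) {
  stopifnot("inundation_depth_cm" %in% names(metadata))
  d <- as.character(metadata$inundation_depth_cm)
  grp <- dplyr::case_when(
    d %in% c("control", "0") ~ "IL",
    d %in% c("5", "10", "20") ~ "IM",
    d %in% c("30", "40") ~ "IH",
    TRUE ~ NA_character_
  )
  if (anyNA(grp)) {
    stop("unknown inundation depth value(s): ",
         paste(unique(d[is.na(grp)]), collapse = ", "), call. = FALSE)
  }
  metadata$group <- grp
  metadata
}
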