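# broom-style tidiers for the package's result objects.

#' @export
tidy.rmt_scan <- function(x, ...) x$scan

#' @export
glance.rmt_scan <- function(x, ...) {
  tibble::tibble(selected_threshold = x$selected, alpha = x$alpha,
                 n_thresholds = nrow(x$scan),
                 n_valid = sum(x$scan$valid))
}

#' @export
tidy.module_partition <- function(x, ...) x$membership

#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(n_modules = max(x$membership$module),
                 n_nodes = nrow(x$membership),
                 modularity = x$modularity,
                 method = x$method)
}

#' @export
tidy.eigengene_set <- function(x, ...) {
  eg <- x$eigengenes
  tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(sample_id = rownames(eg)),
                     tibble::as_tibble(eg)),
    -"sample_id", names_to = "module", values_to = "eigengene"
  ) |>
    dplyr::mutate(module = as.integer(.data$module)) |>
    dplyr::arrange(.data$module, .data$sample_id)
}

#' @export
glance.eigengene_set <- function(x, ...) x$variance

#' @export
tidy.mantel_test <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value,
                 permutations = x$permutations, exact = x$exact)
}

#' @export
glance.mantel_test <- tidy.mantel_test

#' @export
tidy.pca_ordination <- function(x, ...) x$scores

#' @export
glance.pca_ordination <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$explained_variance),
                 explained_variance = x$explained_variance)
}
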