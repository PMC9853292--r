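# ggplot2 displays for the main result types.

#' @export
autoplot.rmt_scan <- function(object, ...) {
  sc <- object$scan[object$scan$valid, ]
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$threshold)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_poisson,
                                    colour = "Poisson")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_goe, colour = "GOE")) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$selected, linetype = 3) +
    ggplot2::labs(x = "correlation threshold", y = "chi-square p-value",
                  colour = "NNSD fit",
                  title = paste0("RMT scan (selected threshold ",
                                 object$selected, ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pca_ordination <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (!is.null(groups)) df$group <- groups
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Zi-Pi keystone plot
#'
#' Scatter of within-module degree (Zi) against among-module connectivity
#' (Pi) with the role-cutoff lines; the four quadrants are the peripheral,
#' connector, module-hub and network-hub regions.
#'
#' @param roles Tibble from [zi_pi()].
#' @param zi_cutoff,pi_cutoff Cutoffs drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_zi_pi <- function(roles, zi_cutoff = 0.25, pi_cutoff = 0.62) {
  ggplot2::ggplot(roles, ggplot2::aes(x = .data$pi, y = .data$zi,
                                      colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = zi_cutoff, linetype = 2) +
    ggplot2::geom_vline(xintercept = pi_cutoff, linetype = 2) +
    ggplot2::labs(x = "among-module connectivity (Pi)",
                  y = "within-module degree (Zi)", colour = "role") +
    ggplot2::theme_minimal()
}

#' Module-trait correlation heatmap
#'
#' Tile plot of Pearson r between module eigengenes and traits, annotated
#' with significance stars.
#'
#' @param module_traits Tibble from [eigengene_trait_correlation()].
#' @return A ggplot object.
#' @export
plot_module_traits <- function(module_traits) {
  ggplot2::ggplot(module_traits,
                  ggplot2::aes(x = .data$trait,
                               y = factor(.data$module),
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "module", fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
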