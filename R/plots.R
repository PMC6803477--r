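# Plotting helpers (ggplot2, suggested dependency).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
}

#' Torso map: tau_116 against alpha_116
#'
#' Scatter of the pseudo bond angle against the pseudo dihedral angle at
#' IMGT position 116, coloured by torso class; the alpha = 0 boundary
#' between extended and kinked bases is drawn.
#'
#' @param report Output of [torso_report()].
#' @return A ggplot object.
#' @export
plot_torso_map <- function(report) {
  need_ggplot()
  ggplot2::ggplot(report, ggplot2::aes(x = .data$alpha116, y = .data$tau116,
                                       colour = .data$torso_class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(alpha[116] * " (deg)"),
                  y = expression(tau[116] * " (deg)"), colour = "torso") +
    ggplot2::theme_minimal()
}

#' PCA scores of one-hot encoded CDR sequences
#'
#' @param pca Output of [one_hot_pca()].
#' @return A ggplot object.
#' @export
plot_sequence_pca <- function(pca) {
  need_ggplot()
  ev <- pca$explained_variance
  pct <- 100 * ev[1:2] / sum(ev)
  ggplot2::ggplot(pca$scores, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                           colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}
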