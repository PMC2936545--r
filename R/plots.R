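#' Module-trait correlation heatmap
#'
#' Tile plot of Spearman correlations between module eigengenes and traits,
#' annotated with the correlation and starred when passing the adjusted
#' significance gate.
#'
#' @param module_trait Output of [module_trait_correlation()].
#' @return A ggplot object.
#' @export
plot_module_trait <- function(module_trait) {
  module_trait |>
    dplyr::mutate(label = sprintf("%.2f%s", .data$rho,
                                  ifelse(.data$significant, "*", ""))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$trait, y = .data$module,
                                 fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' Soft-threshold selection diagnostics
#'
#' Signed scale-free fit and mean connectivity against candidate powers.
#'
#' @param fit_table `fit_table` from [select_soft_power()].
#' @param r2_min Qualification line.
#' @return A ggplot object.
#' @export
plot_scale_free <- function(fit_table, r2_min = 0.80) {
  fit_table |>
    tidyr::pivot_longer(c("signed_r2", "mean_k"), names_to = "panel") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$power, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(
      data = data.frame(panel = "signed_r2", y = r2_min),
      ggplot2::aes(yintercept = .data$y), linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "soft threshold power", y = NULL) +
    ggplot2::theme_minimal()
}

#' Replicate MA plot
#'
#' @param ma Tibble from [replicate_ma()].
#' @return A ggplot object.
#' @export
plot_ma <- function(ma) {
  ggplot2::ggplot(ma, ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, colour = "red") +
    ggplot2::labs(x = "A (mean log2 intensity)",
                  y = "M (log2 replicate ratio)") +
    ggplot2::theme_minimal()
}

#' Module membership versus gene significance scatter
#'
#' @param kme_gs Tibble from [module_membership_vs_significance()].
#' @return A ggplot object.
#' @export
plot_kme_gs <- function(kme_gs) {
  r <- attr(kme_gs, "cor_kme_gs")
  ggplot2::ggplot(kme_gs, ggplot2::aes(x = abs(.data$kME), y = .data$GS)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "module membership |kME|",
                  y = "gene significance |cor(probe, trait)|",
                  subtitle = if (!is.na(r)) sprintf("cor = %.2f", r)) +
    ggplot2::theme_minimal()
}
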