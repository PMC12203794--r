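# ggplot2 visualisations for the main result types.

#' Volcano plot of a differential expression result
#' @param object an `ep_de` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ep_de
#' @export
autoplot.ep_de <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(down = "#2166AC", ns = "grey70",
                                            up = "#B2182B")) +
    ggplot2::labs(x = "log2 fold change (high - low)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Step plot of a Kaplan-Meier curve
#' @param object an `ep_km` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ep_km
#' @export
autoplot.ep_km <- function(object, ...) {
  df <- dplyr::bind_rows(tibble::tibble(time = 0, surv = 1),
                         tibble::as_tibble(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "disease-free survival") +
    ggplot2::theme_minimal()
}

#' Normalised-enrichment-score bar chart of a GSEA result
#' @param object a `gsea_result` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$nes)) |>
    dplyr::arrange(.data$nes) |>
    dplyr::mutate(set = factor(.data$set, levels = .data$set))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes, y = .data$set,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#B2182B", `FALSE` = "grey70")) +
    ggplot2::labs(x = "NES", y = NULL, fill = "significant") +
    ggplot2::theme_minimal()
}

#' Hazard-ratio heatmap of a survival screen
#'
#' log2 hazard ratios per gene per cohort, masked to significant
#' (gene, cohort) pairs.
#' @param screen a `survival_screen`.
#' @return A ggplot.
#' @export
plot_hr_heatmap <- function(screen) {
  df <- screen$results |>
    dplyr::mutate(log2_hr = ifelse(.data$significant, log2(.data$hr), NA_real_))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$cohort_id,
                                   fill = .data$log2_hr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2(HR)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Running-sum plot for one gene set
#' @param ranked a `ranked_list`.
#' @param gene_set character vector of genes.
#' @param weight metric exponent.
#' @return A ggplot of the GSEA running enrichment score.
#' @export
plot_enrichment <- function(ranked, gene_set, weight = 1) {
  es <- enrichment_score(ranked, gene_set, weight = weight)
  ggplot2::ggplot(es$running, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "rank", y = "running enrichment score",
                  subtitle = sprintf("ES = %.3f", es$es)) +
    ggplot2::theme_minimal()
}
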