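# ggplot2 helpers for the main result types.

#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$oof, ggplot2::aes(x = .data$age, y = .data$dnam_age)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::labs(x = "Chronological age (years)",
                  y = "DNAm age (out-of-fold, years)",
                  title = sprintf("%d-fold cross-validation", object$n_folds)) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of an EWAS result
#'
#' @param manhattan Table from [export_manhattan()].
#' @param threshold Genome-wide significance level drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(manhattan, threshold = 1e-7) {
  chroms <- unique(manhattan$chrom)
  df <- dplyr::mutate(manhattan,
                      chrom = factor(.data$chrom, levels = chroms))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$minus_log10_p,
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 2,
                        colour = "red") +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Genomic position", y = "-log10(p)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(0.1, "lines"))
}

#' Heatmap of signed enrichment scores (states x CpG sets)
#'
#' @param results An `enrichment_result` covering one or more sets.
#' @param p_threshold Optional display filter as in [signed_log10p_matrix()].
#' @return A ggplot object.
#' @export
plot_enrichment_heatmap <- function(results, p_threshold = NULL) {
  wide <- signed_log10p_matrix(results, p_threshold)
  long <- tidyr::pivot_longer(wide, -"state", names_to = "set",
                              values_to = "signed_score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$set, y = .data$state,
                                     fill = .data$signed_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "signed\n-log10(p)") +
    ggplot2::theme_minimal()
}

#' Age-trajectory scatter with LOWESS overlay
#'
#' @param report A `trajectory_report`.
#' @param beta,sheet,annotation The data the report was computed from (used
#'   to redraw the per-sample points).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(report, beta, sheet, annotation = NULL) {
  pts <- purrr::map(unique(report$report$target), function(tg) {
    vals <- if (tg %in% rownames(beta)) beta[tg, ]
    else state_mean_methylation(beta, annotation, tg)
    tibble::tibble(target = tg, age = sheet$age[match(colnames(beta),
                                                      sheet$sample_id)],
                   value = vals)
  }) %>% dplyr::bind_rows()
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_line(data = report$curves,
                       ggplot2::aes(x = .data$age, y = .data$fitted),
                       colour = "red", linewidth = 0.8) +
    ggplot2::facet_wrap(~target, scales = "free_y") +
    ggplot2::labs(x = "Chronological age (years)", y = "Beta value") +
    ggplot2::theme_minimal()
}

#' QC PCA score plot coloured by a sample covariate
#'
#' @param pca A `pca_qc` result.
#' @param sheet Sample sheet.
#' @param colour Covariate column to colour by (default `sex`).
#' @return A ggplot object.
#' @export
plot_pca_qc <- function(pca, sheet, colour = "sex") {
  df <- dplyr::left_join(pca$scores, sheet, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data[[colour]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * pca$variance_explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * pca$variance_explained[2])) +
    ggplot2::theme_minimal()
}
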