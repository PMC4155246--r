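#' Plot an R-squared cutoff sweep
#'
#' FDR and FNR as a function of the goodness-of-fit cutoff, the standard way
#' to choose the filter level for a given design.
#'
#' @param object A [tc_rsq_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tc_sweep
#' @export
autoplot.tc_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[c("rsq", "fdr", "fnr")],
                            c("fdr", "fnr"), names_to = "metric",
                            values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(.data$rsq, .data$rate,
                                   colour = toupper(.data$metric))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(R^2 ~ "cutoff"), y = "rate", colour = NULL)
}

#' Plot the screening p-value distribution
#'
#' Histogram of the step-1 p-values; under the global null it should be flat,
#' and an excess near zero reflects genes with non-flat profiles.
#'
#' @param object A [tc_screen()] result.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tc_screen
#' @export
autoplot.tc_screen <- function(object, bins = 20, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$p_value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, length.out = bins + 1),
                            fill = "grey35", colour = "white") +
    ggplot2::labs(x = "screening p-value", y = "genes")
}

#' Plot observed counts and fitted trends for selected genes
#'
#' Observed expression against time, one panel per gene and one colour per
#' series, with the optimised model's fitted mean profile overlaid when a
#' [tc_stepwise()] result is supplied.
#'
#' @param counts Genes x samples matrix used in the fit.
#' @param design The matching [tc_design()].
#' @param genes Character vector of gene ids to display.
#' @param models Optional [tc_stepwise()] result providing fitted profiles.
#' @return A ggplot object.
#' @export
plot_gene_trends <- function(counts, design, genes, models = NULL) {
  m <- as_counts_matrix(counts)
  if (!is.null(colnames(m))) m <- m[, design$sample_id, drop = FALSE]
  missing_genes <- setdiff(genes, rownames(m))
  if (length(missing_genes))
    abort(paste0("gene id(s) not in counts: ",
                 paste(missing_genes, collapse = ", ")))

  obs <- bind_rows(lapply(genes, function(g) {
    tibble(gene_id = g, sample_id = design$sample_id, time = design$time,
           series = as.character(design$series), value = m[g, ])
  }))
  p <- ggplot2::ggplot(obs, ggplot2::aes(.data$time, .data$value,
                                         colour = .data$series)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::labs(x = "time", y = "expression", colour = "series")

  if (!is.null(models)) {
    keep <- intersect(genes, models$gene_id)
    if (length(keep)) {
      mu <- fitted_profiles(models)[keep, , drop = FALSE]
      fit <- bind_rows(lapply(keep, function(g) {
        tibble(gene_id = g, time = design$time,
               series = as.character(design$series),
               value = mu[g, design$sample_id])
      }))
      fit <- dplyr::distinct(fit)
      p <- p + ggplot2::geom_line(data = fit, linewidth = 0.7)
    }
  }
  p
}
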