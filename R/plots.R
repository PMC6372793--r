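# ggplot2 graphics, one per result type.

#' Plot rho distributions by functional category
#'
#' Per-category distribution of the activity-correlation rho: activity
#' categories (energy metabolism, ribosomal proteins, stress) should sit
#' near 1 when the population is transcriptionally active, growth
#' categories (COG D/L/M) near 0 at zero growth.
#'
#' @param object A `zg_activity_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zg_activity_screen <- function(object, ...) {
  df <- object$records %>%
    filter(!is.na(.data$rho)) %>%
    mutate(
      category = factor(.data$category, levels = gene_categories()),
      significant = !is.na(.data$p_adj) & .data$p_adj < object$alpha
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$rho)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$significant),
                         width = 0.2, size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = NULL, y = "Spearman rho vs total mRNA",
                  colour = paste0("FDR < ", object$alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a qPCR population series
#'
#' log10 16S rRNA gene copies per cm^3 against incubation day, one panel
#' per sulfate regime, coloured by substrate; a flat band indicates a
#' stable (zero-growth) population.
#'
#' @param qpcr qPCR tibble ([simulate_qpcr()] / [read_qpcr_tsv()]).
#' @return A ggplot.
#' @export
plot_qpcr_series <- function(qpcr) {
  ggplot2::ggplot(qpcr, ggplot2::aes(x = .data$day,
                                     y = .data$copies_per_cm3,
                                     colour = .data$substrate)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::stat_summary(fun = stats::median, geom = "line") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$sulfate)) +
    ggplot2::labs(x = "day", y = "16S rRNA gene copies per cm^3") +
    ggplot2::theme_minimal()
}

#' Differential-coverage binning plot
#'
#' Native-soil coverage against (GC-transformed) SIP coverage per scaffold,
#' on log axes, point size by scaffold length; when a bin selection is
#' given its gates are drawn and members highlighted.
#'
#' @param scaffolds Scaffold tibble.
#' @param bin Optional `zg_bin` from [select_bin()].
#' @param transformed Plot GC-transformed SIP coverage (default TRUE).
#' @return A ggplot.
#' @export
plot_sip_coverage <- function(scaffolds, bin = NULL, transformed = TRUE) {
  exponent <- if (is.null(bin)) 9 else bin$gates$exponent
  scale <- if (is.null(bin)) 1e15 else bin$gates$scale
  df <- scaffolds %>%
    mutate(cov_b_plot = if (transformed) {
      gc_transform_coverage(.data$coverage_b, .data$gc_percent, exponent, scale)
    } else {
      .data$coverage_b
    })
  if (!is.null(bin)) {
    df <- mutate(df, in_bin = .data$scaffold_id %in% bin$scaffolds$scaffold_id)
  } else {
    df <- mutate(df, in_bin = FALSE)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$coverage_a,
                                        y = .data$cov_b_plot)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$length_nt,
                                     colour = .data$in_bin), alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "coverage, native soil",
                  y = if (transformed) "GC-transformed coverage, SIP fraction"
                      else "coverage, SIP fraction",
                  colour = "in bin", size = "scaffold nt") +
    ggplot2::theme_minimal()
  if (!is.null(bin)) {
    g <- bin$gates
    p <- p + ggplot2::annotate("rect",
      xmin = g$cov_a[1], xmax = g$cov_a[2],
      ymin = g$cov_b_transformed[1], ymax = g$cov_b_transformed[2],
      fill = NA, colour = "#0072B2", linetype = 2
    )
  }
  p
}

#' Volcano plot of a DE table
#'
#' @param object A `zg_de` tibble.
#' @param alpha FDR threshold highlighted.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zg_de <- function(object, alpha = 0.05, ...) {
  df <- mutate(as_tibble(object),
               significant = !is.na(.data$p_adj) & .data$p_adj < alpha)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold_change,
                                        y = -log10(pmax(.data$p_raw, 1e-300)))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        size = 0.7, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = paste0("FDR < ", alpha)) +
    ggplot2::theme_minimal()
  if ("comparison" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$comparison))
  }
  p
}

#' Plot response-group expression profiles
#'
#' Per-gene expression profiles scaled 0-1 ([scale_unit_interval()]),
#' overlaid by response group with the group median highlighted.
#'
#' @param values Expression tibble (`gene_id` + sample columns), typically
#'   variance-stabilized counts over the compared samples.
#' @param clusters Cluster assignment from [cut_clusters()].
#' @return A ggplot.
#' @export
plot_response_groups <- function(values, clusters) {
  m <- counts_matrix(values, allow_negative = TRUE)
  m <- m[rownames(m) %in% clusters$gene_id, , drop = FALSE]
  scaled <- t(apply(m, 1, scale_unit_interval))
  colnames(scaled) <- colnames(m)
  df <- matrix_to_tbl(scaled) %>%
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "scaled") %>%
    left_join(select(clusters, "gene_id", "cluster_id"), by = "gene_id") %>%
    mutate(sample_id = factor(.data$sample_id, levels = colnames(m)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$scaled,
                                   group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.25, colour = "grey40") +
    ggplot2::stat_summary(ggplot2::aes(group = .data$cluster_id),
                          fun = stats::median, geom = "line",
                          colour = "#0072B2", linewidth = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cluster_id)) +
    ggplot2::labs(x = NULL, y = "scaled expression (0-1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
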