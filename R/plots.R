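#' Plot a metagene methylation profile
#'
#' One line per context over upstream, body and downstream bins, with
#' dashed guides at the gene boundaries.
#'
#' @param object A `metagene_profile` from [metagene_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  spec <- attr(object, "bin_spec")
  n_up <- spec$upstream_bp / spec$bin_bp
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin, y = .data$level,
                               colour = .data$context)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(n_up + 0.5,
                                       n_up + spec$n_body_bins + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "bin (upstream | gene body | downstream)",
                  y = "methylation level",
                  colour = "context") +
    ggplot2::theme_minimal()
}

#' Plot a cumulative dominance curve
#'
#' Cumulative share of triplets whose highest-expressed copy is each
#' sub-genome, along the ranking by Tukey interaction p-value.
#'
#' @param object A `dominance_curve` from [cumulative_dominance_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dominance_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              dplyr::all_of(c("LF", "MF1", "MF2")),
                              names_to = "subgenome",
                              values_to = "cumulative_fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank,
                                     y = .data$cumulative_fraction,
                                     colour = .data$subgenome)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "triplets ranked by interaction p-value",
                  y = "cumulative fraction highest-expressed") +
    ggplot2::theme_minimal()
}

#' Plot a heterozygosity profile
#'
#' Per-marker het frequency along the chromosome; the centromere sits at
#' the peak in an FDR half-tetrad population.
#'
#' @param object A `het_profile` from [heterozygosity_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.het_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos_bp,
                                       y = .data$het_freq)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "heterozygosity frequency") +
    ggplot2::theme_minimal()
}

#' Plot expression against gene-body methylation bins
#'
#' Median and quartiles of transformed expression per methylation bin.
#'
#' @param object A `meth_expr_bins` from [methylation_expression_bins()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meth_expr_bins <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), .data$n > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_mid, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q1, ymax = .data$q3)) +
    ggplot2::labs(x = "gene-body mCG level", y = "ln(FPKM + 1)") +
    ggplot2::theme_minimal()
}

#' Plot a triplet correlation matrix in its PCA ordering
#'
#' @param object A `triplet_correlation` from [triplet_correlation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.triplet_correlation <- function(object, ...) {
  ord <- object$ordering
  m <- object$cor[ord, ord]
  d <- as_tibble(as.data.frame(as.table(m)), .name_repair = "minimal")
  names(d) <- c("var1", "var2", "r")
  d$var1 <- factor(d$var1, levels = ord)
  d$var2 <- factor(d$var2, levels = rev(ord))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$var1, y = .data$var2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
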