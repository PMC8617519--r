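# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a trinucleotide spectrum
#'
#' @param object A `mut_spectrum`.
#' @param ... Unused.
#' @return A ggplot faceted by substitution class.
#' @export
autoplot.mut_spectrum <- function(object, ...) {
  d <- tidy(object)
  d$context <- paste0(d$fivep, ".", d$threep)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$context, y = .data$value,
                                  fill = .data$substitution)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(. ~ substitution, scales = "free_x") +
    ggplot2::labs(x = "flanking context (5'.3')", y = "mutations",
                  title = attr(object, "source")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5,
                                                       vjust = 0.5))
}

#' Observed versus reconstructed spectrum of a refit
#'
#' @param object A `sig_refit`.
#' @param ... Unused.
#' @return A ggplot overlaying the observed spectrum and its
#'   non-negative reconstruction.
#' @export
autoplot.sig_refit <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(tidy(object$observed), which = "observed"),
    dplyr::mutate(tidy(object$reconstructed), which = "reconstructed"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$channel, y = .data$value,
                                  fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(. ~ substitution, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "mutations",
                  subtitle = sprintf("fraction explained = %.2f",
                                     object$fraction_explained)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Copy-number heat map of cells by genomic bin
#'
#' A basic tile display of the normalised profiles, rows grouped by
#' cluster, in the spirit of single-cell aneuploidy heat maps.
#'
#' @param cn Normalised profile tibble ([normalize_counts()]).
#' @param assignment Optional cluster assignment used to order rows.
#' @param max_cn Copy numbers are clipped to this value for display.
#' @return A ggplot.
#' @export
plot_cn_heatmap <- function(cn, assignment = NULL, max_cn = 4) {
  cells <- setdiff(names(cn), c("contig", "start", "end", "weight"))
  d <- tidyr::pivot_longer(cn, dplyr::all_of(cells), names_to = "cell",
                           values_to = "cn")
  d$bin <- paste0(d$contig, ":", d$start)
  d$bin <- factor(d$bin, levels = unique(d$bin))
  if (!is.null(assignment)) {
    ord <- assignment[order(assignment$cluster, assignment$cell), ]
    d$cell <- factor(d$cell, levels = ord$cell)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$cell,
                                  fill = pmin(.data$cn, max_cn))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 2, low = "blue", mid = "white",
                                  high = "red", name = "CN") +
    ggplot2::labs(x = "genomic bin", y = "cell") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
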