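# ggplot2 views of the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.mite_age_hist <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_mid / 1e6, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin") / 1e6 * 0.9,
                      fill = "grey35") +
    ggplot2::labs(x = "Insertion age (Myr)", y = "Elements",
                  title = "Insertion-age distribution") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mite_tss_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_mid / 1e3, y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~site, ncol = 1) +
    ggplot2::labs(x = "Distance from site (kb, negative = upstream)",
                  y = "Elements") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mite_depth <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::labs(x = "Consensus position (bp)", y = "Read depth") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mite_positions <- function(object, ...) {
  counts <- as.data.frame(table(factor(
    object$category,
    levels = c("exon", "intron", "upstream", "downstream", "intergenic"))))
  names(counts) <- c("category", "n")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "Elements", title = "Genomic position") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mite_discovery <- function(object, ...) {
  el <- object$elements
  ggplot2::ggplot(el, ggplot2::aes(x = .data$length, y = .data$at_fraction,
                                   colour = .data$family_id)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Element length (bp)", y = "AT fraction",
                  colour = "Family") +
    ggplot2::theme_minimal()
}
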