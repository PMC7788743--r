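utils::globalVariables(c("population", "Freq", "length_class", "pos_bp",
                         "incidence", "chrom"))

#' Bar chart of ROH counts per length class per breed
#'
#' @param runs ROH segment data.frame from [detect_roh()] (with populations).
#' @return a ggplot object.
#' @export
plot_roh_length_bins <- function(runs) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  d <- as.data.frame(table(population = runs$population,
                           length_class = runs$length_class))
  ggplot2::ggplot(d, ggplot2::aes(x = population, y = Freq, fill = length_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "ROH count", fill = "length") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Per-chromosome incidence of common runs per SNP
#'
#' @param inc incidence table from [incidence_per_snp()].
#' @param chroms chromosomes to show (default all).
#' @return a ggplot object (position vs incidence, faceted by chromosome).
#' @export
plot_incidence <- function(inc, chroms = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  if (!is.null(chroms)) inc <- inc[inc$chrom %in% chroms, , drop = FALSE]
  ggplot2::ggplot(inc, ggplot2::aes(x = pos_bp / 1e6, y = incidence)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "animals in ROH") +
    ggplot2::theme_minimal()
}
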