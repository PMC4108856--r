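#' Bar chart of gene-selection frequencies
#'
#' @param freq A [selection_frequency()] table.
#' @param top Number of most-selected genes to show; default 10.
#' @return A ggplot with one horizontal bar per gene. When the table
#'   carries stratified `count_*` columns the bars are stacked by stratum,
#'   mirroring the usual per-classifier breakdown.
#' @export
plot_selection_frequency <- function(freq, top = 10L) {
  shown <- head(freq, top)
  strata_cols <- grep("^count_", names(shown), value = TRUE)
  shown$gene_id <- factor(shown$gene_id, levels = rev(shown$gene_id))
  if (length(strata_cols)) {
    long <- tidyr::pivot_longer(
      shown[c("gene_id", strata_cols)],
      dplyr::all_of(strata_cols),
      names_to = "stratum", values_to = "count", names_prefix = "count_"
    )
    ggplot2::ggplot(long, ggplot2::aes(.data$count, .data$gene_id, fill = .data$stratum)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "times selected", y = NULL, fill = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(shown, ggplot2::aes(.data$frequency, .data$gene_id)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "selection frequency (%)", y = NULL) +
      ggplot2::theme_minimal()
  }
}
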