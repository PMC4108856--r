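#' Welch's unequal-variance t statistic
#'
#' The two-sample t statistic under unknown, unequal group variances, with
#' Welch--Satterthwaite degrees of freedom. Used here purely as a ranking
#' key for gene filtering, not as a hypothesis test.
#'
#' Degenerate inputs get sentinels so every gene is rankable: if both group
#' variances are zero the statistic is 0 when the means agree and signed
#' infinity (ranked first by absolute value) when they differ.
#'
#' @param x0,x1 Numeric values of the gene in class 0 and class 1; each
#'   group needs at least 2 values.
#' @return A one-row tibble with `t` and `df`.
#' @export
#' @examples
#' welch_t_statistic(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
welch_t_statistic <- function(x0, x1) {
  n0 <- length(x0)
  n1 <- length(x1)
  if (n0 < 2L || n1 < 2L) abort_validation("each group needs >= 2 values.")
  m0 <- mean(x0)
  m1 <- mean(x1)
  v0 <- var(x0)
  v1 <- var(x1)
  se2 <- v0 / n0 + v1 / n1
  if (se2 == 0) {
    t <- if (m0 == m1) 0 else sign(m0 - m1) * Inf
    df <- NA_real_
  } else {
    t <- (m0 - m1) / sqrt(se2)
    df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  }
  tibble::tibble(t = t, df = df)
}

#' Rank genes by absolute Welch t statistic
#'
#' Computes the Welch t statistic of every gene between the two classes and
#' orders genes by decreasing |t| (a two-sided criterion, equivalent to
#' ordering by smallest Welch p-value). Ties in |t| keep the original
#' column order, so the ranking is deterministic.
#'
#' @param data An expression tibble (gene columns + `label`).
#' @return A tibble with `gene_id`, `t`, `df`, `rank`, ordered by rank.
#' @export
rank_genes <- function(data) {
  validate_expression(data)
  genes <- gene_ids(data)
  x <- as.matrix(data[genes])
  i0 <- data$label == 0
  n0 <- sum(i0)
  n1 <- sum(!i0)
  if (n0 < 2L || n1 < 2L) abort_validation("each class needs >= 2 samples.")

  m0 <- colMeans(x[i0, , drop = FALSE])
  m1 <- colMeans(x[!i0, , drop = FALSE])
  v0 <- colSums(sweep(x[i0, , drop = FALSE], 2, m0)^2) / (n0 - 1)
  v1 <- colSums(sweep(x[!i0, , drop = FALSE], 2, m1)^2) / (n1 - 1)
  se2 <- v0 / n0 + v1 / n1
  t <- ifelse(se2 == 0, ifelse(m0 == m1, 0, sign(m0 - m1) * Inf), (m0 - m1) / sqrt(se2))
  df <- ifelse(
    se2 == 0, NA_real_,
    se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  )

  ord <- order(-abs(t), seq_along(genes))
  tibble::tibble(
    gene_id = genes[ord], t = unname(t[ord]), df = unname(df[ord]),
    rank = seq_along(genes)
  )
}

#' Retain the top fraction of genes by |t|
#'
#' The pre-selection filter applied before any wrapper search: keeps the
#' `floor(fraction * n_genes)` genes (at least 1) with the largest absolute
#' Welch t statistic. Output columns are ordered by rank, values untouched;
#' the result is the search pool for [run_ga()] and [run_sfs()].
#'
#' @param data An expression tibble.
#' @param fraction Fraction of genes to retain, in (0, 1]; default 0.05.
#' @return A reduced expression tibble (ranked genes + `label`).
#' @export
#' @examples
#' # 5% of 7129 genes -> floor(356.45) = 356 retained
preselect_top_fraction <- function(data, fraction = 0.05) {
  validate_expression(data)
  if (!(is.numeric(fraction) && length(fraction) == 1L && fraction > 0 && fraction <= 1)) {
    abort_validation("`fraction` must lie in (0, 1].")
  }
  ranking <- rank_genes(data)
  n_keep <- max(1L, as.integer(floor(fraction * nrow(ranking))))
  keep <- ranking$gene_id[seq_len(n_keep)]
  out <- data[c(keep, "label")]
  attr(out, "informative") <- attr(data, "informative")
  out
}
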