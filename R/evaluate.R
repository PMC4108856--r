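#' Repeated random holdout evaluation
#'
#' The evaluation protocol of the package: the train/test split is redrawn
#' `n_reps` times (default 50) with seeds derived from `base_seed`, and the
#' classifier is fitted and scored on each. Either a fixed gene subset
#' (`genes`) or a selector function is supplied; a selector — e.g. a GA or
#' stepwise wrapper — is re-run on every repetition and its selected gene
#' set recorded, so selection variability enters the evaluation.
#'
#' @param data An expression tibble.
#' @param spec A [classifier_spec()].
#' @param genes Fixed gene subset to evaluate (ignored if `selector` given).
#' @param selector Optional `function(data, split, seed)` returning a
#'   character vector of selected gene ids for that repetition.
#' @param n_reps Number of repetitions.
#' @param base_seed Seed from which each repetition's seed is derived.
#' @param train_fraction,stratify Passed to [split_holdout()].
#' @return A `repeated_result` with per-repetition scores (tibble, one row
#'   per repetition with a `genes` list-column) and summary statistics via
#'   [glance()].
#' @export
repeated_holdout <- function(data, spec, genes = NULL, selector = NULL,
                             n_reps = 50L, base_seed = 1L,
                             train_fraction = 0.6, stratify = FALSE) {
  validate_expression(data)
  if (!is_count(n_reps)) abort_validation("`n_reps` must be >= 1.")
  if (is.null(genes) && is.null(selector)) {
    abort_validation("supply either `genes` or `selector`.")
  }
  handle <- make_classifier(spec)

  rows <- purrr::map(seq_len(n_reps), function(r) {
    seed_r <- derive_seed(base_seed, r)
    split <- split_holdout(data, train_fraction, seed = seed_r, stratify = stratify)
    sel <- if (is.null(selector)) genes else selector(data, split, seed_r)
    if (length(sel) == 0L) abort_validation("selector returned an empty gene set.")
    sc <- evaluate_split(data, handle, sel, split)
    dplyr::mutate(sc, rep = r, seed = seed_r, genes = list(sel), .before = 1)
  })
  structure(
    list(scores = dplyr::bind_rows(rows), spec = spec, base_seed = base_seed),
    class = "repeated_result"
  )
}

#' @export
print.repeated_result <- function(x, ...) {
  g <- glance(x)
  cat(
    "<repeated_result> ", nrow(x$scores), " repetitions: accuracy ",
    sprintf("%.4f +/- %.4f", g$mean_acc, g$std_acc), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-repetition scores of a repeated holdout
#'
#' @param x A `repeated_result`.
#' @param ... Unused.
#' @return Tibble with one row per repetition.
#' @export
tidy.repeated_result <- function(x, ...) {
  x$scores
}

#' Summary statistics of a repeated holdout
#'
#' @param x A `repeated_result`.
#' @param ... Unused.
#' @return One-row tibble: mean/SD accuracy, mean FP and FN rates, mean
#'   number of genes used.
#' @export
glance.repeated_result <- function(x, ...) {
  s <- x$scores
  tibble::tibble(
    n_reps = nrow(s),
    mean_acc = mean(s$acc), std_acc = sd(s$acc),
    mean_fp = mean(s$fp_rate), mean_fn = mean(s$fn_rate),
    mean_n_genes = mean(lengths(s$genes))
  )
}

#' Parameter-grid sweep with FP/FN summaries
#'
#' Evaluates every configuration of a classifier's parameter grid under
#' repeated holdout on a fixed gene subset, giving one point per
#' configuration in the (mean FP, mean FN) plane — the configuration
#' "cloud" of the method. Two scalar summaries accompany the cloud:
#' `compactness`, the SD of accuracy over all configurations and
#' repetitions (low = robust to the parameter choice), and `distance`, the
#' Euclidean distance of the cloud's mean point from the origin
#' `sqrt(mean_fp^2 + mean_fn^2)` (the origin FP = FN = 0 is perfect
#' classification). Every point satisfies `mean_fp + mean_fn <= 1`.
#'
#' @param data An expression tibble.
#' @param method Classifier name, see [classifier_spec()].
#' @param genes Gene subset used as features throughout the sweep.
#' @param grid Named list of parameter value vectors; default the method's
#'   full declared grid from [default_grids()].
#' @param n_reps Repetitions per configuration.
#' @param base_seed Master seed; every configuration derives its own.
#' @return A `sweep_result` with the per-configuration `points` tibble and
#'   the two summaries.
#' @export
sweep_parameters <- function(data, method, genes, grid = NULL,
                             n_reps = 10L, base_seed = 1L) {
  validate_expression(data)
  grid <- grid %||% default_grids()[[method]]
  if (is.null(grid)) abort_validation(paste0("unknown method: ", method))
  configs <- if (length(grid) == 0L) {
    list(list())
  } else {
    df <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    if (method == "NB") {
      df <- df[!(df$kernel_density == 1 & df$discretize == 1), , drop = FALSE]
    }
    purrr::transpose(as.list(df))
  }
  if (length(configs) == 0L) abort_validation("empty parameter grid.")

  acc_all <- list()
  points <- purrr::imap(configs, function(cfg, i) {
    spec <- classifier_spec(method, cfg, seed = derive_seed(base_seed, 10000L + i))
    rr <- repeated_holdout(
      data, spec,
      genes = genes, n_reps = n_reps,
      base_seed = base_seed # same split sequence for every configuration
    )
    acc_all[[i]] <<- rr$scores$acc
    g <- glance(rr)
    dplyr::bind_cols(
      tibble::as_tibble(cfg),
      tibble::tibble(
        mean_acc = g$mean_acc, acc_sd = g$std_acc,
        mean_fp = g$mean_fp, mean_fn = g$mean_fn
      )
    )
  })
  points <- dplyr::bind_rows(points)
  accs <- unlist(acc_all)
  structure(
    list(
      method = method, points = points,
      compactness = if (length(accs) > 1L) sd(accs) else 0,
      distance = sqrt(mean(points$mean_fp)^2 + mean(points$mean_fn)^2),
      n_reps = n_reps, base_seed = base_seed
    ),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(
    "<sweep_result> ", x$method, ": ", nrow(x$points),
    " configuration(s); compactness ", signif(x$compactness, 4),
    ", distance to origin ", signif(x$distance, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-configuration points of a parameter sweep
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return Tibble with one row per grid configuration.
#' @export
tidy.sweep_result <- function(x, ...) {
  x$points
}

#' One-row summary of a parameter sweep
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return Tibble with compactness and distance to origin.
#' @export
glance.sweep_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_configs = nrow(x$points),
    compactness = x$compactness, distance = x$distance
  )
}

#' FP/FN cloud of a parameter sweep
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot: one point per configuration in the FP/FN plane, with
#'   the contradiagonal `FP + FN = 1` drawn for reference.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$mean_fp, .data$mean_fn)) +
    ggplot2::geom_abline(intercept = 1, slope = -1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "mean false-positive rate", y = "mean false-negative rate",
      title = paste0(
        object$method, ": distance ", signif(object$distance, 3),
        " +/- ", signif(object$compactness, 3)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Gene-selection frequency across runs
#'
#' How often each gene appears in a collection of selected gene sets, as a
#' percentage of runs (2 decimal places). With `strata` (e.g. the
#' classifier behind each run) the count is additionally broken down into
#' one column per stratum; stratified counts always sum to the total.
#'
#' @param runs List of character vectors, one selected gene set per run.
#' @param strata Optional vector of stratum labels, one per run.
#' @return Tibble `gene_id`, `count`, `frequency` (descending), plus
#'   `count_<stratum>` columns when `strata` is given.
#' @export
#' @examples
#' selection_frequency(list(c("a", "b"), c("a"), c("a", "c"), c("b")))
selection_frequency <- function(runs, strata = NULL) {
  if (length(runs) == 0L) abort_validation("need at least one run.")
  if (!is.null(strata) && length(strata) != length(runs)) {
    abort_validation("`strata` must have one label per run.")
  }
  n <- length(runs)
  long <- tibble::tibble(
    run = rep(seq_len(n), lengths(runs)),
    gene_id = unlist(runs, use.names = FALSE)
  )
  long <- dplyr::distinct(long) # a gene counts once per run
  out <- long |>
    dplyr::count(.data$gene_id, name = "count") |>
    dplyr::mutate(frequency = round(100 * .data$count / n, 2)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$gene_id)
  if (!is.null(strata)) {
    long$stratum <- strata[long$run]
    wide <- long |>
      dplyr::count(.data$gene_id, .data$stratum) |>
      tidyr::pivot_wider(
        names_from = "stratum", values_from = "n",
        names_prefix = "count_", values_fill = 0L
      )
    out <- dplyr::left_join(out, wide, by = "gene_id")
  }
  out
}

#' Friedman comparison of methods over common blocks
#'
#' Ranks methods within each block (e.g. each holdout repetition) and
#' tests whether the methods differ, via the rank-based Friedman test with
#' the chi-squared approximation. If the test is significant at `alpha`,
#' the worst performer (lowest mean rank) is taken as the control and each
#' other method is compared to it with a paired Wilcoxon signed-rank test
#' under Holm correction; the significantly different methods are listed
#' from smallest to largest difference. A constant score matrix yields
#' statistic 0, p-value 1 and no post-hoc comparisons.
#'
#' @param scores Matrix or data frame of accuracies, one column per method
#'   and one row per block.
#' @param alpha Significance level for both stages; default 0.05.
#' @return A `friedman_result` list: `statistic`, `p_value`, `control`,
#'   `significant` (character, possibly empty), and the post-hoc table.
#' @export
friedman_compare <- function(scores, alpha = 0.05) {
  m <- as.matrix(scores)
  if (ncol(m) < 2L || nrow(m) < 2L) {
    abort_validation("need >= 2 methods (columns) and >= 2 blocks (rows).")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("method", seq_len(ncol(m)))

  ranks <- t(apply(m, 1, rank))
  mean_rank <- colMeans(ranks)

  if (all(m == m[1, 1])) {
    stat <- 0
    p <- 1
  } else {
    ft <- friedman.test(m)
    stat <- unname(ft$statistic)
    p <- ft$p.value
    if (is.nan(stat)) {
      stat <- 0
      p <- 1
    }
  }

  control <- NA_character_
  significant <- character(0)
  posthoc <- tibble::tibble(
    method = character(), p_value = double(), p_adjusted = double()
  )
  if (p < alpha) {
    control <- colnames(m)[which.min(mean_rank)]
    others <- setdiff(colnames(m), control)
    pvals <- vapply(others, function(meth) {
      d <- m[, meth] - m[, control]
      if (all(d == 0)) {
        return(1)
      }
      suppressWarnings(wilcox.test(m[, meth], m[, control], paired = TRUE)$p.value)
    }, numeric(1))
    padj <- p.adjust(pvals, method = "holm")
    posthoc <- tibble::tibble(
      method = others, p_value = unname(pvals), p_adjusted = unname(padj)
    )
    sig <- posthoc[posthoc$p_adjusted < alpha, ]
    # smallest difference (largest adjusted p) first
    significant <- sig$method[order(-sig$p_adjusted)]
  }

  structure(
    list(
      statistic = stat, p_value = p, mean_ranks = mean_rank,
      control = control, significant = significant, posthoc = posthoc,
      alpha = alpha
    ),
    class = "friedman_result"
  )
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(
    "<friedman_result> chi-squared ", signif(x$statistic, 5),
    ", p = ", format.pval(x$p_value, digits = 3), "\n",
    sep = ""
  )
  if (is.na(x$control)) {
    cat("no statistically significant results (-)\n")
  } else {
    cat(
      "control (worst): ", x$control, "; significantly different: ",
      if (length(x$significant)) paste(x$significant, collapse = ", ") else "(none)",
      "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Post-hoc table of a Friedman comparison
#'
#' @param x A `friedman_result`.
#' @param ... Unused.
#' @return The post-hoc tibble (empty when the omnibus test is not
#'   significant).
#' @export
tidy.friedman_result <- function(x, ...) {
  x$posthoc
}

#' One-row summary of a Friedman comparison
#'
#' @param x A `friedman_result`.
#' @param ... Unused.
#' @return Tibble with statistic, p-value, control and significant count.
#' @export
glance.friedman_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value, control = x$control,
    n_significant = length(x$significant)
  )
}
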