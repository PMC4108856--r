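#' Stepwise forward selection over a gene pool
#'
#' The greedy baseline: starting from the empty set, each step evaluates
#' every unused pool gene appended to the current subset on the given
#' holdout split and adds the one with the highest test accuracy, provided
#' it strictly improves on the current accuracy (by more than `min_delta`).
#' The search stops at the first step with no improvement. Ties between
#' candidates fall to the lower pool column index, so the trace is fully
#' deterministic given the split. The baseline accuracy of the empty set is
#' the test accuracy of always predicting the training majority class.
#'
#' The comparison count grows as roughly `pool size x final subset size`,
#' the usual complexity estimate for stepwise search.
#'
#' @param data The pre-selected pool (expression tibble).
#' @param spec A [classifier_spec()].
#' @param split A [split_holdout()] result.
#' @param min_delta Minimum accuracy gain to accept a candidate (default 0,
#'   i.e. any strict improvement).
#' @param max_genes Optional cap on the subset size.
#' @return An `sfs_trace`: the selection trace, final subset, baseline
#'   accuracy and the number of candidate evaluations performed.
#' @export
run_sfs <- function(data, spec, split, min_delta = 0, max_genes = Inf) {
  validate_expression(data)
  stopifnot(inherits(spec, "classifier_spec"))
  pool <- gene_ids(data)
  if (length(pool) == 0L) abort_validation("empty gene pool.")
  handle <- make_classifier(spec)
  y <- data$label

  maj <- if (sum(y[split$train] == 1L) * 2L >= length(split$train)) 1L else 0L
  baseline_acc <- mean(y[split$test] == maj)

  current <- character(0)
  current_acc <- baseline_acc
  comparison_count <- 0L
  n_failures <- 0L
  trace <- list()

  repeat {
    remaining <- setdiff(pool, current)
    if (length(remaining) == 0L || length(current) >= max_genes) break
    accs <- vapply(remaining, function(g) {
      comparison_count <<- comparison_count + 1L
      tryCatch(
        suppressWarnings(evaluate_split(data, handle, c(current, g), split)$acc),
        error = function(e) {
          n_failures <<- n_failures + 1L
          0
        }
      )
    }, numeric(1))
    best_i <- which.max(accs) # ties: first = lowest pool column index
    if (accs[[best_i]] > current_acc + min_delta) {
      current <- c(current, remaining[best_i])
      current_acc <- unname(accs[[best_i]])
      trace[[length(trace) + 1L]] <- tibble::tibble(
        step = length(current), gene_id = remaining[best_i], acc = current_acc
      )
    } else {
      break
    }
  }

  if (n_failures > 0L) {
    warn(paste0(n_failures, " candidate evaluation(s) failed; scored as accuracy 0."))
  }
  structure(
    list(
      trace = if (length(trace)) dplyr::bind_rows(trace) else
        tibble::tibble(step = integer(), gene_id = character(), acc = double()),
      subset = current, baseline_acc = baseline_acc,
      final_acc = current_acc, comparison_count = comparison_count,
      pool = pool, split = split, spec = spec
    ),
    class = "sfs_trace"
  )
}

#' @export
print.sfs_trace <- function(x, ...) {
  cat(
    "<sfs_trace> ", length(x$subset), " gene(s) selected, accuracy ",
    signif(x$final_acc, 4), " (baseline ", signif(x$baseline_acc, 4), "), ",
    x$comparison_count, " comparisons\n",
    sep = ""
  )
  invisible(x)
}

#' Step-by-step view of a stepwise selection
#'
#' @param x An `sfs_trace`.
#' @param ... Unused.
#' @return One row per accepted gene with the accuracy after its addition.
#' @export
tidy.sfs_trace <- function(x, ...) {
  x$trace
}

#' One-row summary of a stepwise selection
#'
#' @param x An `sfs_trace`.
#' @param ... Unused.
#' @return Tibble with subset size, accuracies and comparison count.
#' @export
glance.sfs_trace <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$subset), baseline_acc = x$baseline_acc,
    final_acc = x$final_acc, comparison_count = x$comparison_count,
    pool_size = length(x$pool)
  )
}

#' Comparison-count estimate for stepwise search
#'
#' The back-of-envelope complexity of stepwise forward selection:
#' `n_pool * mean_selected` candidate evaluations for a pool of `n_pool`
#' genes and a typical final subset of `mean_selected` genes (each of the
#' ~`mean_selected` steps scans ~`n_pool` candidates).
#'
#' @param n_pool Pre-selected pool size.
#' @param mean_selected Mean number of genes finally selected.
#' @return The estimated number of comparisons.
#' @export
#' @examples
#' sfs_comparison_estimate(600, 5) # ~3000
sfs_comparison_estimate <- function(n_pool, mean_selected) {
  n_pool * mean_selected
}
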