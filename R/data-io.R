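#' Validate a two-class expression table
#'
#' The canonical data object of the package is an ordinary tibble whose
#' columns are genes (numeric expression values, one row per sample) plus a
#' final `label` column of 0/1 class codes (0 = "normal", 1 = "cancer").
#' `validate_expression()` checks that shape and returns the data invisibly,
#' so it can sit inside a pipe.
#'
#' @param data A data frame of gene columns plus a `label` column.
#' @return `data`, invisibly, as a tibble.
#' @export
#' @examples
#' d <- tibble::tibble(g1 = rnorm(6), g2 = rnorm(6), label = rep(0:1, 3))
#' validate_expression(d)
validate_expression <- function(data) {
  if (!is.data.frame(data)) abort_validation("`data` must be a data frame.")
  if (!"label" %in% names(data)) {
    abort_format("`data` must contain a `label` column.")
  }
  genes <- setdiff(names(data), "label")
  if (length(genes) == 0L) abort_validation("`data` has no gene columns.")
  if (anyDuplicated(names(data))) {
    abort_validation("gene identifiers (column names) must be unique.")
  }
  lab <- data$label
  if (!all(lab %in% c(0, 1))) {
    abort_validation("`label` must contain only 0 and 1.")
  }
  if (length(unique(lab)) < 2L) {
    abort_validation("both classes (0 and 1) must be present.")
  }
  not_num <- genes[!vapply(data[genes], is.numeric, logical(1))]
  if (length(not_num)) {
    abort_validation(paste0(
      "gene columns must be numeric; offending: ",
      paste(head(not_num, 3), collapse = ", ")
    ))
  }
  invisible(tibble::as_tibble(data))
}

#' Read and write expression tables
#'
#' Delimited text with a header of gene identifiers and a final 0/1 `label`
#' column. The delimiter is taken from the file extension (`.csv` comma,
#' anything else tab) unless given explicitly.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` (default) picks it from the extension.
#' @return `read_expression()` returns a validated tibble;
#'   `write_expression()` returns `data` invisibly.
#' @export
read_expression <- function(path, delim = NULL) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    name_repair = "minimal"
  )
  if (anyDuplicated(names(data))) {
    abort_validation("duplicate gene identifiers in header.")
  }
  if (!"label" %in% names(data)) {
    abort_format("input file has no `label` column.")
  }
  validate_expression(data)
  tibble::as_tibble(data)
}

#' @param data A validated expression tibble.
#' @rdname read_expression
#' @export
write_expression <- function(data, path, delim = NULL) {
  validate_expression(data)
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(data, path, delim = delim)
  invisible(data)
}

#' Gene identifiers and class-0 proportion of an expression table
#'
#' `gene_ids()` lists the gene columns in order; `class_proportion()` is the
#' fraction of samples labelled 0, the "data proportion" conventionally
#' reported alongside two-class microarray datasets.
#'
#' @param data An expression tibble (gene columns + `label`).
#' @return A character vector / a single number.
#' @export
gene_ids <- function(data) {
  setdiff(names(data), "label")
}

#' @rdname gene_ids
#' @export
class_proportion <- function(data) {
  validate_expression(data)
  mean(data$label == 0)
}

#' Random train/test holdout split
#'
#' Draws a single random holdout split of the samples, by default 60% train
#' and 40% test. The split is plain random; `stratify = TRUE` samples within
#' each class instead. If the random draw leaves a class absent from the
#' training set, the draw is retried with a derived seed up to
#' `max_retries` times before failing.
#'
#' @param data An expression tibble.
#' @param train_fraction Fraction of samples assigned to training, in (0,1).
#'   The training size is `train_fraction * n` rounded half-up, so exact
#'   halves go to the training set.
#' @param seed Integer seed; the same seed always reproduces the same split.
#' @param stratify Sample within each class label separately (default off).
#' @param max_retries Bounded number of re-draws when a class is missing
#'   from the training rows.
#' @return An object of class `holdout_split`: a list with integer
#'   `train`, `test` and the `seed` used.
#' @export
#' @examples
#' d <- tibble::tibble(g1 = rnorm(10), label = rep(0:1, 5))
#' s <- split_holdout(d, seed = 1)
#' length(s$train)  # 6
split_holdout <- function(data, train_fraction = 0.6, seed = 1L,
                          stratify = FALSE, max_retries = 100L) {
  validate_expression(data)
  if (!is_prob(train_fraction)) {
    abort_validation("`train_fraction` must lie strictly between 0 and 1.")
  }
  n <- nrow(data)
  if (n < 5L) abort_validation("need at least 5 samples to split.")
  n_train <- as.integer(floor(train_fraction * n + 0.5))
  n_train <- max(1L, min(n - 1L, n_train))
  lab <- data$label

  draw <- function(s) {
    with_local_seed(s, {
      if (stratify) {
        tr <- integer(0)
        for (cl in c(0, 1)) {
          idx <- which(lab == cl)
          k <- as.integer(floor(train_fraction * length(idx) + 0.5))
          k <- max(1L, min(length(idx) - 1L, k))
          tr <- c(tr, sample(idx, k))
        }
        sort(tr)
      } else {
        sort(sample.int(n, n_train))
      }
    })
  }

  used <- as.integer(seed)
  for (r in 0:max_retries) {
    s <- if (r == 0L) used else derive_seed(seed, r)
    tr <- draw(s)
    if (length(unique(lab[tr])) == 2L) {
      return(structure(
        list(train = tr, test = setdiff(seq_len(n), tr), seed = s),
        class = "holdout_split"
      ))
    }
  }
  abort_validation("could not draw a split with both classes in training.")
}

#' @export
print.holdout_split <- function(x, ...) {
  cat(
    "<holdout_split> ", length(x$train), " train / ", length(x$test),
    " test (seed ", x$seed, ")\n",
    sep = ""
  )
  invisible(x)
}
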