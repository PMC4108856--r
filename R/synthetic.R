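#' Specify a synthetic two-class expression dataset
#'
#' Describes a planted-structure generative model that mimics the shape of
#' two-class microarray studies: a handful of truly class-informative genes,
#' optional blocks of redundant genes correlated with them, and a large
#' majority of pure-noise genes, over tens-to-hundreds of samples.
#'
#' Informative genes are class-conditional Gaussians with class means 0 and
#' `effect_size` (in within-class SD units, the SD being `noise_sd`). Each
#' redundant gene is built from its parent informative gene as
#' `rho * parent + sqrt(1 - rho^2) * noise`, which hits the target
#' correlation exactly in expectation. Labels are independent Bernoulli
#' draws with P(class 0) = `class0_proportion`, re-drawn if needed so that
#' each class has at least two samples.
#'
#' @param n_samples,n_genes Dataset dimensions.
#' @param n_informative Number of planted class-informative genes.
#' @param effect_size Difference of class means in within-class SD units.
#' @param n_redundant_per_informative Redundant copies planted per
#'   informative gene.
#' @param redundancy_rho Target correlation of a redundant gene with its
#'   parent, in \[0, 1).
#' @param class0_proportion Expected fraction of class-0 samples, in (0,1).
#' @param noise_sd Within-class standard deviation of every gene.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
#' @examples
#' spec <- synthetic_spec(n_samples = 72, n_genes = 500, n_informative = 5)
#' d <- generate_dataset(spec)
#' informative_genes(d)
synthetic_spec <- function(n_samples, n_genes, n_informative,
                           effect_size = 2, n_redundant_per_informative = 0L,
                           redundancy_rho = 0, class0_proportion = 0.5,
                           noise_sd = 1, seed = 1L) {
  if (!is_count(n_samples, 4L)) abort_validation("`n_samples` must be >= 4.")
  if (!is_count(n_genes)) abort_validation("`n_genes` must be a positive integer.")
  if (!is_count(n_informative, 0L)) abort_validation("`n_informative` must be >= 0.")
  if (!is_count(n_redundant_per_informative, 0L)) {
    abort_validation("`n_redundant_per_informative` must be >= 0.")
  }
  if (n_informative * (1L + n_redundant_per_informative) > n_genes) {
    abort_validation("informative + redundant genes exceed `n_genes`.")
  }
  if (!(is.numeric(redundancy_rho) && redundancy_rho >= 0 && redundancy_rho < 1)) {
    abort_validation("`redundancy_rho` must lie in [0, 1).")
  }
  if (!is_prob(class0_proportion)) {
    abort_validation("`class0_proportion` must lie strictly between 0 and 1.")
  }
  if (!(is.numeric(noise_sd) && noise_sd > 0)) {
    abort_validation("`noise_sd` must be positive.")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
      n_informative = as.integer(n_informative),
      effect_size = effect_size,
      n_redundant_per_informative = as.integer(n_redundant_per_informative),
      redundancy_rho = redundancy_rho,
      class0_proportion = class0_proportion,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a planted two-class expression dataset
#'
#' @param spec A [synthetic_spec()].
#' @return An expression tibble (gene columns + `label`) with attribute
#'   `"informative"` holding the ground-truth informative gene ids;
#'   retrieve it with [informative_genes()]. Gene columns are named
#'   `inf_*`, `red_*_*`, `noise_*` and then shuffled, so names never leak
#'   the planted position.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_samples
    # labels: Bernoulli(1 - class0_proportion) for class 1, guarded
    lab <- rbinom(n, 1L, 1 - spec$class0_proportion)
    tries <- 0L
    while ((sum(lab == 0) < 2L || sum(lab == 1) < 2L) && tries < 1000L) {
      lab <- rbinom(n, 1L, 1 - spec$class0_proportion)
      tries <- tries + 1L
    }
    if (sum(lab == 0) < 2L || sum(lab == 1) < 2L) {
      # deterministic fallback for extreme proportions at tiny n
      lab[1:2] <- 0L
      lab[3:4] <- 1L
    }

    p_inf <- spec$n_informative
    p_red <- p_inf * spec$n_redundant_per_informative
    p_noise <- spec$n_genes - p_inf - p_red

    inf <- matrix(rnorm(n * p_inf, sd = spec$noise_sd), n, p_inf)
    if (p_inf > 0) {
      shift <- spec$effect_size * spec$noise_sd
      inf <- inf + outer(as.numeric(lab == 1), rep(shift, p_inf))
    }

    red <- NULL
    if (p_red > 0) {
      rho <- spec$redundancy_rho
      red <- matrix(0, n, p_red)
      col <- 1L
      for (j in seq_len(p_inf)) {
        # mix against the standardised parent: the raw informative gene has
        # variance inflated by the class-mean shift, which would shrink the
        # realised correlation below rho
        parent <- as.vector(scale(inf[, j]))
        for (r in seq_len(spec$n_redundant_per_informative)) {
          eps <- rnorm(n)
          red[, col] <- spec$noise_sd * (rho * parent + sqrt(1 - rho^2) * eps)
          col <- col + 1L
        }
      }
    }

    noise <- if (p_noise > 0) matrix(rnorm(n * p_noise, sd = spec$noise_sd), n, p_noise) else NULL

    ids_inf <- if (p_inf > 0) sprintf("inf_%03d", seq_len(p_inf)) else character(0)
    ids_red <- if (p_red > 0) {
      sprintf(
        "red_%03d_%d",
        rep(seq_len(p_inf), each = spec$n_redundant_per_informative),
        rep(seq_len(spec$n_redundant_per_informative), times = p_inf)
      )
    } else {
      character(0)
    }
    ids_noise <- if (p_noise > 0) sprintf("noise_%05d", seq_len(p_noise)) else character(0)

    mat <- cbind(inf, red, noise)
    colnames(mat) <- c(ids_inf, ids_red, ids_noise)
    ord <- sample.int(ncol(mat))
    mat <- mat[, ord, drop = FALSE]

    out <- tibble::as_tibble(as.data.frame(mat))
    out$label <- as.integer(lab)
    attr(out, "informative") <- ids_inf
    class(out) <- c("synthetic_expr", class(out))
    out
  })
}

#' Ground-truth informative genes of a synthetic dataset
#'
#' @param data A dataset produced by [generate_dataset()].
#' @return Character vector of informative gene ids.
#' @export
informative_genes <- function(data) {
  truth <- attr(data, "informative")
  if (is.null(truth)) {
    abort_validation("`data` carries no ground-truth informative set.")
  }
  truth
}

#' Precision and recall of a selected gene set against the planted truth
#'
#' @param selected Character vector of selected gene ids (may be empty).
#' @param truth Non-empty character vector of ground-truth informative ids.
#' @return A one-row tibble with `precision` and `recall`. An empty
#'   selection scores 0 on both.
#' @export
#' @examples
#' recovery_score(c("a", "b", "x"), c("a", "b", "c", "d", "e"))
recovery_score <- function(selected, truth) {
  if (length(truth) == 0L) abort_validation("`truth` must be non-empty.")
  hits <- length(intersect(selected, truth))
  tibble::tibble(
    precision = if (length(selected) == 0L) 0 else hits / length(unique(selected)),
    recall = hits / length(unique(truth))
  )
}
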