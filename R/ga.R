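#' Genetic-algorithm configuration
#'
#' Knobs of the wrapper GA: 100 individuals, 10 elites, crossover rate 0.8,
#' mutation rate 0.2 and 200 generations by default, for a budget of at
#' most `population_size * generations` = 20,000 subset evaluations.
#' `lambda` weights the subset-size term and `beta` the mutual-information
#' redundancy term of the fitness; the default operating point is
#' `lambda = 0.4`, `beta = 0.25`.
#'
#' @param population_size Number of chromosomes per generation.
#' @param elite_count Best chromosomes carried unchanged each generation.
#' @param crossover_rate Fraction of non-elite offspring bred by scattered
#'   crossover.
#' @param mutation_rate Fraction of non-elite offspring bred by bounded
#'   mutation of a cloned parent (the complement of `crossover_rate` under
#'   the defaults); any remainder slots are filled by crossover.
#' @param generations Number of generations.
#' @param lambda Weight of the subset-size penalty `k / N`, in \[0, 1\].
#' @param beta Weight of the redundancy penalty `corr(x)`, in \[0, 1\].
#' @param seed Master seed of the run.
#' @param init_max_active Upper bound of the uniform initial subset size
#'   (small-biased initialisation; capped at the pool size).
#' @param train_fraction Wrapper holdout fraction used inside the fitness.
#' @param resample_split Draw a fresh wrapper split every generation
#'   instead of one fixed split per run.
#' @param n_bins Histogram bins for the mutual-information estimates.
#'   `NULL` (default) scales the bin count with the cube root of the
#'   number of training samples, the usual bias-variance compromise for
#'   histogram estimators: at the tens-of-samples scale of expression
#'   studies a fixed fine binning would inflate the pairwise MI of even
#'   independent genes by roughly `(bins - 1)^2 / (2 n)` nats, drowning
#'   the redundancy signal.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 100L, elite_count = 10L,
                      crossover_rate = 0.8, mutation_rate = 0.2,
                      generations = 200L, lambda = 0.4, beta = 0.25,
                      seed = 1L, init_max_active = 50L,
                      train_fraction = 0.6, resample_split = FALSE,
                      n_bins = NULL) {
  if (!is_count(population_size, 2L)) abort_validation("`population_size` must be >= 2.")
  if (!is_count(elite_count, 0L) || elite_count >= population_size) {
    abort_validation("`elite_count` must be < `population_size`.")
  }
  for (r in c(crossover_rate, mutation_rate)) {
    if (!is_prob(r, open = FALSE)) abort_validation("rates must lie in [0, 1].")
  }
  if (!is_count(generations)) abort_validation("`generations` must be >= 1.")
  for (w in c(lambda, beta)) {
    if (!is_prob(w, open = FALSE)) abort_validation("`lambda`/`beta` must lie in [0, 1].")
  }
  structure(
    list(
      population_size = as.integer(population_size),
      elite_count = as.integer(elite_count),
      crossover_rate = crossover_rate, mutation_rate = mutation_rate,
      generations = as.integer(generations),
      lambda = lambda, beta = beta, seed = as.integer(seed),
      init_max_active = as.integer(init_max_active),
      train_fraction = train_fraction,
      resample_split = isTRUE(resample_split),
      n_bins = if (!is.null(n_bins)) as.integer(n_bins)
    ),
    class = "ga_config"
  )
}

#' Wrapper fitness of a gene subset
#'
#' The scalar the GA minimises:
#' `(1 - acc) + lambda * k / N + beta * corr`, combining the test
#' misclassification rate, the relative subset size and the redundancy
#' score of [redundancy_score()]. Lower is better; among subsets of equal
#' accuracy and redundancy the smaller one wins whenever `lambda > 0`.
#'
#' @param acc Test-set accuracy in \[0, 1\].
#' @param k Active genes in the chromosome, >= 1.
#' @param N Pool size.
#' @param corr Redundancy score of the subset.
#' @param lambda,beta Penalty weights.
#' @return The fitness value.
#' @export
#' @examples
#' ga_fitness(acc = 0.95, k = 4, N = 600, corr = -0.2, lambda = 0.4, beta = 0.25)
ga_fitness <- function(acc, k, N, corr, lambda, beta) {
  if (any(k < 1L)) abort_validation("`k` must be >= 1 (empty chromosomes are never scored).")
  if (any(acc < 0 | acc > 1)) abort_validation("`acc` must lie in [0, 1].")
  (1 - acc) + lambda * k / N + beta * corr
}

#' Random initial GA population
#'
#' Each chromosome activates `k ~ Uniform{1..min(init_max_active, N)}`
#' loci chosen uniformly without replacement: active genes and their
#' number are both random, biased toward small subsets.
#'
#' @param cfg A [ga_config()]; its seed makes the draw reproducible.
#' @param N Pool size (chromosome length), >= 1.
#' @return List of `population_size` logical masks of length `N`.
#' @export
init_population <- function(cfg, N) {
  stopifnot(inherits(cfg, "ga_config"))
  if (!is_count(N)) abort_validation("`N` must be a positive integer.")
  with_local_seed(cfg$seed, init_population_impl(cfg$population_size, N, cfg$init_max_active))
}

init_population_impl <- function(pop_size, N, init_max_active) {
  kmax <- min(init_max_active, N)
  lapply(seq_len(pop_size), function(i) {
    k <- sample.int(kmax, 1L)
    mask <- logical(N)
    mask[sample.int(N, k)] <- TRUE
    mask
  })
}

#' Scattered (uniform) crossover of two chromosomes
#'
#' Every offspring bit is copied from one of the two parents by an
#' independent fair coin. An all-zero child is repaired by activating one
#' random locus drawn from the union of the parents' active loci, so no
#' empty chromosome can ever leave the operator.
#'
#' @param p1,p2 Equal-length logical masks.
#' @param seed Optional seed; `NULL` (default) uses the current RNG stream.
#' @return A logical mask.
#' @export
crossover_scattered <- function(p1, p2, seed = NULL) {
  if (length(p1) != length(p2)) abort_validation("parent masks differ in length.")
  op <- function() {
    take1 <- runif(length(p1)) < 0.5
    child <- ifelse(take1, p1, p2)
    if (!any(child)) {
      pool <- which(p1 | p2)
      child[pool[sample.int(length(pool), 1L)]] <- TRUE
    }
    child
  }
  if (is.null(seed)) op() else with_local_seed(seed, op())
}

#' Bounded multi-bit mutation
#'
#' Flips `m ~ Uniform{1..k}` distinct loci (chosen over all positions),
#' where `k` is the chromosome's number of active genes. Bounding the flip
#' count by the active size keeps late-generation subsets from inflating.
#' An emptied chromosome is repaired to a single random active locus.
#'
#' @param mask Logical mask with at least one active bit.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return The mutated logical mask.
#' @export
mutate_bounded <- function(mask, seed = NULL) {
  k <- sum(mask)
  if (k < 1L) abort_validation("cannot mutate an empty chromosome.")
  op <- function() {
    m <- sample.int(k, 1L)
    loci <- sample.int(length(mask), m)
    out <- mask
    out[loci] <- !out[loci]
    if (!any(out)) {
      out[sample.int(length(out), 1L)] <- TRUE
    }
    out
  }
  if (is.null(seed)) op() else with_local_seed(seed, op())
}

# Stochastic universal sampling: n indices drawn with probability
# proportional to `weights`, with evenly spaced pointers.
sus_sample <- function(weights, n) {
  total <- sum(weights)
  if (total <= 0) {
    return(sample.int(length(weights), n, replace = TRUE))
  }
  step <- total / n
  points <- runif(1, 0, step) + (seq_len(n) - 1L) * step
  findInterval(points, cumsum(weights)) + 1L
}

#' Breed the next GA generation
#'
#' The `elite_count` lowest-fitness chromosomes pass unchanged. Of the
#' remaining slots, a `mutation_rate` fraction are bounded-mutation
#' children (a sampled parent cloned and mutated) and the rest are
#' scattered-crossover children. Parents are drawn fitness-proportionally
#' — weight `(worst - fitness) + 1e-9` since fitness is minimised — by
#' stochastic universal sampling.
#'
#' @param population List of logical masks.
#' @param fitness Numeric vector of their fitness values (lower = better).
#' @param cfg A [ga_config()].
#' @return List of masks for the next generation (uses the current RNG
#'   stream; [run_ga()] seeds it once per run).
#' @export
select_next_generation <- function(population, fitness, cfg) {
  stopifnot(inherits(cfg, "ga_config"))
  pop_n <- length(population)
  if (length(fitness) != pop_n) abort_validation("fitness/population length mismatch.")
  elite_idx <- order(fitness)[seq_len(cfg$elite_count)]
  n_rest <- pop_n - cfg$elite_count
  n_mut <- as.integer(round(cfg$mutation_rate * n_rest))
  n_mut <- min(n_mut, n_rest)
  n_cx <- n_rest - n_mut

  finite <- fitness[is.finite(fitness)]
  worst <- if (length(finite)) max(finite) else 1
  w <- (worst - pmin(fitness, worst)) + 1e-9
  parents <- sus_sample(w, 2L * n_cx + n_mut)
  parents <- parents[sample.int(length(parents))] # decouple pointer order

  children <- vector("list", n_rest)
  for (i in seq_len(n_cx)) {
    children[[i]] <- crossover_scattered(
      population[[parents[2L * i - 1L]]], population[[parents[2L * i]]]
    )
  }
  for (i in seq_len(n_mut)) {
    children[[n_cx + i]] <- mutate_bounded(population[[parents[2L * n_cx + i]]])
  }
  c(population[elite_idx], children)
}

#' Run the GA wrapper over a pre-selected gene pool
#'
#' Evolves binary gene masks over the pool for `cfg$generations`
#' generations. Each chromosome is scored by fitting the classifier on the
#' training part of a wrapper holdout split restricted to its active genes
#' (accuracy on the test part), plus the size and redundancy penalties of
#' [ga_fitness()]; the redundancy score is computed on training rows only.
#' Identical masks are evaluated once and memoised, so the evaluation
#' counter never exceeds `population_size * generations`. A classifier
#' failure on a chromosome assigns it a worst-case fitness and is logged.
#'
#' @param data The pre-selected pool (expression tibble).
#' @param spec A [classifier_spec()] scoring candidate subsets.
#' @param cfg A [ga_config()].
#' @return A `ga_result`: best-ever chromosome and gene set, fitness
#'   components, per-generation history, and evaluation counts.
#' @export
run_ga <- function(data, spec, cfg = ga_config()) {
  validate_expression(data)
  stopifnot(inherits(spec, "classifier_spec"), inherits(cfg, "ga_config"))
  pool <- gene_ids(data)
  N <- length(pool)
  handle <- make_classifier(spec)

  split <- split_holdout(data, cfg$train_fraction, seed = derive_seed(cfg$seed, 1L))
  x_all <- as.matrix(data[pool])
  y <- data$label
  # cube-root rule unless the config pins a bin count
  n_bins <- cfg$n_bins %||% max(2L, as.integer(round(length(split$train)^(1 / 3))))
  mi_cache <- new_mi_cache(
    x_all[split$train, , drop = FALSE], y[split$train], n_bins
  )

  fit_cache <- new.env(parent = emptyenv())
  eval_count <- 0L
  n_failures <- 0L
  worst_fitness <- 1 + cfg$lambda + cfg$beta * log(max(n_bins, 2)) + 1

  score_mask <- function(mask, split) {
    key <- paste(which(mask), collapse = ",")
    hit <- fit_cache[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    idx <- which(mask)
    res <- tryCatch(
      {
        sc <- suppressWarnings(evaluate_split(data, handle, pool[idx], split))
        corr <- redundancy_score(idx, y[split$train], n_bins, cache = mi_cache)
        list(
          fitness = ga_fitness(sc$acc, length(idx), N, corr, cfg$lambda, cfg$beta),
          acc = sc$acc, corr = corr, k = length(idx), failed = FALSE
        )
      },
      error = function(e) {
        list(fitness = worst_fitness, acc = NA_real_, corr = NA_real_,
             k = length(idx), failed = TRUE, message = conditionMessage(e))
      }
    )
    eval_count <<- eval_count + 1L
    if (isTRUE(res$failed)) n_failures <<- n_failures + 1L
    fit_cache[[key]] <- res
    res
  }

  best <- NULL
  history <- vector("list", cfg$generations)

  with_local_seed(derive_seed(cfg$seed, 2L), {
    population <- init_population_impl(cfg$population_size, N, cfg$init_max_active)
    for (gen in seq_len(cfg$generations)) {
      if (cfg$resample_split && gen > 1L) {
        split <- split_holdout(
          data, cfg$train_fraction, seed = derive_seed(cfg$seed, 100L + gen)
        )
      }
      scored <- lapply(population, score_mask, split = split)
      fitness <- vapply(scored, `[[`, numeric(1), "fitness")
      gen_best <- which.min(fitness)
      if (is.null(best) || fitness[gen_best] < best$fitness) {
        best <- scored[[gen_best]]
        best$mask <- population[[gen_best]]
      }
      history[[gen]] <- tibble::tibble(
        generation = gen, best_fitness = min(fitness),
        mean_fitness = mean(fitness[is.finite(fitness)]),
        best_ever = best$fitness
      )
      if (gen < cfg$generations) {
        population <- select_next_generation(population, fitness, cfg)
      }
    }
  })

  if (n_failures > 0L) {
    warn(paste0(n_failures, " chromosome evaluation(s) failed; worst-case fitness assigned."))
  }
  structure(
    list(
      best_mask = best$mask, best_genes = pool[best$mask],
      best_fitness = best$fitness,
      components = tibble::tibble(
        acc = best$acc, k = best$k, N = N, corr = best$corr,
        misclass_term = 1 - best$acc,
        size_term = cfg$lambda * best$k / N,
        corr_term = cfg$beta * best$corr
      ),
      history = dplyr::bind_rows(history),
      n_evaluations = eval_count,
      max_evaluations = cfg$population_size * cfg$generations,
      n_failures = n_failures,
      pool = pool, split = split, config = cfg, spec = spec
    ),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  cat(
    "<ga_result> best fitness ", signif(x$best_fitness, 5), " with ",
    length(x$best_genes), " gene(s) after ", nrow(x$history),
    " generation(s); ", x$n_evaluations, "/", x$max_evaluations,
    " evaluations\n",
    sep = ""
  )
  invisible(x)
}

#' Per-gene view of a GA result
#'
#' @param x A `ga_result`.
#' @param ... Unused.
#' @return One row per pool gene with its selection indicator.
#' @export
tidy.ga_result <- function(x, ...) {
  tibble::tibble(gene_id = x$pool, selected = x$best_mask)
}

#' One-row summary of a GA run
#'
#' @param x A `ga_result`.
#' @param ... Unused.
#' @return Tibble with best fitness, its components and evaluation counts.
#' @export
glance.ga_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(best_fitness = x$best_fitness, n_genes = length(x$best_genes)),
    x$components[c("acc", "corr")],
    tibble::tibble(
      n_evaluations = x$n_evaluations, max_evaluations = x$max_evaluations,
      generations = nrow(x$history)
    )
  )
}

#' Fitness-history plot of a GA run
#'
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot of best and mean fitness per generation.
#' @export
autoplot.ga_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$history[c("generation", "best_fitness", "mean_fitness")],
    -"generation",
    names_to = "series", values_to = "fitness"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$fitness,
    colour = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "generation", y = "fitness (lower is better)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}
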