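#' Parameter grid domains for the wrapped classifiers
#'
#' The per-method parameter domains swept in the robustness analysis,
#' shipped as package data (`inst/extdata/param_grids.yaml`). Used both to
#' validate [classifier_spec()] parameters and to enumerate sweep grids.
#'
#' @return Named list of per-method parameter domains.
#' @export
default_grids <- function() {
  path <- system.file("extdata", "param_grids.yaml", package = "evoselect")
  if (path == "") abort("param_grids.yaml not found in the installed package.")
  yaml::read_yaml(path)
}

default_params <- function(method) {
  switch(method,
    LDA = list(),
    SVM = list(kernel = "linear", C = 1, degree = 3, gamma = 0.1, coef0 = 0),
    NB = list(kernel_density = 0, discretize = 0),
    CMANTEC = list(Imax = 10000, gfac = 0.05, phi = 2),
    KNN = list(k = 1, distance = "euclidean"),
    MLP = list(n_hidden = 3, alpha = 0.2, n_cycles = 50)
  )
}

#' Specify a classifier and its parameters
#'
#' A uniform description of one of the six supported classifiers: linear
#' discriminant analysis (LDA), support vector machine (SVM), naive Bayes
#' (NB), the C-MANTEC constructive network (CMANTEC), k-nearest neighbours
#' (KNN) and a multilayer perceptron (MLP). With `strict = TRUE` (default)
#' parameters must come from the declared grid domain of the method, see
#' [default_grids()].
#'
#' @param method One of `"LDA"`, `"SVM"`, `"NB"`, `"CMANTEC"`, `"KNN"`,
#'   `"MLP"`.
#' @param params Named list of method parameters; missing entries take
#'   defaults from the grid.
#' @param seed Integer seed consumed by stochastic trainers (C-MANTEC,
#'   MLP) so identical specs give identical fits.
#' @param strict Validate parameter values against the grid domain.
#' @return A `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("KNN", list(k = 3, distance = "euclidean"))
classifier_spec <- function(method, params = list(), seed = 1L, strict = TRUE) {
  methods <- c("LDA", "SVM", "NB", "CMANTEC", "KNN", "MLP")
  if (!(is.character(method) && length(method) == 1L && method %in% methods)) {
    abort_validation(paste0(
      "`method` must be one of: ", paste(methods, collapse = ", ")
    ))
  }
  full <- modifyList(default_params(method), as.list(params))
  if (strict) {
    domain <- default_grids()[[method]]
    for (nm in names(full)) {
      allowed <- domain[[nm]]
      if (is.null(allowed)) {
        abort_validation(paste0("unknown parameter `", nm, "` for ", method, "."))
      }
      v <- full[[nm]]
      ok <- if (is.numeric(v)) {
        any(abs(unlist(allowed) - v) < 1e-12)
      } else {
        v %in% unlist(allowed)
      }
      if (!ok) {
        abort_validation(paste0(
          "`", nm, "` = ", v, " is off-grid for ", method, "; allowed: ",
          paste(unlist(allowed), collapse = ", ")
        ))
      }
    }
    if (method == "NB" && full$kernel_density == 1 && full$discretize == 1) {
      abort_validation("NB with kernel_density = 1 and discretize = 1 is not supported.")
    }
  }
  structure(
    list(method = method, params = full, seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

#' @export
print.classifier_spec <- function(x, ...) {
  p <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  } else {
    "no parameters"
  }
  cat("<classifier_spec> ", x$method, " (", p, ")\n", sep = "")
  invisible(x)
}

#' Build a trainable classifier handle
#'
#' Wraps the spec into a handle with `$fit(x, y)` returning a fitted model
#' and `$predict(model, x)` returning 0/1 labels, so every selector and
#' evaluator talks to one contract. C-MANTEC routes to [train_cmantec()];
#' LDA and SVM delegate to \pkg{MASS} and \pkg{e1071}; NB, KNN and MLP are
#' implemented in-package to cover the grid variants (kernel-density /
#' discretised NB, chi-squared and cosine kNN distances, online-backprop
#' MLP with an explicit learning rate).
#'
#' @param spec A [classifier_spec()].
#' @return An `evo_classifier` handle.
#' @export
make_classifier <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  p <- spec$params
  fit <- switch(spec$method,
    LDA = function(x, y) MASS::lda(as.matrix(x), grouping = factor(y, levels = c(0, 1))),
    SVM = function(x, y) {
      sg <- scale_guarded(as.matrix(x))
      m <- e1071::svm(sg$x, factor(y, levels = c(0, 1)),
        kernel = p$kernel, cost = p$C, degree = p$degree, gamma = p$gamma,
        coef0 = p$coef0, scale = FALSE
      )
      attr(m, "evo_center") <- sg$center
      attr(m, "evo_scale") <- sg$scale
      m
    },
    NB = function(x, y) nb_fit(as.matrix(x), y, p$kernel_density, p$discretize),
    CMANTEC = function(x, y) {
      train_cmantec(
        as.matrix(x), y,
        cmantec_params(p$Imax, p$gfac, p$phi),
        seed = spec$seed
      )
    },
    KNN = function(x, y) knn_fit(as.matrix(x), y, p$k, p$distance),
    MLP = function(x, y) {
      mlp_fit(as.matrix(x), y, p$n_hidden, p$alpha, p$n_cycles, seed = spec$seed)
    }
  )
  predict_fun <- switch(spec$method,
    LDA = function(model, x) {
      as.integer(as.character(predict(model, as.matrix(x))$class))
    },
    SVM = function(model, x) {
      xs <- sweep(sweep(as.matrix(x), 2, attr(model, "evo_center")), 2,
        attr(model, "evo_scale"), "/"
      )
      as.integer(as.character(predict(model, xs)))
    },
    NB = function(model, x) nb_predict(model, as.matrix(x)),
    CMANTEC = function(model, x) predict(model, as.matrix(x)),
    KNN = function(model, x) knn_predict(model, as.matrix(x)),
    MLP = function(model, x) mlp_predict(model, as.matrix(x))
  )
  structure(list(spec = spec, fit = fit, predict = predict_fun),
    class = "evo_classifier"
  )
}

# Standardisation that tolerates constant columns (sd 0 -> 1).
scale_guarded <- function(x) {
  center <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0 | is.na(s)] <- 1
  list(x = sweep(sweep(x, 2, center), 2, s, "/"), center = center, scale = s)
}

# ---- naive Bayes (Gaussian / kernel density / discretised) ----

nb_fit <- function(x, y, kernel_density = 0, discretize = 0) {
  y <- as.integer(y)
  prior <- c(mean(y == 0), mean(y == 1))
  model <- list(prior = prior, kd = kernel_density == 1, disc = discretize == 1)
  if (model$disc) {
    # equal-frequency bins (up to 4) from training quantiles, Laplace-smoothed
    breaks <- apply(x, 2, function(v) {
      b <- unique(quantile(v, probs = c(0.25, 0.5, 0.75), names = FALSE))
      c(-Inf, b, Inf)
    }, simplify = FALSE)
    model$breaks <- breaks
    model$tables <- lapply(seq_len(ncol(x)), function(j) {
      bins <- cut(x[, j], breaks[[j]], labels = FALSE)
      nb <- length(breaks[[j]]) - 1L
      sapply(c(0L, 1L), function(cl) {
        (tabulate(bins[y == cl], nbins = nb) + 1) / (sum(y == cl) + nb)
      })
    })
  } else if (model$kd) {
    model$dens <- lapply(seq_len(ncol(x)), function(j) {
      lapply(c(0L, 1L), function(cl) {
        v <- x[y == cl, j]
        if (length(unique(v)) == 1L) {
          density(v, bw = 1e-6, n = 256) # constant feature: spike density
        } else {
          density(v, n = 256)
        }
      })
    })
  } else {
    model$mean <- rbind(colMeans(x[y == 0L, , drop = FALSE]), colMeans(x[y == 1L, , drop = FALSE]))
    sds <- rbind(
      apply(x[y == 0L, , drop = FALSE], 2, sd),
      apply(x[y == 1L, , drop = FALSE], 2, sd)
    )
    sds[sds < 1e-9 | is.na(sds)] <- 1e-9
    model$sd <- sds
  }
  structure(model, class = "evo_nb")
}

nb_predict <- function(model, x) {
  n <- nrow(x)
  ll <- matrix(log(model$prior), n, 2, byrow = TRUE)
  eps <- 1e-12
  for (j in seq_len(ncol(x))) {
    if (model$disc) {
      bins <- cut(x[, j], model$breaks[[j]], labels = FALSE)
      tab <- model$tables[[j]]
      ll <- ll + log(tab[bins, , drop = FALSE])
    } else if (model$kd) {
      for (cl in 1:2) {
        d <- model$dens[[j]][[cl]]
        f <- stats::approx(d$x, d$y, xout = x[, j], yleft = 0, yright = 0)$y
        ll[, cl] <- ll[, cl] + log(pmax(f, eps))
      }
    } else {
      for (cl in 1:2) {
        ll[, cl] <- ll[, cl] + stats::dnorm(
          x[, j], model$mean[cl, j], model$sd[cl, j], log = TRUE
        )
      }
    }
  }
  as.integer(ll[, 2] > ll[, 1])
}

# ---- k-nearest neighbours over explicit distance matrices ----

knn_fit <- function(x, y, k, distance) {
  if (!is_count(k)) abort_validation("`k` must be a positive integer.")
  distance <- match.arg(distance, c("euclidean", "chi-squared", "cosine-similarity"))
  shift <- if (distance == "chi-squared") apply(x, 2, min) else NULL
  structure(
    list(x = x, y = as.integer(y), k = as.integer(k), distance = distance, shift = shift),
    class = "evo_knn"
  )
}

knn_distances <- function(model, x) {
  tr <- model$x
  switch(model$distance,
    euclidean = {
      cross <- x %*% t(tr)
      d2 <- outer(rowSums(x^2), rowSums(tr^2), "+") - 2 * cross
      sqrt(pmax(d2, 0))
    },
    `chi-squared` = {
      # min-shift to non-negative using training minima
      a <- sweep(x, 2, model$shift)
      b <- sweep(tr, 2, model$shift)
      a[a < 0] <- 0
      t(apply(a, 1, function(r) {
        colSums((t(b) - r)^2 / (t(b) + r + 1e-12))
      }))
    },
    `cosine-similarity` = {
      nx <- sqrt(rowSums(x^2))
      ntr <- sqrt(rowSums(tr^2))
      sim <- (x %*% t(tr)) / (pmax(outer(nx, ntr), 1e-12))
      1 - sim
    }
  )
}

knn_predict <- function(model, x) {
  d <- knn_distances(model, x)
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(x))
  apply(d, 1, function(r) {
    nn <- order(r)[seq_len(model$k)] # distance ties broken by train index
    votes <- sum(model$y[nn] == 1L)
    as.integer(votes * 2L >= model$k) # even split falls to class 1
  })
}

# ---- multilayer perceptron: one sigmoid hidden layer, online backprop ----

mlp_fit <- function(x, y, n_hidden, alpha, n_cycles, seed = 1L) {
  sg <- scale_guarded(x)
  xs <- cbind(1, sg$x)
  y <- as.numeric(y)
  d <- ncol(xs)
  with_local_seed(seed, {
    W1 <- matrix(runif(n_hidden * d, -0.5, 0.5), n_hidden, d)
    w2 <- runif(n_hidden + 1L, -0.5, 0.5)
    n <- nrow(xs)
    for (cycle in seq_len(n_cycles)) {
      for (i in sample.int(n)) {
        a1 <- plogis(W1 %*% xs[i, ])
        a1b <- c(1, a1)
        out <- plogis(sum(w2 * a1b))
        err <- out - y[i]
        delta_out <- err * out * (1 - out)
        delta_hid <- (w2[-1] * delta_out) * a1 * (1 - a1)
        w2 <- w2 - alpha * delta_out * a1b
        W1 <- W1 - alpha * (delta_hid %*% t(xs[i, ]))
      }
    }
    structure(
      list(W1 = W1, w2 = w2, center = sg$center, scale = sg$scale),
      class = "evo_mlp"
    )
  })
}

mlp_predict <- function(model, x) {
  xs <- cbind(1, sweep(sweep(x, 2, model$center), 2, model$scale, "/"))
  a1 <- plogis(xs %*% t(model$W1))
  out <- plogis(cbind(1, a1) %*% model$w2)
  as.integer(out > 0.5)
}

#' Score one classifier on one holdout split
#'
#' Fits the classifier on the training rows restricted to the given gene
#' subset and scores the test rows, with class 1 ("cancer") as positive.
#' False-positive and false-negative rates are normalised by the total
#' number of test patterns, so `acc + fp_rate + fn_rate = 1` exactly and
#' `fp_rate + fn_rate <= 1` always holds.
#'
#' @param data An expression tibble.
#' @param spec A [classifier_spec()] or prebuilt [make_classifier()] handle.
#' @param genes Non-empty character vector of gene ids to use as features.
#' @param split A [split_holdout()] result.
#' @return One-row tibble: `acc`, `fp_rate`, `fn_rate`, `n_test`.
#' @export
evaluate_split <- function(data, spec, genes, split) {
  if (length(genes) == 0L) abort_validation("`genes` must be non-empty.")
  handle <- if (inherits(spec, "evo_classifier")) spec else make_classifier(spec)
  missing <- setdiff(genes, names(data))
  if (length(missing)) {
    abort_validation(paste0("unknown genes: ", paste(head(missing, 3), collapse = ", ")))
  }
  x <- as.matrix(data[genes])
  y <- data$label
  model <- handle$fit(x[split$train, , drop = FALSE], y[split$train])
  pred <- handle$predict(model, x[split$test, , drop = FALSE])
  score_predictions(pred, y[split$test])
}

# Confusion arithmetic shared by every evaluator.
score_predictions <- function(pred, truth) {
  n <- length(truth)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tibble::tibble(
    acc = (n - fp - fn) / n, fp_rate = fp / n, fn_rate = fn / n, n_test = n
  )
}
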