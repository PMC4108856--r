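#' C-MANTEC parameter set
#'
#' The three knobs of the constructive network: `Imax`, the maximum number
#' of times each hidden neuron may learn per learning cycle (also the
#' initial temperature T0 of every thermal perceptron); `gfac`, the growing
#' factor — when no eligible neuron's thermal factor reaches `gfac` the
#' current learning cycle ends and a new neuron is recruited; and `phi`,
#' the noise threshold in SD units for deleting over-learnt training
#' patterns.
#'
#' @param Imax Maximum iterations per neuron per learning cycle (>= 1).
#' @param gfac Growing factor, > 0 (grid values are well below 1).
#' @param phi Noise threshold in SD units; `Inf` disables deletion.
#' @return A `cmantec_params` list.
#' @export
cmantec_params <- function(Imax = 10000L, gfac = 0.05, phi = 2) {
  if (!is_count(Imax)) abort_validation("`Imax` must be a positive integer.")
  if (!(is.numeric(gfac) && gfac > 0)) abort_validation("`gfac` must be > 0.")
  if (!(is.numeric(phi) && !is.na(phi))) abort_validation("`phi` must be numeric.")
  structure(
    list(Imax = as.integer(Imax), gfac = gfac, phi = phi),
    class = "cmantec_params"
  )
}

#' Thermal factor of a perceptron for one input
#'
#' The plasticity of a thermal perceptron with current temperature `temp`,
#' initial temperature `t0` and net input `h = w . x`:
#' `(temp / t0) * exp(-|h| / temp)`, defined as 0 at `temp = 0` (the neuron
#' is frozen). Always in \[0, 1\]; large when the neuron is hot and the
#' pattern sits near its hyperplane.
#'
#' @param temp Current temperature, in \[0, t0\].
#' @param t0 Initial temperature, > 0.
#' @param h Net input of the neuron for the pattern.
#' @return The thermal factor.
#' @export
#' @examples
#' thermal_factor(2, 4, 2)  # 0.5 * exp(-1)
thermal_factor <- function(temp, t0, h) {
  if (t0 <= 0) abort_validation("`t0` must be positive.")
  ifelse(temp <= 0, 0, (temp / t0) * exp(-abs(h) / pmax(temp, .Machine$double.eps)))
}

#' Noise-pattern deletion mask
#'
#' Flags training patterns learnt far more often than average during the
#' learning cycle that just ended: pattern i is deleted iff
#' `NTL[i] >= mu + phi * sigma`, where `mu` and `sigma` are the mean and
#' population SD of the NTL counts. When `sigma = 0` (all counts equal)
#' nothing is deleted — otherwise every pattern would trivially qualify.
#' Setting `use_variance = TRUE` thresholds on the variance instead of the
#' SD, an alternative reading of the filter kept switchable.
#'
#' @param ntl Integer vector: times each retained pattern was learnt in the
#'   cycle.
#' @param phi Threshold in SD units.
#' @param use_variance Threshold on `mu + phi * sigma^2` instead.
#' @return Integer indices (into `ntl`) of patterns to delete.
#' @export
#' @examples
#' noise_filter_mask(c(2, 2, 2, 2, 10), phi = 2)  # 5
noise_filter_mask <- function(ntl, phi, use_variance = FALSE) {
  if (length(ntl) < 1L) abort_validation("need at least one pattern.")
  mu <- mean(ntl)
  sigma2 <- mean((ntl - mu)^2)
  if (sigma2 == 0) {
    return(integer(0))
  }
  spread <- if (use_variance) sigma2 else sqrt(sigma2)
  which(ntl >= mu + phi * spread)
}

#' Train a C-MANTEC constructive network
#'
#' Grows a single hidden layer of thermal perceptrons whose signs feed a
#' majority gate. Training presents randomly chosen misclassified patterns;
#' among the hidden neurons voting against the desired output, the one with
#' the largest thermal factor learns the pattern (`delta_w = Tfac * t * x`
#' with internal target `t` in {-1, +1}), its temperature dropping by 1
#' per pattern learnt. When no wrong-voting neuron's thermal factor reaches
#' `gfac` the learning cycle ends: the noise filter deletes over-learnt
#' patterns, a fresh neuron initialised to learn the triggering pattern is
#' added, and temperatures and learn counts reset. Training stops when the
#' majority gate classifies every retained pattern correctly.
#'
#' Inputs are standardised to zero mean / unit variance using training
#' statistics (stored for prediction); the bias input is fixed at 1.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y 0/1 labels, both classes present.
#' @param params A [cmantec_params()].
#' @param seed Integer seed for pattern presentation and initial weights.
#' @param max_neurons Growth guard: exceeding it aborts with diagnostics.
#' @param tie_class Network output when the hidden vote is split evenly
#'   (even neuron count); default class 1.
#' @return A `cmantec_net` with weights, architecture and an audit log of
#'   deletions.
#' @export
train_cmantec <- function(x, y, params = cmantec_params(), seed = 1L,
                          max_neurons = 50L, tie_class = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) abort_validation("row/label length mismatch.")
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L) {
    abort_validation("labels must contain both classes 0 and 1.")
  }
  stopifnot(inherits(params, "cmantec_params"))

  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  xa <- cbind(1, xs) # bias first
  n <- nrow(xa)
  d <- ncol(xa)
  target <- ifelse(y == 1L, 1, -1)
  tie_sign <- if (tie_class == 1L) 1 else -1
  t0 <- params$Imax

  with_local_seed(seed, {
    W <- matrix(rnorm(d, sd = 0.01), nrow = 1L) # neurons x (d)
    temps <- t0
    retained <- seq_len(n)
    ntl <- rep(0L, n)
    H <- xa %*% t(W) # n x neurons, updated incrementally
    deletions <- list()
    n_cycles <- 1L

    net_sign <- function() {
      votes <- rowSums(sign(H[retained, , drop = FALSE]) + 0) # sign(0) = 0
      ifelse(votes == 0, tie_sign, sign(votes))
    }

    repeat {
      wrong_pos <- which(net_sign() != target[retained])
      if (length(wrong_pos) == 0L) break
      p <- retained[wrong_pos[sample.int(length(wrong_pos), 1L)]]
      tgt <- target[p]
      h_p <- H[p, ]
      wrong_neurons <- which(sign(h_p) != tgt)
      if (length(wrong_neurons) == 0L) {
        # majority tie lost on tie rule: treat all neurons as eligible
        wrong_neurons <- seq_along(h_p)
      }
      tf <- thermal_factor(temps[wrong_neurons], t0, h_p[wrong_neurons])
      best <- wrong_neurons[which.max(tf)]
      if (max(tf) >= params$gfac) {
        W[best, ] <- W[best, ] + max(tf) * tgt * xa[p, ]
        H[, best] <- xa %*% W[best, ]
        temps[best] <- max(0, temps[best] - 1)
        ntl[p] <- ntl[p] + 1L
      } else {
        # learning cycle ends: filter noise, recruit a neuron
        del_local <- noise_filter_mask(ntl[retained], params$phi)
        if (length(del_local)) {
          cyc_ntl <- ntl[retained]
          mu <- mean(cyc_ntl)
          sigma <- sqrt(mean((cyc_ntl - mu)^2))
          deletions[[length(deletions) + 1L]] <- tibble::tibble(
            cycle = n_cycles, pattern = retained[del_local],
            ntl = cyc_ntl[del_local], mu = mu, sigma = sigma,
            phi = params$phi
          )
          retained <- retained[-del_local]
          if (length(unique(y[retained])) < 2L || length(retained) < 2L) {
            break # degenerate residue; stop growing
          }
        }
        if (nrow(W) >= max_neurons) {
          abort(paste0(
            "C-MANTEC failed to converge within ", max_neurons,
            " hidden neurons (", length(retained), " patterns retained); ",
            "raise `max_neurons` or revisit Imax/gfac."
          ), class = "evoselect_convergence_error")
        }
        W <- rbind(W, tgt * xa[p, ])
        H <- cbind(H, xa %*% W[nrow(W), ])
        temps <- rep(t0, nrow(W))
        ntl <- rep(0L, n)
        n_cycles <- n_cycles + 1L
      }
    }

    structure(
      list(
        weights = W, center = center, scale = scale_,
        params = params, tie_class = as.integer(tie_class),
        n_neurons = nrow(W), n_cycles = n_cycles,
        retained = retained,
        deletions = if (length(deletions)) dplyr::bind_rows(deletions) else
          tibble::tibble(
            cycle = integer(), pattern = integer(), ntl = integer(),
            mu = double(), sigma = double(), phi = double()
          ),
        seed = as.integer(seed)
      ),
      class = "cmantec_net"
    )
  })
}

#' Predict class labels from a C-MANTEC network
#'
#' Each hidden thermal perceptron votes with the sign of its net input and
#' the majority decides; an even split falls to the configured tie class.
#'
#' @param object A `cmantec_net`.
#' @param newdata Feature matrix with the training feature dimension.
#' @param ... Unused.
#' @return Integer 0/1 labels.
#' @export
predict.cmantec_net <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$center)) {
    abort_validation("feature dimension mismatch with the trained network.")
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  H <- cbind(1, xs) %*% t(object$weights)
  votes <- rowSums(sign(H))
  tie_sign <- if (object$tie_class == 1L) 1 else -1
  as.integer(ifelse(votes == 0, tie_sign, sign(votes)) > 0)
}

#' @export
print.cmantec_net <- function(x, ...) {
  cat(
    "<cmantec_net> ", x$n_neurons, " hidden neuron(s), ",
    x$n_cycles, " learning cycle(s), ",
    nrow(x$deletions), " pattern deletion(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy per-neuron summary of a C-MANTEC network
#'
#' @param x A `cmantec_net`.
#' @param ... Unused.
#' @return One row per hidden neuron: weight norm and bias.
#' @export
tidy.cmantec_net <- function(x, ...) {
  tibble::tibble(
    neuron = seq_len(x$n_neurons),
    bias = x$weights[, 1],
    weight_norm = sqrt(rowSums(x$weights[, -1, drop = FALSE]^2))
  )
}

#' One-row summary of a C-MANTEC fit
#'
#' @param x A `cmantec_net`.
#' @param ... Unused.
#' @return Tibble with neuron count, cycles, deletions and parameters.
#' @export
glance.cmantec_net <- function(x, ...) {
  tibble::tibble(
    n_neurons = x$n_neurons, n_cycles = x$n_cycles,
    n_deleted = nrow(x$deletions),
    Imax = x$params$Imax, gfac = x$params$gfac, phi = x$params$phi
  )
}
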