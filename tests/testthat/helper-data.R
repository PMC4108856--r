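# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# Tiny labelled expression tibble with explicit values.
tiny_dataset <- function(n = 10L, p = 3L, seed = 1L) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(d) <- paste0("g", seq_len(p))
  d$label <- rep_len(c(0L, 1L), n)
  tibble::as_tibble(d)
}

# Planted dataset wrapper with package defaults suitable for fast tests.
planted_dataset <- function(n_samples = 100L, n_genes = 200L,
                            n_informative = 5L, effect_size = 2,
                            seed = 11L, ...) {
  generate_dataset(synthetic_spec(
    n_samples = n_samples, n_genes = n_genes, n_informative = n_informative,
    effect_size = effect_size, seed = seed, ...
  ))
}

# A dataset one of whose genes equals the class label: any reasonable
# classifier is a perfect oracle on it.
oracle_dataset <- function(n = 40L, seed = 5L) {
  set.seed(seed)
  lab <- rep_len(c(0L, 1L), n)
  tibble::tibble(
    perfect = as.numeric(lab),
    noise1 = rnorm(n), noise2 = rnorm(n),
    label = lab
  )
}

# Classifier handle with arbitrary prediction behaviour, for confusion
# arithmetic tests (bypasses training entirely).
constant_handle <- function(value) {
  structure(
    list(
      spec = list(method = "CONST"),
      fit = function(x, y) NULL,
      predict = function(model, x) rep(as.integer(value), nrow(x))
    ),
    class = "evo_classifier"
  )
}

# Handle that memorises the full data's labels by row signature; with a
# label-equal gene included it acts as the true-label oracle.
identity_handle <- function() {
  structure(
    list(
      spec = list(method = "ORACLE"),
      fit = function(x, y) list(x = x, y = y),
      predict = function(model, x) as.integer(x[, 1] > 0.5)
    ),
    class = "evo_classifier"
  )
}

# XOR-structured dataset: jittered corner prototypes whose pair (xa, xb)
# determines the label while each alone carries no signal; remaining genes
# are noise.
xor_dataset <- function(n = 80L, n_noise = 4L, seed = 14L) {
  set.seed(seed)
  a <- rep(c(0, 0, 1, 1), n / 4)
  b <- rep(c(0, 1, 0, 1), n / 4)
  d <- tibble::tibble(
    xa = a + rnorm(n, sd = 0.05),
    xb = b + rnorm(n, sd = 0.05)
  )
  for (j in seq_len(n_noise)) d[[paste0("n", j)]] <- rnorm(n)
  d$label <- as.integer(xor(a == 1, b == 1))
  d
}
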