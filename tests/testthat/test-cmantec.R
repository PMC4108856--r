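test_that("thermal factor follows its closed form", {
  expect_equal(thermal_factor(4, 4, 0), 1)
  expect_equal(thermal_factor(0, 4, 3), 0)
  expect_equal(thermal_factor(2, 4, 2), 0.5 * exp(-1), tolerance = 1e-12)
  # always within [0, 1]
  for (temp in c(0, 1, 5, 10)) {
    for (h in c(-3, 0, 2, 50)) {
      tf <- thermal_factor(temp, 10, h)
      expect_gte(tf, 0)
      expect_lte(tf, 1)
    }
  }
})

test_that("noise filter deletes exactly the over-learnt patterns", {
  # mu = 3.6, population SD = 3.2: threshold at phi = 2 is 10.0
  expect_identical(noise_filter_mask(c(2, 2, 2, 2, 10), phi = 2), 5L)
  # phi = 0.5: threshold 5.2, same single deletion
  expect_identical(noise_filter_mask(c(2, 2, 2, 2, 10), phi = 0.5), 5L)
  # equal counts: sigma = 0 disables deletion
  expect_identical(noise_filter_mask(rep(4, 6), phi = 1), integer(0))
  # variance reading is switchable: threshold 3.6 + 2 * 10.24 > 10
  expect_identical(
    noise_filter_mask(c(2, 2, 2, 2, 10), phi = 2, use_variance = TRUE),
    integer(0)
  )
})

test_that("separable blobs are learnt by a single neuron", {
  set.seed(61)
  x <- rbind(
    matrix(rnorm(100, mean = 0), 50, 2),
    matrix(rnorm(100, mean = 5), 50, 2)
  )
  y <- rep(0:1, each = 50)
  net <- train_cmantec(x, y, cmantec_params(1000, 0.05, 1e6), seed = 2)
  expect_equal(net$n_neurons, 1)
  expect_equal(mean(predict(net, x) == y), 1)
  expect_equal(nrow(net$deletions), 0)
})

test_that("XOR needs more than one neuron and reaches zero training error", {
  set.seed(67)
  proto <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  x <- proto[rep(1:4, each = 10), ]
  y <- rep(c(0L, 1L, 1L, 0L), each = 10)
  net <- train_cmantec(x, y, cmantec_params(1000, 0.05, 1e6), seed = 3)
  expect_gt(net$n_neurons, 1)
  expect_lte(net$n_neurons, 7)
  expect_equal(mean(predict(net, x) == y), 1)
  # the four prototypes themselves classify correctly
  expect_equal(predict(net, proto), c(0L, 1L, 1L, 0L))
})

test_that("training terminates with perfect accuracy on retained patterns", {
  set.seed(71)
  x <- matrix(rnorm(120 * 3), 120, 3)
  y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(120, sd = 0.4) > 0)
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  net <- train_cmantec(x, y, cmantec_params(1000, 0.1, 2), seed = 4)
  pred <- predict(net, x[net$retained, , drop = FALSE])
  expect_equal(mean(pred == y[net$retained]), 1)

  # every logged deletion satisfied the threshold at deletion time
  if (nrow(net$deletions) > 0) {
    expect_true(all(
      net$deletions$ntl >= net$deletions$mu + net$deletions$phi * net$deletions$sigma
    ))
    expect_true(all(net$deletions$sigma > 0))
  }

  # determinism: same data, params, seed -> same network
  net2 <- train_cmantec(x, y, cmantec_params(1000, 0.1, 2), seed = 4)
  expect_identical(net$weights, net2$weights)
  expect_identical(net$deletions, net2$deletions)
})

test_that("an infinite phi never deletes patterns", {
  set.seed(73)
  x <- matrix(rnorm(60 * 2), 60, 2)
  y <- as.integer(x[, 1] + rnorm(60, sd = 0.8) > 0)
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  net <- train_cmantec(x, y, cmantec_params(1000, 0.1, Inf), seed = 5, max_neurons = 80)
  expect_equal(nrow(net$deletions), 0)
  expect_length(net$retained, 60)
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(train_cmantec(x, rep(1L, 10), cmantec_params(), seed = 1),
    class = "evoselect_validation_error"
  )
  expect_error(cmantec_params(Imax = 0), class = "evoselect_validation_error")
  expect_error(cmantec_params(gfac = -1), class = "evoselect_validation_error")
})

test_that("the majority gate votes as constructed", {
  # hand-built network: 3 neurons with fixed signs for a probe input
  fake <- structure(
    list(
      weights = rbind(c(0, 1), c(0, 1), c(0, -1)), # bias, one feature
      center = 0, scale = 1, tie_class = 1L,
      params = cmantec_params(), n_neurons = 3L, n_cycles = 1L,
      retained = 1L,
      deletions = tibble::tibble(), seed = 1L
    ),
    class = "cmantec_net"
  )
  # x = +1 -> votes (+, +, -) -> class 1; x = -1 -> votes (-, -, +) -> 0
  expect_identical(predict(fake, matrix(c(1, -1), 2, 1)), c(1L, 0L))

  # single-neuron network: output is that neuron's sign
  solo <- fake
  solo$weights <- rbind(c(0, 1))
  solo$n_neurons <- 1L
  expect_identical(predict(solo, matrix(c(2, -2), 2, 1)), c(1L, 0L))

  # two-neuron tie falls to the configured class
  tie <- fake
  tie$weights <- rbind(c(0, 1), c(0, -1))
  tie$n_neurons <- 2L
  expect_identical(predict(tie, matrix(1, 1, 1)), 1L)
  tie$tie_class <- 0L
  expect_identical(predict(tie, matrix(1, 1, 1)), 0L)

  expect_error(predict(fake, matrix(1, 1, 3)), class = "evoselect_validation_error")
})
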