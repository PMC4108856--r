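test_that("fitness combines its three terms exactly", {
  expect_equal(ga_fitness(1, 3, 10, 0, 0, 0), 0)
  expect_equal(
    ga_fitness(0.95, 4, 600, -0.2, 0.4, 0.25),
    0.05 + 0.4 * 4 / 600 + 0.25 * (-0.2),
    tolerance = 1e-12
  )
  # smaller subsets preferred at equal accuracy and redundancy
  expect_lt(
    ga_fitness(0.9, 5, 100, -0.1, 0.4, 0.25),
    ga_fitness(0.9, 10, 100, -0.1, 0.4, 0.25)
  )
  expect_error(ga_fitness(0.9, 0, 10, 0, 0.4, 0.25),
    class = "evoselect_validation_error"
  )
})

test_that("config guards its domains", {
  expect_error(ga_config(elite_count = 100, population_size = 100),
    class = "evoselect_validation_error"
  )
  expect_error(ga_config(lambda = 2), class = "evoselect_validation_error")
  cfg <- ga_config()
  expect_equal(cfg$population_size * cfg$generations, 20000)
})

test_that("initial population has the documented size distribution", {
  cfg <- ga_config(seed = 5)
  pop <- init_population(cfg, N = 1)
  expect_true(all(vapply(pop, sum, numeric(1)) == 1))

  expect_identical(init_population(cfg, 40), init_population(cfg, 40))

  # k ~ Uniform{1..min(50, N)}: chi-squared goodness of fit at N = 20
  cfg2 <- ga_config(population_size = 100, seed = 9)
  ks <- unlist(lapply(1:100, function(i) {
    vapply(
      init_population(ga_config(population_size = 100, seed = i), 20),
      sum, numeric(1)
    )
  }))
  counts <- tabulate(ks, nbins = 20)
  expect_gt(chisq.test(counts)$p.value, 0.001)
  expect_true(all(ks >= 1 & ks <= 20))
})

test_that("scattered crossover mixes bits fairly and repairs empties", {
  p1 <- c(TRUE, TRUE, FALSE, FALSE)
  p2 <- c(FALSE, FALSE, TRUE, TRUE)
  expect_identical(crossover_scattered(p1, p1, seed = 1), p1)

  set.seed(11)
  kids <- replicate(4000, crossover_scattered(p1, p2), simplify = FALSE)
  # every child bit comes from one of the parents, never empty
  for (child in kids[1:50]) {
    expect_true(all(child == p1 | child == p2))
    expect_gte(sum(child), 1)
  }
  match1 <- rowMeans(vapply(kids, function(ch) ch == p1, logical(4)))
  expect_true(all(abs(match1 - 0.5) < 0.05))

  # complementary single-bit parents: child is empty half the time before
  # repair; repair must leave exactly one active bit from the union
  q1 <- c(TRUE, FALSE)
  q2 <- c(FALSE, TRUE)
  set.seed(13)
  for (i in 1:200) {
    child <- crossover_scattered(q1, q2)
    expect_gte(sum(child), 1)
  }
})

test_that("bounded mutation flips between 1 and k bits", {
  m1 <- c(TRUE, rep(FALSE, 9))
  set.seed(17)
  for (i in 1:100) expect_gte(sum(mutate_bounded(m1)), 1)
  # k = 1: exactly one bit flips; hitting the active bit triggers repair,
  # which can move the bit (2 changes) or restore it (0 changes)
  flips <- replicate(300, sum(xor(mutate_bounded(m1), m1)))
  expect_true(all(flips <= 2))
  expect_gt(mean(flips == 1), 0.75)

  # m uniform on {1..3} for k = 3
  m3 <- c(TRUE, TRUE, TRUE, rep(FALSE, 27))
  set.seed(19)
  ms <- replicate(3000, {
    out <- mutate_bounded(m3)
    sum(xor(out, m3))
  })
  # repair can perturb counts only when the chromosome empties, which
  # requires flipping exactly the three active bits - rare at N = 30
  freq <- tabulate(ms, nbins = 3) / length(ms)
  expect_true(all(abs(freq - 1 / 3) < 0.05))
})

test_that("generation breeding follows the elite/crossover/mutation split", {
  cfg <- ga_config(seed = 23)
  N <- 30
  set.seed(23)
  pop <- init_population(cfg, N)
  fitness <- seq(0.01, 1, length.out = 100)
  nxt <- select_next_generation(pop, fitness, cfg)
  expect_length(nxt, 100)
  # the 10 best pass unchanged
  for (i in 1:10) expect_identical(nxt[[i]], pop[[i]])

  # a vastly better chromosome is always carried as an elite
  fitness2 <- rep(0.9, 100)
  fitness2[57] <- 0.001
  nxt2 <- select_next_generation(pop, fitness2, cfg)
  expect_true(any(vapply(nxt2[1:10], identical, logical(1), pop[[57]])))
})

test_that("GA respects its evaluation budget and monotone best fitness", {
  d <- planted_dataset(n_samples = 60, n_genes = 30, n_informative = 3, seed = 127)
  spec <- classifier_spec("KNN", list(k = 1), seed = 3)
  for (s in 1:20) {
    fit <- run_ga(d, spec, ga_config(
      generations = 6, seed = s, init_max_active = 10
    ))
    expect_lte(fit$n_evaluations, fit$max_evaluations)
    expect_equal(fit$max_evaluations, 600)
    # elitism: best-ever trace is non-increasing
    expect_true(all(diff(fit$history$best_ever) <= 1e-12))
    # component decomposition re-sums to the stored fitness
    comp <- fit$components
    expect_equal(
      comp$misclass_term + comp$size_term + comp$corr_term,
      fit$best_fitness,
      tolerance = 1e-12
    )
    expect_gte(length(fit$best_genes), 1)
  }
})

test_that("a single perfectly predictive gene pool is selected outright", {
  od <- oracle_dataset(n = 40)
  d <- od[c("perfect", "label")]
  fit <- run_ga(
    d, classifier_spec("KNN", list(k = 1)),
    ga_config(population_size = 10, elite_count = 2, generations = 2, seed = 1)
  )
  expect_identical(fit$best_genes, "perfect")
  expect_equal(fit$components$acc, 1)
})

test_that("GA runs are reproducible from the config seed", {
  d <- planted_dataset(n_samples = 50, n_genes = 25, n_informative = 3, seed = 131)
  spec <- classifier_spec("KNN", list(k = 1), seed = 3)
  cfg <- ga_config(generations = 4, seed = 99, population_size = 30, elite_count = 3)
  a <- run_ga(d, spec, cfg)
  b <- run_ga(d, spec, cfg)
  expect_identical(a$best_genes, b$best_genes)
  expect_identical(a$history, b$history)
})

test_that("tidy/glance/autoplot expose the GA result", {
  d <- planted_dataset(n_samples = 50, n_genes = 20, n_informative = 2, seed = 137)
  fit <- run_ga(
    d, classifier_spec("KNN", list(k = 1)),
    ga_config(population_size = 20, elite_count = 2, generations = 3, seed = 7)
  )
  td <- tidy(fit)
  expect_equal(nrow(td), 20)
  expect_setequal(td$gene_id[td$selected], fit$best_genes)
  g <- glance(fit)
  expect_equal(g$n_genes, length(fit$best_genes))
  expect_s3_class(autoplot(fit), "ggplot")
})
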