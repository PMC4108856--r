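test_that("repeated holdout reports per-repetition identities", {
  od <- oracle_dataset(n = 60)
  rr <- repeated_holdout(
    od, classifier_spec("KNN", list(k = 1)),
    genes = "perfect", n_reps = 8, base_seed = 3
  )
  s <- tidy(rr)
  expect_equal(nrow(s), 8)
  expect_true(all(abs(s$acc + s$fp_rate + s$fn_rate - 1) < 1e-12))
  g <- glance(rr)
  expect_equal(g$mean_acc, 1)
  expect_equal(g$std_acc, 0)
  expect_equal(g$mean_fp, 0)
  expect_equal(g$mean_fn, 0)

  # determinism across calls
  rr2 <- repeated_holdout(
    od, classifier_spec("KNN", list(k = 1)),
    genes = "perfect", n_reps = 8, base_seed = 3
  )
  expect_identical(rr$scores, rr2$scores)
})

test_that("a per-repetition selector is re-run and recorded", {
  d <- planted_dataset(n_samples = 60, n_genes = 20, n_informative = 3, seed = 157)
  calls <- 0L
  rr <- repeated_holdout(
    d, classifier_spec("KNN", list(k = 1)),
    selector = function(data, split, seed) {
      calls <<- calls + 1L
      gene_ids(data)[(seed %% 5) + 1:2]
    },
    n_reps = 5, base_seed = 9
  )
  expect_equal(calls, 5L)
  expect_equal(lengths(rr$scores$genes), rep(2L, 5))
})

test_that("parameter sweeps summarise compactness and distance", {
  od <- oracle_dataset(n = 50)
  sw <- sweep_parameters(
    od, "KNN",
    genes = "perfect",
    grid = list(k = c(1, 3, 5), distance = "euclidean"),
    n_reps = 4, base_seed = 11
  )
  expect_equal(nrow(sw$points), 3)
  # all configurations perfect: compactness and distance collapse to 0
  expect_equal(sw$compactness, 0)
  expect_equal(sw$distance, 0)
  expect_true(all(sw$points$mean_fp + sw$points$mean_fn <= 1 + 1e-12))

  # distance recomputes from the mean point of the cloud
  d <- planted_dataset(n_samples = 60, n_genes = 15, n_informative = 2, seed = 163)
  genes <- head(rank_genes(d)$gene_id, 2)
  sw2 <- sweep_parameters(
    d, "KNN",
    genes = genes,
    grid = list(k = c(1, 7), distance = c("euclidean", "cosine-similarity")),
    n_reps = 3, base_seed = 13
  )
  expect_equal(nrow(sw2$points), 4)
  expect_equal(
    sw2$distance,
    sqrt(mean(sw2$points$mean_fp)^2 + mean(sw2$points$mean_fn)^2),
    tolerance = 1e-12
  )
  expect_true(all(sw2$points$mean_fp + sw2$points$mean_fn <= 1 + 1e-12))
  expect_s3_class(autoplot(sw2), "ggplot")
})

test_that("C-MANTEC's configuration cloud is at least as compact as kNN's", {
  d <- planted_dataset(
    n_samples = 70, n_genes = 30, n_informative = 3,
    effect_size = 1.2, seed = 167
  )
  genes <- head(rank_genes(d)$gene_id, 4)
  sw_cm <- sweep_parameters(
    d, "CMANTEC",
    genes = genes,
    grid = list(Imax = 1000, gfac = c(0.01, 0.1, 0.3), phi = c(1, 2, 4)),
    n_reps = 4, base_seed = 17
  )
  sw_knn <- sweep_parameters(
    d, "KNN",
    genes = genes,
    grid = list(
      k = c(1, 4, 7, 10),
      distance = c("euclidean", "chi-squared", "cosine-similarity")
    ),
    n_reps = 4, base_seed = 17
  )
  expect_lte(sw_cm$compactness, sw_knn$compactness)
})

test_that("selection frequencies count once per run and recombine", {
  runs <- list(c("a", "b"), "a", c("a", "c"), "b", c("a", "a"))
  freq <- selection_frequency(runs)
  expect_equal(freq$frequency[freq$gene_id == "a"], 80)
  expect_equal(freq$frequency[freq$gene_id == "b"], 40)
  expect_true(all(freq$frequency <= 100))

  # 25 of 50 runs -> 50.00
  half <- selection_frequency(c(
    replicate(25, "g", simplify = FALSE),
    replicate(25, "other", simplify = FALSE)
  ))
  expect_equal(half$frequency[half$gene_id == "g"], 50)

  # 299 of 300 pooled runs -> 99.67
  pooled <- selection_frequency(c(
    replicate(299, "top", simplify = FALSE),
    list("rest")
  ))
  expect_equal(pooled$frequency[pooled$gene_id == "top"], 99.67)

  # stratified counts sum back to the pooled count
  strata <- c("LDA", "LDA", "SVM", "SVM", "KNN")
  sf <- selection_frequency(runs, strata = strata)
  strat_cols <- grep("^count_", names(sf), value = TRUE)
  expect_equal(rowSums(sf[strat_cols]), sf$count)
})

test_that("Friedman comparison matches the hand-computed statistic", {
  # strict ordering in every block: ranks 1/2/3 -> chi-squared = 8
  m <- cbind(a = c(1, 2, 1, 2), b = c(2, 3, 3, 4), c = c(5, 6, 7, 8))
  res <- friedman_compare(m)
  expect_equal(res$statistic, 8, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(8, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_identical(res$control, "a")

  # identical columns: statistic 0, p 1, nothing significant
  m0 <- matrix(1, 4, 3, dimnames = list(NULL, c("x", "y", "z")))
  res0 <- friedman_compare(m0)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_identical(res0$control, NA_character_)
  expect_length(res0$significant, 0)

  # non-significant outcome marks no control ("-")
  set.seed(19)
  mn <- cbind(p = rnorm(6), q = rnorm(6))
  resn <- friedman_compare(mn)
  if (resn$p_value >= 0.05) {
    expect_identical(resn$control, NA_character_)
    expect_length(resn$significant, 0)
  }

  # rank-based: any within-block monotone transformation leaves it alone
  res_t <- friedman_compare(exp(m))
  expect_equal(res_t$statistic, res$statistic)

  expect_error(friedman_compare(m[, 1, drop = FALSE]),
    class = "evoselect_validation_error"
  )
})

test_that("a clear ordering with enough blocks yields significant post-hocs", {
  set.seed(23)
  n <- 30
  m <- cbind(
    worst = rnorm(n, 0.7, 0.02),
    mid = rnorm(n, 0.8, 0.02),
    best = rnorm(n, 0.9, 0.02)
  )
  res <- friedman_compare(m)
  expect_lt(res$p_value, 0.05)
  expect_identical(res$control, "worst")
  expect_true(all(c("mid", "best") %in% res$significant))
  expect_equal(nrow(tidy(res)), 2)
})
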