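test_that("classifier specs validate against the declared grids", {
  # a published grid point must be accepted
  expect_s3_class(
    classifier_spec("SVM", list(
      kernel = "polynomial", C = 15, degree = 1, gamma = 0.6, coef0 = 0
    )),
    "classifier_spec"
  )
  expect_error(classifier_spec("KNN", list(k = 0)),
    class = "evoselect_validation_error"
  )
  expect_error(classifier_spec("KNN", list(k = 25)),
    class = "evoselect_validation_error"
  )
  expect_error(
    classifier_spec("NB", list(kernel_density = 1, discretize = 1)),
    class = "evoselect_validation_error"
  )
  expect_error(classifier_spec("RF"), class = "evoselect_validation_error")
  # off-grid values allowed with strict = FALSE
  expect_s3_class(classifier_spec("KNN", list(k = 25), strict = FALSE), "classifier_spec")

  grids <- default_grids()
  expect_setequal(
    names(grids), c("LDA", "SVM", "NB", "CMANTEC", "KNN", "MLP")
  )
  expect_length(grids$CMANTEC$phi, 11)
})

test_that("1-NN memorises its training data", {
  d <- planted_dataset(n_samples = 40, n_genes = 10, seed = 83)
  handle <- make_classifier(classifier_spec("KNN", list(k = 1)))
  x <- as.matrix(d[gene_ids(d)])
  model <- handle$fit(x, d$label)
  expect_equal(handle$predict(model, x), d$label)
})

test_that("all six classifiers satisfy the fit/predict contract", {
  d <- planted_dataset(n_samples = 60, n_genes = 20, seed = 89)
  split <- split_holdout(d, seed = 1)
  genes <- head(rank_genes(d)$gene_id, 4)
  for (m in c("LDA", "SVM", "NB", "CMANTEC", "KNN", "MLP")) {
    sc <- evaluate_split(d, classifier_spec(m, seed = 7), genes, split)
    expect_equal(sc$acc + sc$fp_rate + sc$fn_rate, 1, tolerance = 1e-12)
    expect_gte(sc$acc, 0)
    expect_lte(sc$acc, 1)
    expect_equal(sc$n_test, length(split$test))
    # planted effect-2 genes should support better-than-chance accuracy
    expect_gt(sc$acc, 0.6)
  }
})

test_that("NB variants fit and differ where they should", {
  d <- planted_dataset(n_samples = 80, n_genes = 10, seed = 97)
  split <- split_holdout(d, seed = 2)
  genes <- head(rank_genes(d)$gene_id, 3)
  gauss <- evaluate_split(d, classifier_spec("NB"), genes, split)
  kde <- evaluate_split(
    d, classifier_spec("NB", list(kernel_density = 1)), genes, split
  )
  disc <- evaluate_split(
    d, classifier_spec("NB", list(discretize = 1)), genes, split
  )
  for (sc in list(gauss, kde, disc)) {
    expect_equal(sc$acc + sc$fp_rate + sc$fn_rate, 1, tolerance = 1e-12)
    expect_gt(sc$acc, 0.6)
  }
})

test_that("Gaussian NB agrees with the e1071 reference", {
  set.seed(101)
  x <- matrix(rnorm(200), 50, 4)
  y <- rep_len(c(0L, 1L), 50)
  x[y == 1, 1] <- x[y == 1, 1] + 1.5
  handle <- make_classifier(classifier_spec("NB"))
  mine <- handle$predict(handle$fit(x, y), x)
  ref <- e1071::naiveBayes(x, factor(y, levels = c(0, 1)))
  theirs <- as.integer(as.character(predict(ref, x)))
  expect_equal(mine, theirs)
})

test_that("Euclidean kNN agrees with the class::knn reference", {
  set.seed(103)
  xtr <- matrix(rnorm(120), 30, 4)
  ytr <- rep_len(c(0L, 1L), 30)
  xte <- matrix(rnorm(60), 15, 4)
  for (k in c(1L, 3L)) {
    handle <- make_classifier(classifier_spec("KNN", list(k = k)))
    mine <- handle$predict(handle$fit(xtr, ytr), xte)
    ref <- as.integer(as.character(class::knn(xtr, xte, factor(ytr), k = k)))
    expect_equal(mine, ref)
  }
})

test_that("alternative kNN distances behave sanely", {
  d <- planted_dataset(n_samples = 70, n_genes = 10, seed = 107)
  split <- split_holdout(d, seed = 3)
  genes <- head(rank_genes(d)$gene_id, 3)
  for (dist in c("chi-squared", "cosine-similarity")) {
    sc <- evaluate_split(
      d, classifier_spec("KNN", list(k = 3, distance = dist)), genes, split
    )
    expect_gt(sc$acc, 0.5)
  }
})

test_that("stochastic trainers are deterministic given their seed", {
  d <- planted_dataset(n_samples = 50, n_genes = 12, seed = 109)
  split <- split_holdout(d, seed = 4)
  genes <- head(rank_genes(d)$gene_id, 3)
  for (m in c("CMANTEC", "MLP")) {
    a <- evaluate_split(d, classifier_spec(m, seed = 42), genes, split)
    b <- evaluate_split(d, classifier_spec(m, seed = 42), genes, split)
    expect_identical(a, b)
  }
})

test_that("confusion arithmetic matches hand-computed rates", {
  d <- tiny_dataset(n = 25, p = 2)
  split <- split_holdout(d, 0.6, seed = 5) # 15 train / 10 test
  truth <- d$label[split$test]

  always1 <- evaluate_split(d, constant_handle(1), "g1", split)
  expect_equal(always1$fn_rate, 0)
  expect_equal(always1$fp_rate, mean(truth == 0))
  expect_equal(always1$acc, mean(truth == 1))

  always0 <- evaluate_split(d, constant_handle(0), "g1", split)
  expect_equal(always0$fp_rate, 0)
  expect_equal(always0$fn_rate, mean(truth == 1))

  # an oracle on the label-equal gene is perfect
  od <- oracle_dataset()
  osplit <- split_holdout(od, seed = 6)
  oracle <- evaluate_split(od, identity_handle(), "perfect", osplit)
  expect_equal(oracle$acc, 1)
  expect_equal(oracle$fp_rate, 0)
  expect_equal(oracle$fn_rate, 0)

  expect_error(evaluate_split(d, constant_handle(1), character(0), split),
    class = "evoselect_validation_error"
  )
  expect_error(evaluate_split(d, constant_handle(1), "nope", split),
    class = "evoselect_validation_error"
  )
})
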