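test_that("combination enumeration is exhaustive, sorted and lexicographic", {
  combos <- enumerate_combinations(c("e", "b", "a", "d", "c"), 2)
  expect_equal(nrow(combos), choose(5, 2))
  expect_equal(combos[1, ], c("a", "b"))
  expect_equal(combos[nrow(combos), ], c("d", "e"))
  # sorted within each tuple, no duplicates, lexicographic stream
  labels <- apply(combos, 1, paste, collapse = "+")
  expect_false(any(duplicated(labels)))
  expect_equal(labels, sort(labels, method = "radix"))

  expect_equal(enumerate_combinations(c("a", "b", "c"), 3), t(matrix(c("a", "b", "c"))))
  expect_error(enumerate_combinations(c("a", "b", "c"), 4), "exceeds the number")
  expect_error(enumerate_combinations(letters, 5), "maximum")
  expect_error(enumerate_combinations(c("a", "a", "b"), 2), "duplicates")
})

test_that("accuracy record counts true positives and negatives directly", {
  rec <- classification_accuracy(
    predicted = c("cancer", "cancer", "control", "control", "cancer"),
    actual = c("cancer", "control", "control", "cancer", "cancer")
  )
  expect_equal(rec$tp, 2)
  expect_equal(rec$tn, 1)
  expect_equal(rec$n, 5)
  expect_equal(rec$accuracy, 3 / 5)

  # property: equals (TP + TN)/N for random prediction/label vectors
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    pred <- sample(c("cancer", "control"), n, replace = TRUE)
    act <- sample(c("cancer", "control"), n, replace = TRUE)
    rec <- classification_accuracy(pred, act)
    expect_equal(rec$accuracy, sum(pred == act) / n)
    expect_lte(rec$tp + rec$tn, rec$n)
  }
})

test_that("linear classifier separates separable data and rejects one class", {
  x <- matrix(c(rnorm(20, -5, 0.1), rnorm(20, 5, 0.1)), ncol = 1)
  y <- rep(c("control", "cancer"), each = 20)
  fit <- train_linear_classifier(x, y)
  expect_equal(fit$train_accuracy, 1.0)
  expect_length(fit$weights, 1)

  # two points, one per class
  fit2 <- train_linear_classifier(matrix(c(0, 1), ncol = 1), c("control", "cancer"))
  expect_equal(fit2$train_accuracy, 1.0)

  expect_error(train_linear_classifier(x, rep("cancer", 40)), "both classes")
  expect_error(train_linear_classifier(x, rep(c("a", "b"), 20)), "labels")
})

test_that("training accuracy on overlapping Gaussians approaches the Bayes rate", {
  # equal-variance 1-D Gaussians at -1/+1: Bayes accuracy Phi(1) ~ 0.841
  set.seed(31)
  x <- matrix(c(rnorm(500, -1), rnorm(500, 1)), ncol = 1)
  y <- rep(c("control", "cancer"), each = 500)
  fit <- train_linear_classifier(x, y)
  expect_gte(fit$train_accuracy, 0.78)
  expect_lte(fit$train_accuracy, 0.90)
})

test_that("fold assignment is stratified, seeded and guarded", {
  labels <- rep(c("cancer", "control"), c(25, 20))
  f <- make_folds(labels, folds = 5, seed = 3)
  expect_identical(f, make_folds(labels, folds = 5, seed = 3))
  expect_false(identical(f, make_folds(labels, folds = 5, seed = 4)))
  for (cls in unique(labels)) {
    per_fold <- table(f[labels == cls])
    expect_lte(diff(range(per_fold)), 1) # balanced within class
  }
  expect_error(make_folds(rep(c("cancer", "control"), c(3, 20)), folds = 5), "fewer samples")
})

test_that("cross-validated accuracy is deterministic and saturates on separable data", {
  ds <- tiny_unpaired_dataset(n_genes = 3, n_per_class = 20, shift = 10, seed = 6)
  acc <- cross_validated_accuracy(ds, "g01", seed = 1)
  expect_equal(acc, 1.0)
  expect_identical(acc, cross_validated_accuracy(ds, "g01", seed = 1))
  expect_error(cross_validated_accuracy(ds, "nope", seed = 1), "not in dataset")
})

test_that("cross-validated accuracy is at chance under permuted labels", {
  base <- tiny_unpaired_dataset(n_genes = 1, n_per_class = 20, shift = 0, seed = 10)
  accs <- vapply(1:50, function(s) {
    perm <- base
    set.seed(1000 + s)
    perm$samples$condition <- sample(perm$samples$condition)
    cross_validated_accuracy(perm, "g01", seed = s)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("marker ranking equals an independent brute-force re-computation", {
  sim <- simulate_study(simulation_config(
    n_genes = 40, n_patients = 20,
    de_fraction = 0.25, log2fc_low = 1, log2fc_high = 2, seed = 13
  ))
  de <- call_differential(sim$dataset)
  genes <- de$gene[de$is_de]
  expect_gte(length(genes), 8)
  genes <- sort(genes, method = "radix")[1:8]

  for (k in 1:2) {
    ranked <- rank_markers(sim$dataset, genes,
      k = k, top_n = choose(8, k),
      seed = 99
    )
    # oracle: score every combination separately, re-sort independently
    fold_ids <- make_folds(sample_conditions(sim$dataset), 5, seed = 99)
    combos <- t(utils::combn(sort(genes, method = "radix"), k))
    acc <- apply(combos, 1, function(g) {
      cross_validated_accuracy(sim$dataset, g, fold_ids = fold_ids)
    })
    lab <- apply(combos, 1, paste, collapse = "+")
    ord <- order(-acc, lab, method = "radix")
    expect_identical(ranked$genes, lab[ord])
    expect_equal(ranked$cv_accuracy, acc[ord])
  }
})

test_that("equal-accuracy combinations are ordered lexicographically", {
  # two genes with identical values tie exactly; a third breaks ties
  ds <- tiny_unpaired_dataset(n_genes = 3, n_per_class = 10, shift = 6, seed = 2)
  ds$exprs["g02", ] <- ds$exprs["g01", ]
  ranked <- rank_markers(ds, c("g03", "g02", "g01"), k = 1, seed = 1)
  expect_equal(ranked$cv_accuracy[1], ranked$cv_accuracy[2])
  pair <- ranked$genes[ranked$cv_accuracy == ranked$cv_accuracy[1]]
  expect_identical(pair[1:2], sort(pair[1:2], method = "radix"))
})

test_that("prefilter restricts the pool to the best single genes", {
  sim <- simulate_study(simulation_config(
    n_genes = 60, n_patients = 15,
    de_fraction = 0.2, log2fc_low = 1, log2fc_high = 2.5, seed = 17
  ))
  de <- call_differential(sim$dataset)
  genes <- de$gene[de$is_de]
  ranked <- rank_markers(sim$dataset, genes, k = 2, seed = 5, prefilter = 4)
  expect_equal(nrow(ranked), choose(4, 2))
  pool <- unique(unlist(strsplit(ranked$genes, "+", fixed = TRUE)))
  expect_lte(length(pool), 4)
  expect_error(rank_markers(sim$dataset, genes, k = 1, seed = 5, prefilter = 4), "k >= 2")
  expect_error(rank_markers(sim$dataset, character(0), k = 1, seed = 5), "empty")
})

test_that("test-set evaluation refits on the full training set and flags platform misses", {
  ds <- tiny_unpaired_dataset(n_genes = 4, n_per_class = 12, shift = 8, seed = 20)
  ranked <- rank_markers(ds, c("g01", "g02", "g03"), k = 2, seed = 7)
  # identical test set: separable combos stay perfect
  ev <- evaluate_on_test(ranked, ds, list(same = ds))
  expect_equal(ev$same_accuracy, rep(1.0, nrow(ev)))
  # a test platform lacking g02: every combo containing it becomes NA
  dropped <- expression_dataset(
    ds$exprs[c("g01", "g03", "g04"), ],
    ds$samples
  )
  ev2 <- evaluate_on_test(ranked, ds, list(small = dropped))
  has_g02 <- grepl("g02", ev2$genes, fixed = TRUE)
  expect_true(all(is.na(ev2$small_accuracy[has_g02])))
  expect_true(all(!is.na(ev2$small_accuracy[!has_g02])))
})

test_that("generalization: planted panels keep their accuracy on fresh cohorts", {
  ok <- vapply(1:10, function(s) {
    cfg <- simulation_config(
      n_genes = 40, n_patients = 20, de_fraction = 0.1,
      planted_panels = list(c("g03", "g07")), panel_margin = 8, seed = 300 + s
    )
    train <- simulate_study(cfg)$dataset
    test <- simulate_panel(
      list(a = cfg, b = simulation_config(n_genes = 40, n_patients = 20, seed = 1)),
      test_cohorts = 1
    )$panel$cancers$a$tests[[1]]
    ranked <- rank_markers(train, c("g03", "g07"), k = 2, seed = s)
    ev <- evaluate_on_test(ranked, train, list(t1 = test))
    abs(ev$t1_accuracy[1] - ev$cv_accuracy[1]) <= 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("adding an informative gene never hurts training accuracy on separable data", {
  ds <- tiny_unpaired_dataset(n_genes = 3, n_per_class = 15, shift = 7, seed = 23)
  y <- sample_conditions(ds)
  acc1 <- train_linear_classifier(t(ds$exprs["g01", , drop = FALSE]), y)$train_accuracy
  acc2 <- train_linear_classifier(t(ds$exprs[c("g01", "g02"), ]), y)$train_accuracy
  expect_gte(acc2, acc1 - 0.01)
})
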