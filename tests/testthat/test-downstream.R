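test_that("GMT files round-trip and malformed lines are rejected", {
  sets <- list(
    pathway_a = structure(c("g1", "g2", "g3"), description = "first pathway"),
    pathway_b = structure(c("g2", "g4"), description = "second pathway")
  )
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(names(back), names(sets))
  expect_equal(as.character(back$pathway_a), c("g1", "g2", "g3"))
  expect_equal(attr(back$pathway_b, "description"), "second pathway")

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("just_a_name\tdesc", bad)
  expect_error(read_gmt(bad), "malformed")
})

test_that("gene-set collections enforce the background universe", {
  bg <- paste0("g", 1:10)
  expect_warning(
    coll <- gene_set_collection(list(s1 = c("g1", "g2", "outside")), bg),
    "dropped"
  )
  expect_equal(coll$sets$s1, c("g1", "g2"))
  expect_warning(
    expect_warning(
      coll2 <- gene_set_collection(list(s1 = "g1", gone = "outside"), bg),
      "dropped"
    ),
    "removed"
  )
  expect_equal(names(coll2$sets), "s1")
  expect_error(
    suppressWarnings(gene_set_collection(list(gone = "outside"), bg)),
    "no usable"
  )
})

test_that("hypergeometric enrichment matches closed forms", {
  bg <- paste0("g", 1:20)
  coll <- gene_set_collection(list(s = paste0("g", 1:5)), bg)

  # full overlap of a 5-gene query with a 5-gene set in a background of 20:
  # only one of the C(20,5) draws achieves it
  res <- hypergeometric_enrichment(paste0("g", 1:5), coll)
  expect_equal(res$overlap, 5)
  expect_equal(res$p_value, 1 / choose(20, 5))
  expect_equal(res$p_value, 1 / 15504, tolerance = 1e-12)
  expect_true(res$enriched)

  # zero overlap: the upper tail at 0 is all of probability space
  res0 <- hypergeometric_enrichment(paste0("g", 16:20), coll)
  expect_equal(res0$overlap, 0)
  expect_equal(res0$p_value, 1)
  expect_false(res0$enriched)

  # query = background: overlap is forced, p = 1 for every set
  resb <- hypergeometric_enrichment(bg, coll)
  expect_equal(resb$p_value, 1)
})

test_that("enrichment p equals the exact tail sum over a sweep of small instances", {
  N <- 15
  bg <- paste0("g", seq_len(N))
  for (K in c(1, 3, 7, 12, 15)) {
    coll <- gene_set_collection(list(s = bg[seq_len(K)]), bg)
    for (n in c(1, 4, 9, 15)) {
      for (ov in seq(max(0, K + n - N), min(K, n))) {
        query <- c(bg[seq_len(ov)], if (n > ov) bg[seq(K + 1, K + n - ov)])
        res <- hypergeometric_enrichment(query, coll)
        expect_equal(res$overlap, ov)
        expect_equal(res$p_value, hyper_tail(ov, K, n, N),
          tolerance = 1e-12,
          info = sprintf("K=%d n=%d ov=%d", K, n, ov)
        )
      }
    }
  }
})

test_that("enrichment is monotone in overlap and anti-monotone in alpha", {
  N <- 100
  bg <- paste0("g", seq_len(N))
  coll <- gene_set_collection(list(s = bg[1:20]), bg)
  p <- vapply(0:10, function(ov) {
    query <- c(bg[seq_len(ov)], if (ov < 10) bg[seq(21, 30 - ov)])
    hypergeometric_enrichment(query, coll)$p_value
  }, numeric(1))
  expect_true(all(diff(p) < 0)) # larger overlap, smaller p (fixed sizes)

  res <- hypergeometric_enrichment(bg[1:10], coll, alpha = 0.05)
  res_strict <- hypergeometric_enrichment(bg[1:10], coll, alpha = 0.001)
  expect_lte(sum(res_strict$enriched), sum(res$enriched))
})

test_that("query genes outside the background are dropped, empty queries error", {
  bg <- paste0("g", 1:10)
  coll <- gene_set_collection(list(s = bg[1:3]), bg)
  expect_warning(res <- hypergeometric_enrichment(c("g1", "nope"), coll), "dropped")
  expect_equal(res$query_size, 1)
  expect_error(
    suppressWarnings(hypergeometric_enrichment("nope", coll)),
    "empty"
  )
})

test_that("secretory filtering applies the membership-and-floor predicate", {
  candidates <- data.frame(
    rank = 1:4,
    genes = c("a+b", "a+c", "b+d", "a"),
    k = c(2, 2, 2, 1),
    cv_accuracy = c(0.85, 0.95, 0.65, 0.72),
    stringsAsFactors = FALSE
  )
  class(candidates) <- c("marker_candidates", "data.frame")
  secretory <- c("a", "b", "d")
  kept <- filter_secretory(candidates, secretory, accuracy_floor = 0.70)
  # a+c dropped (c not secretory, despite accuracy); b+d dropped (floor)
  expect_equal(kept$genes, c("a+b", "a"))
  # subset + idempotence
  expect_true(all(kept$genes %in% candidates$genes))
  expect_equal(filter_secretory(kept, secretory, accuracy_floor = 0.70), kept)
  expect_error(filter_secretory(candidates, character(0)), "empty")
})

test_that("secretory filtering equals direct predicate evaluation on simulated candidates", {
  sim <- simulate_study(simulation_config(
    n_genes = 50, n_patients = 15,
    de_fraction = 0.2, log2fc_low = 1, log2fc_high = 2.5, seed = 77
  ))
  de <- call_differential(sim$dataset)
  ranked <- rank_markers(sim$dataset, de$gene[de$is_de], k = 2, seed = 4)
  set.seed(78)
  secretory <- sample(gene_ids(sim$dataset), 25)
  kept <- filter_secretory(ranked, secretory, accuracy_floor = 0.70)
  pred <- vapply(seq_len(nrow(ranked)), function(i) {
    genes <- strsplit(ranked$genes[i], "+", fixed = TRUE)[[1]]
    all(genes %in% secretory) && ranked$cv_accuracy[i] >= 0.70
  }, logical(1))
  expect_equal(kept$genes, ranked$genes[pred])
})

test_that("multi-cancer tables qualify via their per-cancer training accuracies", {
  combos <- data.frame(
    genes = c("a+b", "b+d", "a+d"),
    k = 2, count = c(2L, 1L, 0L),
    c1_train = c(0.9, 0.70, 0.70),
    c2_train = c(0.8, 0.60, NA),
    stringsAsFactors = FALSE
  )
  class(combos) <- c("multi_cancer_combos", "data.frame")
  kept <- filter_secretory(combos, c("a", "b", "d"),
    accuracy_floor = 0.75,
    min_qualifying = 2
  )
  expect_equal(kept$genes, "a+b")
  # missing accuracies never qualify; b+d and a+d reach the floor only once
  kept1 <- filter_secretory(combos, c("a", "b", "d"),
    accuracy_floor = 0.70,
    min_qualifying = 1
  )
  expect_equal(kept1$genes, c("a+b", "b+d", "a+d"))
})

test_that("survival correlation recovers exact anti-correlation and errors on degenerate input", {
  toy <- data.frame(
    cancer = c("a", "b", "c"),
    de_gene_count = c(1, 2, 3),
    five_year_survival_rate = c(90, 80, 70)
  )
  res <- survival_correlation(toy)
  expect_equal(res$r, -1)
  expect_equal(res$n, 3)

  const <- toy
  const$five_year_survival_rate <- c(50, 50, 50)
  expect_error(survival_correlation(const), "constant")
  expect_error(survival_correlation(toy[1:2, ]), "at least 3")
  bad <- toy
  bad$five_year_survival_rate[1] <- 150
  expect_error(survival_correlation(bad), "\\[0, 100\\]")
})

test_that("correlation matches the textbook formula on arbitrary 7-point tables", {
  counts <- c(118, 231, 247, 294, 311, 683, 885)
  set.seed(55)
  for (i in 1:5) {
    rates <- round(runif(7, 5, 95), 1)
    rec <- data.frame(
      cancer = paste0("c", 1:7),
      de_gene_count = counts,
      five_year_survival_rate = rates
    )
    res <- survival_correlation(rec)
    ora <- textbook_pearson(counts, rates)
    expect_equal(res$r, ora$r, tolerance = 1e-12)
    expect_equal(res$p_value, ora$p, tolerance = 1e-12)
  }
  # spearman is rank-based: invariant to monotone transforms of the counts
  rec <- data.frame(
    cancer = paste0("c", 1:7),
    de_gene_count = counts,
    five_year_survival_rate = c(89, 64, 62, 88, 24, 15, 5)
  )
  s1 <- survival_correlation(rec, method = "spearman")
  rec$de_gene_count <- log(rec$de_gene_count)
  s2 <- survival_correlation(rec, method = "spearman")
  expect_equal(s1$r, s2$r)
})

test_that("permuted survival rates exceed the observed |r| at the rate implied by p", {
  counts <- c(118, 231, 247, 294, 311, 683, 885)
  rates <- c(89, 64, 62, 88, 24, 15, 5)
  rec <- data.frame(
    cancer = paste0("c", 1:7),
    de_gene_count = counts, five_year_survival_rate = rates
  )
  obs <- survival_correlation(rec)
  set.seed(99)
  null_r <- vapply(1:200, function(i) {
    rec$five_year_survival_rate <- sample(rates)
    survival_correlation(rec)$r
  }, numeric(1))
  emp <- mean(abs(null_r) >= abs(obs$r))
  # the permutation rate should be of the same order as the t-test p
  expect_lt(abs(emp - obs$p_value), 0.06)
})
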