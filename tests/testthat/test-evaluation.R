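test_that("metrics reproduce the published worked example from raw counts", {
  # 54 predicted size-3 complexes, 19 of them true, 87 reference trimers
  m <- confusion_metrics(confusion_counts(tp = 19, fp = 54 - 19,
                                          tn = 0, fn = 87 - 19))
  expect_equal(round(m[["precision"]], 3), 0.352)
  expect_equal(round(m[["recall"]], 3), 0.218)
  expect_equal(round(m[["f_measure"]], 3), 0.270)
})

test_that("metric identities and zero-denominator conventions hold", {
  # precision = recall = p implies F = p
  m <- confusion_metrics(confusion_counts(tp = 30, fp = 10, tn = 5, fn = 10))
  expect_equal(m[["precision"]], m[["recall"]])
  expect_equal(m[["f_measure"]], m[["precision"]])

  m0 <- confusion_metrics(confusion_counts(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_equal(unname(m0[c("precision", "recall", "f_measure")]),
               c(0, 0, 0))
  expect_error(confusion_metrics(confusion_counts()), "no evaluated")
  expect_error(confusion_counts(tp = -1))
})

test_that("metrics stay in range with F bounded by the larger component", {
  for (seed in 1:30) {
    cc <- withr::with_seed(seed, {
      as.list(stats::setNames(sample(0:20, 4, replace = TRUE),
                              c("tp", "fp", "tn", "fn")))
    })
    if (Reduce(`+`, cc) == 0) next
    m <- confusion_metrics(do.call(confusion_counts, cc))
    expect_true(all(m >= 0 & m <= 1))
    expect_lte(m[["f_measure"]], max(m[["precision"]], m[["recall"]]) + 1e-12)
    expect_equal(m[["f_measure"]] == 0, cc$tp == 0)
  }
})

test_that("dataset construction keeps connected trimers and samples the negative pool", {
  # one trimer present as a triangle, one with a member missing an edge
  edges <- data.frame(
    a = c("A", "B", "A", "D", "F", "F", "F", "G", "G", "H"),
    b = c("B", "C", "C", "E", "G", "H", "I", "H", "I", "I"),
    weight = 1:10)
  net <- ppi_network(edges)
  cat3 <- complex_catalogue(list(c("A", "B", "C"), c("D", "E", "Q"),
                                 c("F", "G", "H", "I")))
  ds <- build_dataset(cat3, net, n_negatives = 3, seed = 5)
  expect_equal(sum(ds$label == 1), 1)
  expect_equal(ds$key[ds$label == 1], triplet_key(c("A", "B", "C")))
  # the size-4 clique offers all four 3-subsets
  expect_equal(attr(ds, "n_negative_pool"), 4)
  expect_equal(sum(ds$label == -1), 3)
  ds2 <- build_dataset(cat3, net, n_negatives = 3, seed = 5)
  expect_identical(ds, ds2)
  expect_error(build_dataset(cat3, net, n_negatives = 50, seed = 1),
               "50")
})

test_that("3-subsets equal to catalogued trimers are excluded from negatives", {
  edges <- data.frame(a = c("F", "F", "F", "G", "G", "H"),
                      b = c("G", "H", "I", "H", "I", "I"),
                      weight = rep(5, 6))
  net <- ppi_network(edges)
  cat3 <- complex_catalogue(list(c("F", "G", "H"), c("F", "G", "H", "I")))
  ds <- build_dataset(cat3, net, n_negatives = 3, seed = 2)
  expect_equal(attr(ds, "n_negative_pool"), 3)  # FGH excluded
  expect_false(triplet_key(c("F", "G", "H")) %in% ds$key[ds$label == -1])
})

test_that("stratified folds partition the dataset exactly", {
  labels <- rep(c(1, -1), times = c(12, 20))
  for (seed in 1:5) {
    fold <- triphase:::stratified_folds(labels, folds = 4, seed = seed)
    expect_equal(sort(unique(fold)), 1:4)
    expect_length(fold, 32)
    expect_equal(as.vector(table(fold)), rep(8, 4))
    expect_true(all(tapply(labels == 1, fold, sum) == 3))
  }
})

test_that("cross-validation is reproducible and reports all four metrics", {
  s <- small_benchmark(seed = 8)
  ctx <- triplet_context(s$net, s$dom)
  r1 <- cross_validate(s$net, s$dom, s$cat, methods = "single-phase",
                       alpha = c(0, 0.5), folds = 4, repeats = 2,
                       n_negatives = 15, seed = 9, ctx = ctx)
  r2 <- cross_validate(s$net, s$dom, s$cat, methods = "single-phase",
                       alpha = c(0, 0.5), folds = 4, repeats = 2,
                       n_negatives = 15, seed = 9, ctx = ctx)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2)  # one row per alpha
  expect_true(all(c("accuracy", "precision", "recall", "f_measure")
                  %in% names(r1)))
  expect_true(all(r1$f_measure >= 0 & r1$f_measure <= 1))
  detail <- attr(r1, "detail")
  # fold partition: each fold's counts sum to the fold size, folds cover all
  per_rep <- tapply(detail$tp + detail$fp + detail$tn + detail$fn,
                    list(detail$repeat_, detail$alpha), sum)
  expect_true(all(per_rep == 12 + 15))  # 12 planted trimers + 15 negatives
})

test_that("a perfect separation yields ceiling metrics through the CV machinery", {
  s <- small_benchmark(seed = 10)
  res <- cross_validate(s$net, s$dom, s$cat, methods = "single-phase",
                        alpha = 0.5, folds = 4, repeats = 1,
                        n_negatives = 15, seed = 3)
  expect_true(all(res[, c("accuracy", "precision", "recall", "f_measure")]
                  >= 0.9))
})
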