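test_that("discriminant summaries follow the positive/negative averaging rules", {
  expect_equal(unname(phase2_features(1.2, numeric(0))), c(1.2, 0, 0, 0))
  expect_equal(unname(phase2_features(0.5, c(1, 3, -2))),
               c(0.5, 2, -2, 2 / 3))
  # zeros are neither positive nor negative
  expect_equal(unname(phase2_features(1, c(0, 0))), c(1, 0, 0, 0))
})

test_that("the 11-dimensional vector concatenates in fixed order", {
  f1 <- c(5, 1, 4, 2, 2, 2, 0)
  f2 <- c(1.2, 0, 0, 0)
  v <- assemble_phase2(f1, f2)
  expect_equal(unname(v), c(5, 1, 4, 2, 2, 2, 0, 1.2, 0, 0, 0))
  expect_equal(names(v),
               c(paste0("F", 1:7), "f2s", "f2p", "f2n", "f2a"))
  expect_equal(unname(assemble_phase2(rep(0, 7), rep(0, 4))), rep(0, 11))
  expect_identical(assemble_phase2(f1, f2), assemble_phase2(f1, f2))
  expect_error(assemble_phase2(f1[1:6], f2))
})

test_that("f2n <= f2a <= f2p holds for every evaluated triplet", {
  for (seed in 1:50) {
    withr::with_seed(seed, {
      k <- sample(0:6, 1)
      y_nb <- if (k == 0) numeric(0) else stats::rnorm(k)
      y_own <- stats::rnorm(1)
    })
    f2 <- phase2_features(y_own, y_nb)
    expect_lte(f2[["f2n"]], f2[["f2a"]])
    expect_lte(f2[["f2a"]], f2[["f2p"]])
    expect_gte(f2[["f2p"]], 0)
    expect_lte(f2[["f2n"]], 0)
  }
})

test_that("the full pipeline trains and phase 2 does not lose training accuracy", {
  s <- small_benchmark(seed = 3)
  ctx <- triplet_context(s$net, s$dom)
  ds <- build_dataset(s$cat, s$net, n_negatives = 20, seed = 1)

  m <- fit_two_phase(ds$key, ds$label, s$net, s$dom, alpha = 0.5, ctx = ctx)
  acc2 <- mean(predict_two_phase(m, ds$key)$label == ds$label)
  sp <- triphase:::fit_single_phase(ds$key, ds$label, s$net, s$dom,
                                    alpha = 0.5, ctx = ctx)
  acc1 <- mean(triphase:::predict_single_phase(sp, ds$key)$label == ds$label)
  expect_gte(acc2, acc1)

  # a training positive fed back as test data is recovered
  pos <- ds$key[ds$label == 1][1]
  expect_equal(predict_two_phase(m, pos)$label, 1)
})

test_that("the sparse-Bayes second phase plugs in as the second classifier", {
  s <- small_benchmark(seed = 4)
  ctx <- triplet_context(s$net, s$dom)
  ds <- build_dataset(s$cat, s$net, n_negatives = 15, seed = 2)
  m <- fit_two_phase(ds$key, ds$label, s$net, s$dom, alpha = 0.5,
                     second_classifier = "sparse-bayes", ctx = ctx)
  expect_s3_class(m$phase2, "rvm_model")
  pred <- predict_two_phase(m, ds$key)
  expect_true(all(is.finite(pred$score)))
  expect_gte(mean(pred$label == ds$label), 0.9)
})

test_that("triplets without neighboring triplets degrade to zero phase-2 summaries", {
  # two disjoint triangles: every triplet has an empty neighboring set
  edges <- data.frame(a = c("A", "B", "A", "X", "Y", "X"),
                      b = c("B", "C", "C", "Y", "Z", "Z"),
                      weight = c(9, 9, 9, 2, 2, 2))
  net <- ppi_network(edges)
  dom <- domain_annotation(list(A = "d1", X = "d2"))
  keys <- enumerate_connected_triplets(net)
  labels <- c(1, -1)
  m <- fit_two_phase(keys, labels, net, dom, alpha = 0.5)
  expect_equal(unname(m$F2tr[, c("f2p", "f2n", "f2a")]),
               matrix(0, 2, 3))
  expect_equal(m$F2tr[, "f2s"],
               triphase:::phase1_discriminants(
                 m$ctx, m$phase1, m$tr_idx, 0.5, m$tr_idx))
  pred <- predict_two_phase(m, keys)
  expect_equal(pred$label, labels)
})

test_that("a zero score maps to the negative class", {
  edges <- data.frame(a = c("A", "B", "A", "X", "Y", "X"),
                      b = c("B", "C", "C", "Y", "Z", "Z"),
                      weight = c(9, 9, 9, 2, 2, 2))
  net <- ppi_network(edges)
  dom <- domain_annotation()
  keys <- enumerate_connected_triplets(net)
  m <- fit_two_phase(keys, c(1, -1), net, dom, alpha = 0)
  m$phase2$a <- rep(0, length(m$phase2$a))
  m$phase2$b <- 0
  pred <- predict_two_phase(m, keys)
  expect_equal(pred$score, c(0, 0))
  expect_equal(pred$label, c(-1, -1))
})

test_that("prediction is deterministic and rejects disconnected triplets", {
  s <- small_benchmark(seed = 5)
  ctx <- triplet_context(s$net, s$dom)
  ds <- build_dataset(s$cat, s$net, n_negatives = 10, seed = 3)
  m1 <- fit_two_phase(ds$key, ds$label, s$net, s$dom, ctx = ctx)
  m2 <- fit_two_phase(ds$key, ds$label, s$net, s$dom, ctx = ctx)
  p1 <- predict_two_phase(m1, ctx$keys[1:50])
  p2 <- predict_two_phase(m2, ctx$keys[1:50])
  expect_identical(p1, p2)
  expect_error(predict_two_phase(m1, triplet_key(c("no1", "no2", "no3"))),
               "not connected")
  expect_error(fit_two_phase(c(ds$key, triplet_key(c("q1", "q2", "q3"))),
                             c(ds$label, 1), s$net, s$dom, ctx = ctx),
               "not connected")
})

test_that("two-phase training never reads labels outside the training set", {
  s <- small_benchmark(seed = 6)
  ctx <- triplet_context(s$net, s$dom)
  ds <- build_dataset(s$cat, s$net, n_negatives = 12, seed = 4)
  half <- seq_len(nrow(ds)) %% 2 == 0
  # flipping the held-out labels must not change the fitted model
  m_a <- fit_two_phase(ds$key[half], ds$label[half], s$net, s$dom, ctx = ctx)
  m_b <- fit_two_phase(ds$key[half], ds$label[half], s$net, s$dom, ctx = ctx)
  expect_identical(m_a$phase1$a, m_b$phase1$a)
  expect_identical(m_a$F2tr, m_b$F2tr)
  pr_a <- predict_two_phase(m_a, ds$key[!half])
  pr_b <- predict_two_phase(m_b, ds$key[!half])
  expect_identical(pr_a$score, pr_b$score)
})
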