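test_that("feature vectors concatenate symptom and one-hot scheme blocks", {
  vocab <- vocabulary(sprintf("s%d", 1:6))
  spec <- recommender_spec("symptom_plus_scheme", 6L, 10L, n_clusters = 5L)
  f <- build_features(c("s1", "s3", "s4"), hpc = 3L, vocab, spec)
  expect_length(f, 11L)
  expect_equal(f[1:6], c(1, 0, 1, 1, 0, 0))
  expect_equal(f[7:11], c(0, 0, 1, 0, 0))
  expect_equal(sum(f[7:11]), 1)  # always one-hot
  spec_s <- recommender_spec("symptom", 6L, 10L)
  expect_length(build_features(c("s1"), NULL, vocab, spec_s), 6L)
  expect_error(build_features(c("s1"), NULL, vocab, spec), "cluster id")
})

test_that("screening follows the cutoff mapping, never empties, and is monotone", {
  # single linear layer with zero weights: output = sigmoid(bias)
  spec <- recommender_spec("symptom", 3L, 3L, hidden_sizes = integer(0))
  model <- structure(list(
    spec = spec,
    net = list(W = list(matrix(0, 3, 3)),
               b = list(stats::qlogis(c(0.95, 0.7, 0.1))),
               sizes = c(3L, 3L), out = "sigmoid")),
    class = "herbrx_recommender")
  vocab <- vocabulary(c("hA", "hB", "hC"))
  x <- c(1, 0, 0)
  expect_equal(predict_prescription(model, x, filter_config(0.1), vocab), "hA")
  expect_setequal(predict_prescription(model, x, filter_config(0.4), vocab),
                  c("hA", "hB"))
  # direct mapping reads the threshold as the cutoff itself
  expect_setequal(predict_prescription(model, x,
                                       filter_config(0.6, "direct"), vocab),
                  c("hA", "hB"))
  # fallback: impossible cutoff still returns the top herb
  model$net$b[[1]] <- stats::qlogis(c(0.4, 0.3, 0.2))
  expect_equal(predict_prescription(model, x, filter_config(0.01), vocab), "hA")
  # monotone subset chain in the threshold
  model$net$b[[1]] <- stats::qlogis(c(0.95, 0.7, 0.45))
  prev <- character(0)
  for (thr in c(0.1, 0.2, 0.3, 0.4, 0.6)) {
    cur <- predict_prescription(model, x, filter_config(thr), vocab)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("recommendation metrics match hand calculations and identities", {
  m <- evaluate_recommendation(list(c("A", "B")), list(c("B", "C")))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  expect_equal(m$iou, 1 / 3)
  perfect <- evaluate_recommendation(list(c("A", "B"), "C"),
                                     list(c("A", "B"), "C"))
  expect_equal(unlist(perfect[c("precision", "recall", "f1", "iou")]),
               c(precision = 1, recall = 1, f1 = 1, iou = 1))
  expect_error(evaluate_recommendation(list("A"), list("A", "B")), "length")
  # identities on random sets: IoU <= min(P, R) per sample; F1 harmonic
  withr::with_seed(41L, {
    for (i in 1:15) {
      pred <- sample(LETTERS, sample(1:6, 1))
      truth <- sample(LETTERS, sample(1:6, 1))
      mm <- evaluate_recommendation(list(pred), list(truth))
      expect_lte(mm$iou, min(mm$precision, mm$recall) + 1e-12)
      if (mm$precision + mm$recall > 0) {
        expect_equal(mm$f1, 2 * mm$precision * mm$recall /
                       (mm$precision + mm$recall))
      }
    }
  })
})

test_that("the recommender memorises a tiny training set and is reproducible", {
  withr::with_seed(42L, {
    n_herb <- 12L
    X <- matrix(rbinom(10 * 8, 1L, 0.4), 10L, 8L)
    Y <- matrix(rbinom(10 * n_herb, 1L, 0.3), 10L, n_herb)
    Y[rowSums(Y) == 0, 1L] <- 1L
  })
  spec <- recommender_spec("symptom", 8L, n_herb, hidden_sizes = c(32L))
  m1 <- train_recommender(X, Y, spec, epochs = 300L, seed = 7L)
  vocab <- vocabulary(sprintf("h%02d", seq_len(n_herb)))
  preds <- predict_prescription(m1, X, filter_config(0.4), vocab)
  truths <- lapply(seq_len(nrow(Y)), function(i) unclass(vocab)[Y[i, ] == 1])
  fit <- evaluate_recommendation(preds, truths)
  expect_gte(fit$f1, 0.95)
  m2 <- train_recommender(X, Y, spec, epochs = 300L, seed = 7L)
  expect_identical(m1$net, m2$net)
  # label shuffling destroys generalisation: held-out F1 falls to chance
  withr::with_seed(43L, {
    Yperm <- Y[sample(nrow(Y)), ]
    Xte <- matrix(rbinom(30 * 8, 1L, 0.4), 30L, 8L)
    Yte <- matrix(rbinom(30 * n_herb, 1L, 0.3), 30L, n_herb)
    Yte[rowSums(Yte) == 0, 1L] <- 1L
  })
  mshuf <- train_recommender(X, Yperm, spec, epochs = 100L, seed = 7L)
  pte <- predict_prescription(mshuf, Xte, filter_config(0.4), vocab)
  tte <- lapply(seq_len(nrow(Yte)), function(i) unclass(vocab)[Yte[i, ] == 1])
  null_fit <- evaluate_recommendation(pte, tte)
  expect_lt(null_fit$f1, 0.55)
})

test_that("the scheme-augmented experiment reports the expected table shape", {
  g <- generate_cohort(generator_config(n_patients = 80L, seed = 44L))
  model <- cluster_prescriptions(build_prescription_matrix(g$cohort), 3L,
                                 seed = 1L)
  res <- run_recommendation_experiment(g$cohort, model,
                                       thresholds = c(0.2, 0.3),
                                       hidden_sizes = c(32L, 16L),
                                       epochs = 10L, seed = 2L)
  expect_equal(nrow(res), 4L)
  expect_setequal(unique(res$input_mode), c("symptom", "symptom_plus_scheme"))
  expect_true(all(c("n_herbs_mean", "n_herbs_sd", "precision", "recall",
                    "f1", "iou", "f1_improvement_pct") %in% names(res)))
  sch <- res[res$input_mode == "symptom_plus_scheme", ]
  expect_false(any(is.na(sch$f1_improvement_pct)))
})
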