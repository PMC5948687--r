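test_that("a separable toy problem is classified perfectly at threshold 0", {
  set.seed(71)
  toy <- separable_toy()
  m <- train_binary(toy$x, toy$y, positive = "OXY")
  s <- decision_score(m, toy$x)
  expect_true(all(s[toy$y == "OXY"] > 0))
  expect_true(all(s[toy$y == "NONOXY"] < 0))
  expect_equal(unname(predict_label(m, toy$x[1, ])), "positive")
})

test_that("training is deterministic and rejects degenerate input", {
  set.seed(72)
  toy <- separable_toy()
  m1 <- train_binary(toy$x, toy$y, positive = "OXY", seed = 5)
  m2 <- train_binary(toy$x, toy$y, positive = "OXY", seed = 5)
  expect_identical(m1$coefs, m2$coefs)
  expect_identical(decision_score(m1, toy$x), decision_score(m2, toy$x))
  expect_error(train_binary(toy$x, rep("OXY", nrow(toy$x)), positive = "OXY"),
               "single class")
  xb <- toy$x; xb[1, 1] <- NaN
  expect_error(train_binary(xb, toy$y, positive = "OXY"), "non-finite")
})

test_that("batch scoring equals per-row scoring", {
  set.seed(73)
  toy <- separable_toy()
  m <- train_binary(toy$x, toy$y, positive = "OXY")
  batch <- decision_score(m, toy$x)
  single <- vapply(seq_len(nrow(toy$x)),
                   function(i) decision_score(m, toy$x[i, ]), numeric(1))
  expect_equal(batch, single, tolerance = 1e-10)
})

test_that("decision scores validate feature dimension and mode", {
  set.seed(74)
  toy <- separable_toy(d = 20)
  m <- train_binary(toy$x, toy$y, positive = "OXY", feature_mode = "AC")
  expect_error(decision_score(m, numeric(5)), "dimension mismatch")
  v <- dipeptide_composition(rand_seq(50))
  expect_error(decision_score(m, v), "mode mismatch")
  expect_silent(decision_score(m, aa_composition(rand_seq(50))))
})

test_that("threshold semantics: extremes and monotone positive counts", {
  set.seed(75)
  toy <- separable_toy()
  m <- train_binary(toy$x, toy$y, positive = "OXY")
  expect_true(all(predict_label(m, toy$x, -Inf) == "positive"))
  expect_true(all(predict_label(m, toy$x, Inf) == "negative"))
  npos <- vapply(seq(-2, 2, 0.25),
                 function(t) sum(predict_label(m, toy$x, t) == "positive"),
                 numeric(1))
  expect_true(all(diff(npos) <= 0))
})

test_that("label-flip symmetry negates linear-kernel decision scores", {
  set.seed(76)
  toy <- separable_toy(n = 15)
  m1 <- train_binary(toy$x, toy$y, positive = "OXY", kernel = "linear")
  m2 <- train_binary(toy$x, toy$y, positive = "NONOXY", kernel = "linear")
  expect_equal(decision_score(m1, toy$x), -decision_score(m2, toy$x),
               tolerance = 1e-6)
})

test_that("inner-CV grid tuning selects and records one parameter pair", {
  set.seed(77)
  toy <- separable_toy(n = 25)
  m <- train_binary(toy$x, toy$y, positive = "OXY",
                    cost = c(1, 10), gamma = c(0.05, 0.5), seed = 3)
  expect_true(m$cost %in% c(1, 10))
  expect_true(m$gamma %in% c(0.05, 0.5))
  expect_length(m$cost, 1L)
})

test_that("public predict path reproduces training-time scores (no skew)", {
  ds <- tiny_dataset(10, seed = 6)
  fm <- encode_dataset(ds, "AC")
  m <- train_binary(fm$x, binary_labels(ds), positive = "OXY",
                    feature_mode = "AC")
  expect_equal(decision_score(m, fm$x), m$train_scores, tolerance = 0)
})

test_that("train_bundle builds seven consistent models and checks classes", {
  ds <- tiny_dataset(8, seed = 13)
  b <- train_bundle(ds, feature_mode = "AC", seed = 2)
  expect_s3_class(b, "oxyprot_bundle")
  expect_named(b$subclass, OXY_CLASSES)
  expect_equal(b$binary$positive_label, "OXY")
  for (cl in OXY_CLASSES) {
    expect_equal(b$subclass[[cl]]$feature_mode, "AC")
  }
  dropped <- ds[ds$label != "LEG", ]
  class(dropped) <- c("labeled_dataset", "data.frame")
  expect_error(train_bundle(dropped, "AC"), "LEG")
})

test_that("classify_sequence ranks sub-classes and honors thresholds", {
  ds <- tiny_dataset(12, seed = 14)
  b <- train_bundle(ds, feature_mode = "AC", seed = 2)
  r1 <- classify_sequence(b, ds$seq[1])
  r2 <- classify_sequence(b, ds$seq[1])
  expect_identical(r1, r2)                    # deterministic
  expect_equal(names(r1$scores)[1], r1$call)
  expect_true(all(diff(r1$scores) <= 0))      # ranked descending
  # thresholds above every score: sub-class call flagged, binary still there
  r3 <- classify_sequence(b, ds$seq[1], thresholds = 1e6)
  expect_false(r3$above_threshold)
  expect_true(r3$binary_label %in% c("OXY", "NONOXY"))
})

test_that("strong-signal training examples are recovered by their own class", {
  ds <- tiny_dataset(15, seed = 15)
  b <- train_bundle(ds, feature_mode = "AC", seed = 2)
  oxy <- ds[ds$label %in% OXY_CLASSES, ]
  hits <- vapply(seq_len(nrow(oxy)), function(i) {
    classify_sequence(b, oxy$seq[i])$call == oxy$label[i]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("save / load round trip reproduces scores exactly", {
  ds <- tiny_dataset(8, seed = 16)
  b <- train_bundle(ds, feature_mode = "AC", seed = 2)
  dir <- withr::local_tempdir()
  save_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  b2 <- load_bundle(dir)
  expect_equal(b2$feature_mode, "AC")
  set.seed(99)
  probes <- t(vapply(1:100, function(i) {
    v <- stats::runif(20); v / sum(v)
  }, numeric(20)))
  expect_lt(max(abs(decision_score(b$binary, probes) -
                    decision_score(b2$binary, probes))), 1e-9)
  for (cl in OXY_CLASSES) {
    expect_lt(max(abs(decision_score(b$subclass[[cl]], probes) -
                      decision_score(b2$subclass[[cl]], probes))), 1e-9)
  }
})

test_that("subsampling negative policy matches class sizes, seeded", {
  set.seed(78)
  x <- rbind(matrix(stats::rnorm(200, 1), ncol = 4),
             matrix(stats::rnorm(40, -1), ncol = 4))
  y <- c(rep("OXY", 50), rep("NONOXY", 10))
  m <- train_binary(x, y, positive = "OXY", class_balance = "subsample",
                    seed = 4)
  expect_equal(m$meta$n_pos, 10L)
  expect_equal(m$meta$n_neg, 10L)
  m2 <- train_binary(x, y, positive = "OXY", class_balance = "subsample",
                     seed = 4)
  expect_identical(m$train_scores, m2$train_scores)
})
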