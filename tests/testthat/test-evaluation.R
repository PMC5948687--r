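test_that("fold sizes follow the near-equal division rule", {
  p <- make_folds(rep("a", 10), k = 5, repeats = 1, seed = 1, stratified = FALSE)
  expect_equal(as.integer(sort(table(p$assignment[1, ]))), rep(2L, 5))
  p <- make_folds(rep("a", 11), k = 5, repeats = 1, seed = 1, stratified = FALSE)
  expect_equal(as.integer(sort(table(p$assignment[1, ]), decreasing = TRUE)),
               c(3L, 2L, 2L, 2L, 2L))
  expect_error(make_folds(rep("a", 10), k = 1), "k must be")
  expect_error(make_folds(rep("a", 3), k = 5), "at least k")
  expect_warning(make_folds(c(rep("a", 10), "b"), k = 5, repeats = 1),
                 "smaller than k")
})

test_that("random plans are exhaustive, balanced, stratified, reproducible", {
  set.seed(81)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    k <- sample(2:5, 1)
    labels <- sample(c("OXY", "NONOXY"), n, replace = TRUE, prob = c(0.6, 0.4))
    if (min(table(labels)) < k) next
    seed <- sample.int(1e6, 1)
    p <- make_folds(labels, k = k, repeats = 2, seed = seed)
    for (r in 1:2) {
      fold <- p$assignment[r, ]
      expect_true(all(fold %in% 1:k))          # partition: every item in one fold
      for (cl in unique(labels)) {             # near-equal sizes per stratum
        cs <- table(factor(fold[labels == cl], levels = 1:k))
        expect_lte(max(cs) - min(cs), 1)
      }
    }
    p2 <- make_folds(labels, k = k, repeats = 2, seed = seed)
    expect_identical(p$assignment, p2$assignment)
  }
})

test_that("confusion counts match a brute-force loop", {
  cc <- confusion_at(c(1, -1), c("OXY", "NONOXY"), 0)
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]), c(TP = 1, TN = 1, FP = 0, FN = 0))
  cc <- confusion_at(c(1, -1, 2), c("OXY", "OXY", "NONOXY"), -5)
  expect_equal(cc$FN + cc$TN, 0L)              # threshold below min score
  set.seed(82)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    s <- stats::rnorm(n)
    y <- sample(c("OXY", "NONOXY"), n, replace = TRUE)
    t <- stats::rnorm(1)
    cc <- confusion_at(s, y, t)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in 1:n) {
      if (s[j] >= t && y[j] == "OXY") tp <- tp + 1
      else if (s[j] < t && y[j] != "OXY") tn <- tn + 1
      else if (s[j] >= t) fp <- fp + 1
      else fn <- fn + 1
    }
    expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(tp, tn, fp, fn))
    expect_equal(cc$TP + cc$FN, sum(y == "OXY"))
    expect_equal(cc$TN + cc$FP, sum(y != "OXY"))
  }
})

test_that("metrics reproduce closed-form values and symmetries", {
  m <- compute_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(m), c(ACC = 1, Sen = 1, Sep = 1, MCC = 1))

  m <- compute_metrics(list(TP = 90, TN = 80, FP = 20, FN = 10))
  expect_equal(m$ACC, 0.85)
  expect_equal(m$Sen, 0.90)
  expect_equal(m$Sep, 0.80)
  expect_equal(m$MCC, 7000 / sqrt(110 * 100 * 100 * 90), tolerance = 1e-12)

  # TP<->TN, FP<->FN swap fixes ACC and MCC, exchanges Sen and Sep
  m2 <- compute_metrics(list(TP = 80, TN = 90, FP = 10, FN = 20))
  expect_equal(m2$ACC, m$ACC)
  expect_equal(m2$MCC, m$MCC)
  expect_equal(m2$Sen, m$Sep)
  expect_equal(m2$Sep, m$Sen)

  # zero-denominator convention
  expect_equal(compute_metrics(list(TP = 0, TN = 5, FP = 0, FN = 5))$MCC, 0)
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "all-zero")
})

test_that("metrics agree with the reconstruction oracle on random tables", {
  set.seed(83)
  for (i in 1:2500) {
    cts <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                   c("TP", "TN", "FP", "FN")))
    if (sum(unlist(cts)) == 0) next
    got <- compute_metrics(cts)
    want <- oracle_metrics(cts$TP, cts$TN, cts$FP, cts$FN)
    expect_equal(got$ACC, want$ACC, tolerance = 1e-12)
    if (!is.nan(want$Sen)) expect_equal(got$Sen, want$Sen, tolerance = 1e-12)
    if (!is.nan(want$Sep)) expect_equal(got$Sep, want$Sep, tolerance = 1e-12)
    expect_equal(got$MCC, want$MCC, tolerance = 1e-9)
  }
})

test_that("threshold sweep covers the grid and composes from primitives", {
  set.seed(84)
  s <- stats::rnorm(100)
  y <- sample(c("OXY", "NONOXY"), 100, replace = TRUE)
  sw <- threshold_sweep(s, y)
  expect_equal(nrow(sw), 31L)                 # -1.5 .. 1.5 by 0.1
  expect_true(all(diff(sw$Sen) <= 1e-12))     # Sen non-increasing
  expect_true(all(diff(sw$Sep) >= -1e-12))    # Sep non-decreasing
  for (j in sample(31, 8)) {
    m <- compute_metrics(confusion_at(s, y, sw$threshold[j]))
    expect_equal(sw$ACC[j], m$ACC)
    expect_equal(sw$MCC[j], m$MCC)
  }
  av <- attr(sw, "averages")
  expect_equal(unname(av["ACC"]), mean(sw$ACC))
  expect_error(threshold_sweep(s, y, t_min = 1, t_max = 0), "t_min")
})

test_that("ROC endpoints, monotonicity, and separable AUC", {
  s <- c(3, 2, 1, -1, -2, -3)
  y <- c("OXY", "OXY", "OXY", "NONOXY", "NONOXY", "NONOXY")
  r <- roc_curve(s, y)
  expect_equal(r$auc, 1.0)
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_error(roc_curve(s, rep("OXY", 6)), "both classes")
})

test_that("AUC equals the pairwise rank statistic on random score sets", {
  set.seed(85)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    s <- sample(round(stats::rnorm(n), 1))    # rounded -> ties occur
    y <- sample(c("OXY", "NONOXY"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(roc_curve(s, y)$auc, oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(86)
  for (i in 1:20) {
    n <- 80
    y <- sample(c(1, 0), n, replace = TRUE)
    s <- stats::rnorm(n) + y
    got <- roc_curve(s, ifelse(y == 1, "OXY", "NONOXY"))$auc
    want <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(87)
  s <- stats::rnorm(300)
  y <- sample(c("OXY", "NONOXY"), 300, replace = TRUE)
  a0 <- roc_curve(s, y)$auc
  expect_equal(roc_curve(exp(s), y)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_curve(2 * s + 7, y)$auc, a0, tolerance = 1e-12)
})

test_that("labels independent of scores give a null AUC near one half", {
  set.seed(88)
  s <- stats::rnorm(2000)
  y <- sample(c("OXY", "NONOXY"), 2000, replace = TRUE)
  expect_lt(abs(roc_curve(s, y)$auc - 0.5), 0.04)
})

test_that("cross-validation yields one out-of-fold score per item per repeat", {
  set.seed(89)
  toy <- separable_toy(n = 30, d = 4)
  plan <- make_folds(toy$y, k = 5, repeats = 3, seed = 7)
  cv <- cross_validate(toy$x, toy$y, plan, positive = "OXY")
  expect_false(anyNA(cv$scores))
  expect_equal(dim(cv$scores), c(3L, 60L))
  expect_equal(unname(cv$mean["ACC"]), 1.0)    # separable limit
  # determinism: same plan + seed reproduce identical pooled scores
  cv2 <- cross_validate(toy$x, toy$y, plan, positive = "OXY")
  expect_identical(cv$scores, cv2$scores)
  # pooled confusion counts sum to n per repeat
  cc <- confusion_at(cv$scores[1, ], toy$y, 0)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 60L)
  expect_error(cross_validate(toy$x[1:10, ], toy$y[1:10], plan,
                              positive = "OXY"), "plan is for")
})

test_that("permuted labels drive cross-validated AUC to chance", {
  set.seed(90)
  x <- matrix(stats::rnorm(100 * 5), ncol = 5)
  y <- sample(rep(c("OXY", "NONOXY"), each = 50))   # independent of x
  plan <- make_folds(y, k = 5, repeats = 20, seed = 11)
  cv <- cross_validate(x, y, plan, positive = "OXY")
  expect_gt(unname(cv$mean["AUC"]), 0.4)
  expect_lt(unname(cv$mean["AUC"]), 0.6)
})

test_that("cross-class confusion accounting and degenerate thresholds", {
  ds <- tiny_dataset(10, seed = 17)
  oxy <- ds[ds$label %in% OXY_CLASSES, ]
  class(oxy) <- c("labeled_dataset", "data.frame")
  b <- train_bundle(ds, feature_mode = "AC", seed = 3)
  ccm <- cross_class_confusion(b, oxy)
  expect_equal(dim(ccm), c(6L, 7L))
  # accounting: recognized + unrecognized = class size, per row
  sizes <- table(oxy$label)[OXY_CLASSES]
  expect_equal(attr(ccm, "recognized") + ccm[, "unrecognized"],
               sizes, ignore_attr = TRUE)
  # diagonal dominance under strong separation
  for (r in OXY_CLASSES) expect_equal(max(ccm[r, OXY_CLASSES]), ccm[r, r])
  # thresholds at +Inf leave every sequence unrecognized
  ccm_inf <- cross_class_confusion(b, oxy, thresholds = Inf)
  expect_equal(unname(ccm_inf[, "unrecognized"]), unname(as.integer(sizes)))
  expect_true(all(ccm_inf[, OXY_CLASSES] == 0))
  bad <- ds
  expect_error(cross_class_confusion(b, bad), "unknown label")
})
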