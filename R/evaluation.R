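#' Build a repeated k-fold cross-validation plan
#'
#' Partitions `n` items into `k` folds of nearly equal size (sizes differ
#' by at most one), independently for each repeat, reproducibly from the
#' seed. With `stratified = TRUE` (default) the near-equal split holds
#' within every class, keeping per-class proportions constant across folds;
#' classes smaller than `k` are spread over as many folds as they have
#' members, with a warning.
#'
#' @param labels Class label per item (only sizes are used when
#'   `stratified = FALSE`).
#' @param k Number of folds (default 5).
#' @param repeats Number of independent repetitions (default 20).
#' @param seed Integer seed; the same seed regenerates the identical plan.
#' @param stratified Stratify folds by label.
#' @return A `cv_plan`: list with `assignment` (repeats x n integer matrix
#'   of fold indices), `n`, `k`, `repeats`, `seed`, `stratified`.
#' @export
make_folds <- function(labels, k = 5L, repeats = 20L, seed = 1L,
                       stratified = TRUE) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("need at least k items")
  if (stratified) {
    small <- names(which(table(labels) < k))
    if (length(small) > 0L) {
      warning("class(es) smaller than k spread over fewer folds: ",
              paste(small, collapse = ", "))
    }
  }
  assignment <- with_seed(seed, {
    t(vapply(seq_len(repeats), function(r) {
      fold <- integer(n)
      if (stratified) {
        for (cl in unique(labels)) {
          idx <- which(labels == cl)
          fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
      } else {
        fold <- sample(rep_len(seq_len(k), n))
      }
      fold
    }, integer(n)))
  })
  structure(list(assignment = assignment, n = n, k = k,
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 stratified = stratified),
            class = "cv_plan")
}

#' Repeated cross-validated out-of-fold scoring
#'
#' For every repeat of the plan, trains the discriminator on k-1 folds and
#' scores the held-out fold, so each item receives exactly one out-of-fold
#' decision score per repeat. Metrics (accuracy, sensitivity, specificity,
#' MCC at threshold 0, and AUC) are computed on the pooled out-of-fold
#' scores within each repeat, then averaged over repeats.
#'
#' @param x Feature matrix.
#' @param y Labels.
#' @param plan A `cv_plan` for `nrow(x)` items.
#' @param positive Positive-class label.
#' @inheritParams train_binary
#' @return A `cv_result`: list with `scores` (repeats x n matrix of pooled
#'   out-of-fold scores), `per_repeat` (data.frame of per-repeat metrics),
#'   `mean` (named vector of metric means over repeats), `positive`.
#' @export
cross_validate <- function(x, y, plan, positive, kernel = "rbf",
                           cost = 10, gamma = NULL,
                           class_balance = "weight", seed = 1L) {
  stopifnot(inherits(plan, "cv_plan"))
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != plan$n) stop("plan is for ", plan$n, " items, data has ", nrow(x))
  scores <- matrix(NA_real_, nrow = plan$repeats, ncol = plan$n)
  for (r in seq_len(plan$repeats)) {
    for (f in seq_len(plan$k)) {
      te <- plan$assignment[r, ] == f
      if (!any(te)) next
      m <- train_binary(x[!te, , drop = FALSE], y[!te], positive = positive,
                        kernel = kernel, cost = cost, gamma = gamma,
                        class_balance = class_balance, seed = seed)
      scores[r, te] <- decision_score(m, x[te, , drop = FALSE])
    }
  }
  per_repeat <- do.call(rbind, lapply(seq_len(plan$repeats), function(r) {
    mets <- compute_metrics(confusion_at(scores[r, ], y, 0, positive))
    data.frame(repeat_ = r, ACC = mets$ACC, Sen = mets$Sen, Sep = mets$Sep,
               MCC = mets$MCC, AUC = roc_curve(scores[r, ], y, positive)$auc)
  }))
  structure(list(scores = scores, per_repeat = per_repeat,
                 mean = colMeans(per_repeat[, -1, drop = FALSE]),
                 positive = positive, labels = y),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result over", nrow(x$scores), "repeat(s); mean metrics:\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Confusion counts at a decision threshold
#'
#' An example is predicted positive iff its score is `>= threshold`. TP is
#' a positive example predicted positive, TN a negative predicted negative,
#' FP a negative predicted positive, FN a positive predicted negative.
#'
#' @param scores Numeric decision scores.
#' @param labels Labels, same length.
#' @param threshold Decision cutoff.
#' @param positive Positive-class label (default `"OXY"`).
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_at <- function(scores, labels, threshold, positive = "OXY") {
  if (length(scores) == 0L) stop("empty input")
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  pred <- scores >= threshold
  structure(list(TP = sum(pred & pos), TN = sum(!pred & !pos),
                 FP = sum(pred & !pos), FN = sum(!pred & pos)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity and MCC from confusion counts
#'
#' * `ACC = (TP + TN) / (TP + TN + FP + FN)`
#' * `Sen = TP / (TP + FN)` (true-positive rate)
#' * `Sep = TN / (TN + FP)` (true-negative rate)
#' * `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`
#'
#' When any factor of the MCC denominator is zero the coefficient is
#' undefined; the standard convention `MCC = 0` is used. `Sen` (`Sep`) is
#' `NaN` when no positives (negatives) exist.
#'
#' @param cc A `confusion_counts` object (or list with TP/TN/FP/FN).
#' @return List with `ACC`, `Sen`, `Sep`, `MCC`.
#' @export
compute_metrics <- function(cc) {
  tp <- as.numeric(cc$TP); tn <- as.numeric(cc$TN)
  fp <- as.numeric(cc$FP); fn <- as.numeric(cc$FN)
  total <- tp + tn + fp + fn
  if (total == 0) stop("all-zero confusion counts")
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(ACC = (tp + tn) / total,
       Sen = tp / (tp + fn),
       Sep = tn / (tn + fp),
       MCC = if (denom2 == 0) 0 else (tp * tn - fp * fn) / sqrt(denom2))
}

#' Threshold sweep of confusion-derived metrics
#'
#' Evaluates the confusion matrix and its metrics on a grid of decision
#' thresholds (default -1.5 to +1.5 in steps of 0.1, i.e. 31 points) and
#' reports the grid averages of accuracy, sensitivity and specificity.
#' Sensitivity is non-increasing and specificity non-decreasing in the
#' threshold.
#'
#' @inheritParams confusion_at
#' @param t_min,t_max,step Grid limits and spacing (`t_min < t_max`,
#'   `step > 0`).
#' @return data.frame with one row per threshold (`threshold`, `TP`, `TN`,
#'   `FP`, `FN`, `ACC`, `Sen`, `Sep`, `MCC`) and attribute `averages`
#'   (named vector: grid means of ACC, Sen, Sep).
#' @export
threshold_sweep <- function(scores, labels, t_min = -1.5, t_max = 1.5,
                            step = 0.1, positive = "OXY") {
  if (!(t_min < t_max) || step <= 0) stop("need t_min < t_max and step > 0")
  grid <- seq(t_min, t_max, by = step)
  if (length(grid) == 0L) stop("empty threshold grid")
  rows <- lapply(grid, function(t) {
    cc <- confusion_at(scores, labels, t, positive)
    mets <- compute_metrics(cc)
    data.frame(threshold = t, TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
               ACC = mets$ACC, Sen = mets$Sen, Sep = mets$Sep, MCC = mets$MCC)
  })
  out <- do.call(rbind, rows)
  attr(out, "averages") <- c(ACC = mean(out$ACC), Sen = mean(out$Sen),
                             Sep = mean(out$Sep))
  out
}

#' ROC curve and AUC
#'
#' Computes the (FPR, TPR) operating points at every distinct score
#' threshold, anchored at (0,0) and (1,1), and the area under the curve by
#' the trapezoidal rule. With ties handled by the trapezoid, the AUC equals
#' the Mann-Whitney rank statistic
#' `P(score_pos > score_neg) + 0.5 * P(tie)`.
#'
#' @inheritParams confusion_at
#' @return A `roc_result`: list with `points` (data.frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels, positive = "OXY") {
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  # cumulative counts at each distinct score (predict positive iff >= s)
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = c(Inf, s[last]),
                                     fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC with", nrow(x$points), "points; AUC =", round(x$auc, 4), "\n")
  invisible(x)
}

#' Cross-class confusion matrix of the six sub-class models
#'
#' For every oxygen-binding sequence, checks which sub-class models accept
#' it (decision score at or above that model's threshold). Cell `(r, c)`
#' counts class-`r` sequences accepted by model `c`; a sequence accepted by
#' several models is counted in each accepting column, so the diagnostic
#' captures both phenomena of interest -- sequences recognized by other
#' classes' models, and sequences recognized by none (the `unrecognized`
#' column). Per row, `recognized + unrecognized = class size`, where
#' `recognized` counts sequences accepted by at least one model.
#'
#' @param bundle An `oxyprot_bundle`.
#' @param dataset A `labeled_dataset` whose labels are all oxy sub-classes.
#' @param pssms Named list of `pssm` objects (PSSM mode only).
#' @param thresholds Scalar or named per-model thresholds.
#' @return Integer matrix, rows = the six sub-classes, columns = the six
#'   models plus `unrecognized`; attributes `recognized` (per-row counts)
#'   and `own_argmax` (per-row count of sequences whose own model has the
#'   top score).
#' @export
cross_class_confusion <- function(bundle, dataset, pssms = NULL,
                                  thresholds = 0) {
  stopifnot(inherits(bundle, "oxyprot_bundle"),
            inherits(dataset, "labeled_dataset"))
  bad <- setdiff(unique(dataset$label), OXY_CLASSES)
  if (length(bad) > 0L) stop("unknown label(s): ", paste(bad, collapse = ", "))
  fm <- encode_dataset(dataset, mode = bundle$feature_mode, pssms = pssms)
  thr <- function(name) {
    if (length(thresholds) == 1L && is.null(names(thresholds))) return(thresholds)
    thresholds[[name]] %||% 0
  }
  smat <- vapply(OXY_CLASSES, function(cl) {
    decision_score(bundle$subclass[[cl]], fm$x)
  }, numeric(nrow(fm$x)))
  smat <- matrix(smat, nrow = nrow(fm$x), ncol = 6L,
                 dimnames = list(NULL, OXY_CLASSES))
  acc <- vapply(OXY_CLASSES, function(cl) smat[, cl] >= thr(cl),
                logical(nrow(fm$x)))
  acc <- matrix(acc, nrow = nrow(fm$x), ncol = 6L,
                dimnames = list(NULL, OXY_CLASSES))
  out <- matrix(0L, nrow = 6L, ncol = 7L,
                dimnames = list(OXY_CLASSES, c(OXY_CLASSES, "unrecognized")))
  recognized <- integer(6L); own_argmax <- integer(6L)
  names(recognized) <- names(own_argmax) <- OXY_CLASSES
  argmax <- OXY_CLASSES[apply(smat, 1, which.max)]
  for (r in OXY_CLASSES) {
    rows <- dataset$label == r
    out[r, OXY_CLASSES] <- colSums(acc[rows, , drop = FALSE])
    out[r, "unrecognized"] <- sum(rowSums(acc[rows, , drop = FALSE]) == 0L)
    recognized[r] <- sum(rowSums(acc[rows, , drop = FALSE]) > 0L)
    own_argmax[r] <- sum(argmax[rows] == r)
  }
  structure(out, recognized = recognized, own_argmax = own_argmax)
}

#' Write a per-model metrics table as TSV
#'
#' One row per model with ACC / Sen / Sep / MCC (and AUC when present),
#' mirroring the usual per-approach performance-table layout.
#'
#' @param rows Named list of metric lists (one per model).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(rows, path) {
  cols <- unique(unlist(lapply(rows, names)))
  df <- data.frame(model = names(rows))
  for (cn in cols) {
    df[[cn]] <- vapply(rows, function(r) as.numeric(r[[cn]] %||% NA), numeric(1))
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
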