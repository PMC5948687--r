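#' Train a binary SVM discriminator
#'
#' Fits a support-vector machine separating `positive` examples from the
#' rest. Features are standardized (per-column center/scale estimated on
#' the training rows and stored with the model, so the identical transform
#' is applied at prediction time). When `cost` or `gamma` are vectors, the
#' pair is selected by stratified inner cross-validation on the training
#' data (accuracy at threshold 0; ties favor the smaller cost, then the
#' smaller gamma). Class imbalance is handled by per-class weights
#' inversely proportional to class size (`class_balance = "weight"`, the
#' default) or by seeded subsampling of the majority class to match the
#' minority (`"subsample"`).
#'
#' @param x Numeric feature matrix, one row per example.
#' @param y Character/factor labels.
#' @param positive Label treated as the positive class.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param cost SVM cost parameter(s) `C > 0`; a vector triggers tuning.
#' @param gamma RBF width parameter(s); a vector triggers tuning. Ignored
#'   for the linear kernel. Default `1 / ncol(x)`.
#' @param class_balance `"weight"`, `"subsample"`, or `"none"`.
#' @param tune_folds Folds for the inner tuning CV.
#' @param feature_mode Optional feature-mode tag stored with the model.
#' @param seed Integer seed controlling tuning folds and subsampling.
#' @return An `oxyprot_model`: the decision function's support vectors,
#'   dual coefficients, offset, kernel parameters, scaler, and training
#'   metadata. `decision_score()` applied to a model is deterministic.
#' @export
train_binary <- function(x, y, positive, kernel = c("rbf", "linear"),
                         cost = 10, gamma = NULL,
                         class_balance = c("weight", "subsample", "none"),
                         tune_folds = 3L, feature_mode = NULL, seed = 1L) {
  kernel <- match.arg(kernel)
  class_balance <- match.arg(class_balance)
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("feature matrix contains non-finite values")
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  yb <- ifelse(y == positive, positive, paste0("not_", positive))
  if (length(unique(yb)) < 2L) stop("training data contains a single class")
  if (min(table(yb)) < 2L) stop("need >= 2 examples per class")
  if (is.null(gamma)) gamma <- 1 / ncol(x)

  if (class_balance == "subsample") {
    tab <- table(yb)
    nmin <- min(tab)
    keep <- with_seed(seed, unlist(lapply(names(tab), function(cl) {
      idx <- which(yb == cl)
      if (length(idx) > nmin) sort(sample(idx, nmin)) else idx
    })))
    keep <- sort(keep)
    x <- x[keep, , drop = FALSE]
    yb <- yb[keep]
  }

  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale_, "/")

  cw <- NULL
  if (class_balance == "weight") {
    tab <- table(yb)
    cw <- as.numeric(length(yb) / (2 * tab))
    names(cw) <- names(tab)
  }

  if (length(cost) > 1L || (kernel == "rbf" && length(gamma) > 1L)) {
    best <- tune_svm_grid(xs, yb, positive, kernel, cost,
                          if (kernel == "rbf") gamma else 0,
                          cw, tune_folds, seed)
    cost <- best$cost
    gamma <- best$gamma
  } else {
    cost <- cost[1]; gamma <- gamma[1]
  }

  m <- fit_svm_raw(xs, yb, positive, kernel, cost, gamma, cw)
  m$center <- center
  m$scale <- scale_
  m$feature_mode <- feature_mode
  m$meta <- list(n_pos = sum(yb == positive), n_neg = sum(yb != positive),
                 seed = as.integer(seed), class_balance = class_balance)
  m$train_scores <- decision_score(m, x)
  m
}

# Fit on pre-standardized features and extract a self-contained decision
# function (support vectors, dual coefs, offset, sign convention).
fit_svm_raw <- function(xs, yb, positive, kernel, cost, gamma, class_weights) {
  yf <- factor(yb)
  fit <- e1071::svm(xs, yf,
                    kernel = if (kernel == "rbf") "radial" else "linear",
                    cost = cost, gamma = if (kernel == "rbf") gamma else 1,
                    scale = FALSE, class.weights = class_weights,
                    probability = FALSE)
  dv <- attr(stats::predict(fit, xs[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  first <- strsplit(colnames(dv), "/")[[1]][1]
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 positive_label = positive,
                 sv = unname(as.matrix(fit$SV)),
                 coefs = as.numeric(fit$coefs), rho = as.numeric(fit$rho),
                 sign = if (identical(first, positive)) 1 else -1),
            class = "oxyprot_model")
}

# Inner-CV grid selection; ties broken toward smaller cost then gamma.
tune_svm_grid <- function(xs, yb, positive, kernel, costs, gammas,
                          class_weights, k, seed) {
  grid <- expand.grid(gamma = sort(gammas), cost = sort(costs))
  plan <- make_folds(yb, k = k, repeats = 1L, seed = seed, stratified = TRUE)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (f in seq_len(k)) {
      te <- plan$assignment[1, ] == f
      m <- fit_svm_raw(xs[!te, , drop = FALSE], yb[!te], positive,
                       kernel, grid$cost[g], grid$gamma[g], class_weights)
      s <- svm_scores(m, xs[te, , drop = FALSE])
      correct <- correct + sum((s >= 0) == (yb[te] == positive))
    }
    correct / length(yb)
  }, numeric(1))
  best <- grid[order(-acc, grid$cost, grid$gamma)[1], ]
  list(cost = best$cost, gamma = best$gamma)
}

# Decision values on already-standardized rows.
svm_scores <- function(m, xs) {
  k <- if (m$kernel == "linear") {
    m$sv %*% t(xs)
  } else {
    # exp(-gamma * ||u - v||^2), computed via the expansion
    d2 <- outer(rowSums(m$sv^2), rowSums(xs^2), "+") - 2 * m$sv %*% t(xs)
    exp(-m$gamma * pmax(d2, 0))
  }
  m$sign * (drop(crossprod(m$coefs, k)) - m$rho)
}

#' Raw SVM decision score for feature vectors
#'
#' The uncalibrated margin `f(x)`; larger values are more positive-class
#' like, and `sign(f)` is the predicted class at threshold 0. Batch scoring
#' of a matrix equals per-row scoring.
#'
#' @param m An `oxyprot_model`.
#' @param x Feature vector (length = model dimension) or matrix with one
#'   row per example.
#' @return Numeric vector of decision scores.
#' @export
decision_score <- function(m, x) {
  stopifnot(inherits(m, "oxyprot_model"))
  if (is.null(dim(x))) {
    xmode <- attr(x, "mode")
    if (!is.null(xmode) && !is.null(m$feature_mode) &&
        !identical(xmode, m$feature_mode)) {
      stop("feature mode mismatch: model is ", m$feature_mode,
           ", input is ", xmode)
    }
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != length(m$center)) {
    stop("feature dimension mismatch: model expects ", length(m$center),
         ", got ", ncol(x))
  }
  xs <- sweep(sweep(x, 2, m$center, "-"), 2, m$scale, "/")
  svm_scores(m, xs)
}

#' Predict the binary label at a decision threshold
#'
#' @inheritParams decision_score
#' @param threshold Decision cutoff; an example is called positive iff its
#'   score is `>= threshold`.
#' @return Character vector, `"positive"` / `"negative"`.
#' @export
predict_label <- function(m, x, threshold = 0) {
  ifelse(decision_score(m, x) >= threshold, "positive", "negative")
}

#' @export
print.oxyprot_model <- function(x, ...) {
  cat("oxyprot_model:", x$positive_label, "vs rest;", x$kernel,
      "kernel, C =", x$cost,
      if (x$kernel == "rbf") paste(", gamma =", signif(x$gamma, 4)) else "",
      ";", nrow(x$sv), "support vectors\n")
  invisible(x)
}

#' Train the full model bundle: binary plus six sub-class discriminators
#'
#' Trains the oxygen-binding vs non-binding model on the whole dataset and
#' one one-vs-rest model per oxy sub-class present. The sub-class models'
#' negatives are, by default, the other five sub-classes only
#' (`negative_policy = "oxy_rest"`), reflecting that sub-class models
#' discriminate among oxygen-binding proteins; `"oxy_rest_plus_nonoxy"`
#' adds the non-oxy pool to each negative set.
#'
#' @param dataset A `labeled_dataset` containing all six sub-classes and a
#'   `NONOXY` pool.
#' @param feature_mode One of `"AC"`, `"DC"`, `"PSSM"`, `"HYBRID"`.
#' @param pssms Named list of `pssm` objects (PSSM mode only).
#' @param negative_policy `"oxy_rest"` or `"oxy_rest_plus_nonoxy"`.
#' @inheritParams train_binary
#' @return An `oxyprot_bundle`: list with `binary`, `subclass` (named list
#'   of six models), `feature_mode`, and training metadata.
#' @export
train_bundle <- function(dataset, feature_mode = "AC", pssms = NULL,
                         kernel = "rbf", cost = 10, gamma = NULL,
                         negative_policy = c("oxy_rest", "oxy_rest_plus_nonoxy"),
                         class_balance = "weight", seed = 1L) {
  negative_policy <- match.arg(negative_policy)
  missing_cls <- setdiff(OXY_CLASSES, unique(dataset$label))
  if (length(missing_cls) > 0L) {
    stop("missing sub-class(es): ", paste(missing_cls, collapse = ", "))
  }
  if (!any(dataset$label == NONOXY_LABEL)) {
    stop("missing sub-class(es): ", NONOXY_LABEL)
  }
  fm <- encode_dataset(dataset, mode = feature_mode, pssms = pssms)
  ybin <- binary_labels(dataset)
  binary <- train_binary(fm$x, ybin, positive = "OXY", kernel = kernel,
                         cost = cost, gamma = gamma,
                         class_balance = class_balance,
                         feature_mode = feature_mode, seed = seed)
  oxy_rows <- ybin == "OXY"
  subclass <- lapply(OXY_CLASSES, function(cl) {
    rows <- if (negative_policy == "oxy_rest") oxy_rows else rep(TRUE, nrow(fm$x))
    train_binary(fm$x[rows, , drop = FALSE], dataset$label[rows],
                 positive = cl, kernel = kernel, cost = cost, gamma = gamma,
                 class_balance = class_balance, feature_mode = feature_mode,
                 seed = seed)
  })
  names(subclass) <- OXY_CLASSES
  structure(list(binary = binary, subclass = subclass,
                 feature_mode = feature_mode,
                 negative_policy = negative_policy,
                 class_sizes = as.list(table(dataset$label)),
                 seed = as.integer(seed)),
            class = "oxyprot_bundle")
}

#' @export
print.oxyprot_bundle <- function(x, ...) {
  cat("oxyprot_bundle (", x$feature_mode, " features): binary OXY model + ",
      length(x$subclass), " sub-class models\n", sep = "")
  invisible(x)
}

#' Classify one protein sequence with a trained bundle
#'
#' Scores the sequence with the binary oxygen-binding model and all six
#' sub-class models. The sub-class call is the argmax of the sub-class
#' scores, ties broken by the fixed class order
#' `ERY < HCY < HEME < HEMO < LEG < MYO`; if no sub-class score reaches its
#' threshold the call is flagged (`above_threshold = FALSE`) but the
#' binary result is still reported.
#'
#' @param bundle An `oxyprot_bundle`.
#' @param seq Cleaned residue string.
#' @param pssm A `pssm` object for the sequence (required in PSSM mode).
#' @param thresholds Decision threshold(s): a scalar applied to every
#'   model, or a named vector with entries `OXY` and/or sub-class names.
#' @return List with `binary_score`, `binary_label`, `scores` (six
#'   sub-class scores, ranked descending), `call`, `above_threshold`.
#' @export
classify_sequence <- function(bundle, seq, pssm = NULL, thresholds = 0) {
  stopifnot(inherits(bundle, "oxyprot_bundle"))
  thr <- function(name) {
    if (length(thresholds) == 1L && is.null(names(thresholds))) return(thresholds)
    thresholds[[name]] %||% 0
  }
  v <- switch(bundle$feature_mode,
    AC = aa_composition(seq),
    DC = dipeptide_composition(seq),
    HYBRID = hybrid_composition(seq),
    PSSM = {
      if (is.null(pssm)) stop("PSSM-mode bundle requires a pssm for the query")
      if (!isTRUE(attr(pssm, "normalized"))) pssm <- normalize_pssm(pssm)
      pssm_composition(pssm)
    })
  bscore <- decision_score(bundle$binary, v)
  sub <- vapply(bundle$subclass, decision_score, numeric(1), x = v)
  # argmax in fixed class order: order() is stable, so ties keep class order
  ranked <- sub[order(-sub)]
  call <- OXY_CLASSES[which.max(sub[OXY_CLASSES])]
  above <- sub[call] >= thr(call)
  list(binary_score = unname(bscore),
       binary_label = if (bscore >= thr("OXY")) "OXY" else NONOXY_LABEL,
       scores = ranked, call = call, above_threshold = unname(above))
}

# ---- persistence ----

write_model_file <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("kernel\t", m$kernel),
    paste0("cost\t", fmt_num(m$cost)),
    paste0("gamma\t", fmt_num(m$gamma)),
    paste0("rho\t", fmt_num(m$rho)),
    paste0("sign\t", m$sign),
    paste0("positive_label\t", m$positive_label),
    paste0("feature_mode\t", m$feature_mode %||% "NA"),
    paste0("center\t", paste(fmt_num(m$center), collapse = "\t")),
    paste0("scale\t", paste(fmt_num(m$scale), collapse = "\t")),
    paste0("coefs\t", paste(fmt_num(m$coefs), collapse = "\t")),
    "SV"), con)
  for (i in seq_len(nrow(m$sv))) {
    writeLines(paste(fmt_num(m$sv[i, ]), collapse = "\t"), con)
  }
}

read_model_file <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t")
  key <- vapply(kv, `[`, character(1), 1L)
  val <- function(k) kv[[which(key == k)[1]]][-1]
  sv_start <- which(key == "SV")[1]
  sv <- do.call(rbind, lapply(kv[seq(sv_start + 1L, length(kv))], as.numeric))
  fmode <- val("feature_mode")
  structure(list(kernel = val("kernel"),
                 cost = as.numeric(val("cost")),
                 gamma = as.numeric(val("gamma")),
                 positive_label = val("positive_label"),
                 sv = sv, coefs = as.numeric(val("coefs")),
                 rho = as.numeric(val("rho")),
                 sign = as.numeric(val("sign")),
                 center = as.numeric(val("center")),
                 scale = as.numeric(val("scale")),
                 feature_mode = if (identical(fmode, "NA")) NULL else fmode),
            class = "oxyprot_model")
}

#' Persist a model bundle as a directory of text files
#'
#' Writes a JSON manifest (feature mode, negative policy, class sizes,
#' seed) plus one parameter file per model. Numbers are stored in full
#' precision: a save / load round trip reproduces decision scores exactly.
#'
#' @param bundle An `oxyprot_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "oxyprot_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(feature_mode = bundle$feature_mode,
                   negative_policy = bundle$negative_policy,
                   class_sizes = bundle$class_sizes,
                   seed = bundle$seed,
                   kernel = bundle$binary$kernel,
                   hyperparams = list(
                     note = "kernel and parameters unspecified in source publication; package defaults recorded per model"),
                   models = c("OXY", OXY_CLASSES))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_model_file(bundle$binary, file.path(dir, "model_OXY.tsv"))
  for (cl in OXY_CLASSES) {
    write_model_file(bundle$subclass[[cl]],
                     file.path(dir, paste0("model_", cl, ".tsv")))
  }
  invisible(dir)
}

#' Load a model bundle saved by [save_bundle()]
#'
#' @param dir Bundle directory.
#' @return An `oxyprot_bundle`.
#' @export
load_bundle <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  binary <- read_model_file(file.path(dir, "model_OXY.tsv"))
  subclass <- lapply(OXY_CLASSES, function(cl) {
    read_model_file(file.path(dir, paste0("model_", cl, ".tsv")))
  })
  names(subclass) <- OXY_CLASSES
  structure(list(binary = binary, subclass = subclass,
                 feature_mode = mf$feature_mode,
                 negative_policy = mf$negative_policy,
                 class_sizes = mf$class_sizes, seed = mf$seed),
            class = "oxyprot_bundle")
}
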