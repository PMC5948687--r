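# Shared fixtures and independent brute-force oracles.

rand_seq <- function(L, prob = NULL) {
  paste(sample(AA_ALPHABET20, L, replace = TRUE, prob = prob), collapse = "")
}

rand_pssm <- function(L, id = "p", lo = -10L, hi = 12L) {
  pssm_matrix(id, rand_seq(L),
              matrix(sample(lo:hi, L * 20L, replace = TRUE), nrow = L))
}

# Counting oracles, written as direct per-letter loops (independent of the
# tabulate()-based encoders).
oracle_ac <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  vapply(AA_ALPHABET20, function(a) sum(chars == a), numeric(1)) / length(chars)
}

oracle_dc <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  v <- stats::setNames(numeric(400L),
                       as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, paste0))))
  for (i in seq_len(L - 1L)) {
    key <- paste0(chars[i], chars[i + 1L])
    v[key] <- v[key] + 1
  }
  v / (L - 1L)
}

# Double loop over positions and target columns.
oracle_pssm_comp <- function(norm) {
  chars <- strsplit(norm$residues, "")[[1]]
  L <- length(chars)
  v <- numeric(400L)
  for (i in seq_len(L)) {
    r <- match(chars[i], AA_ALPHABET20)
    for (cc in 1:20) {
      v[(r - 1L) * 20L + cc] <- v[(r - 1L) * 20L + cc] + norm$scores[i, cc]
    }
  }
  v / L
}

# Metric oracles by reconstructing the label/prediction vectors: accuracy is
# a mean of agreements, MCC the Pearson correlation of the binary vectors.
oracle_metrics <- function(tp, tn, fp, fn) {
  truth <- c(rep(1, tp + fn), rep(0, tn + fp))
  pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  mcc <- suppressWarnings(stats::cor(truth, pred))
  list(ACC = mean(truth == pred),
       Sen = if (tp + fn > 0) mean(pred[truth == 1]) else NaN,
       Sep = if (tn + fp > 0) mean(1 - pred[truth == 0]) else NaN,
       MCC = if (is.na(mcc)) 0 else mcc)
}

# Mann-Whitney pairwise AUC oracle.
oracle_auc <- function(scores, labels, positive = "OXY") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# A two-blob feature set that is linearly separable by a wide margin.
separable_toy <- function(n = 20L, d = 5L, gap = 6) {
  x <- rbind(matrix(stats::rnorm(n * d, gap), ncol = d),
             matrix(stats::rnorm(n * d, -gap), ncol = d))
  list(x = x, y = rep(c("OXY", "NONOXY"), each = n))
}

# Small labeled dataset covering all seven classes.
tiny_dataset <- function(n_per_class = 8L, seed = 42L, separation = "strong") {
  make_benchmark(default_profiles(separation), n_per_class = n_per_class,
                 seed = seed, make_pssms = FALSE)$dataset
}
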