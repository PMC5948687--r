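# Background amino-acid frequencies (approximate database-wide averages),
# alphabet order ACDEFGHIKLMNPQRSTVWY.
BASE_AA_FREQ <- c(
  A = 0.078, C = 0.019, D = 0.053, E = 0.063, F = 0.040,
  G = 0.072, H = 0.022, I = 0.053, K = 0.059, L = 0.091,
  M = 0.024, N = 0.043, P = 0.052, Q = 0.040, R = 0.051,
  S = 0.068, T = 0.059, V = 0.066, W = 0.014, Y = 0.032)

# Two signature residues per sub-class that the generator enriches,
# echoing the kind of per-class composition shifts seen in real
# oxy-protein sets (e.g. alanine enrichment in leghemoglobin, lysine in
# hemoglobin, valine in myoglobin).
CLASS_SIGNATURES <- list(
  ERY = c("F", "E"), HCY = c("H", "R"), HEME = c("C", "M"),
  HEMO = c("K", "L"), LEG = c("A", "G"), MYO = c("V", "W"))

#' Construct a synthetic class profile
#'
#' @param label Class label.
#' @param composition Named 20-vector on the simplex (all entries > 0,
#'   summing to 1), alphabet order.
#' @param length_range Integer `(min, max)` sequence lengths, `min >= 2`.
#' @param coupling Optional 20 x 20 row-stochastic matrix of first-order
#'   residue transition probabilities; when set, sequences are generated as
#'   a Markov chain instead of i.i.d. draws.
#' @return A `class_profile` object.
#' @export
class_profile <- function(label, composition, length_range = c(80L, 300L),
                          coupling = NULL) {
  composition <- as.numeric(composition)
  stopifnot(length(composition) == 20L)
  if (any(composition <= 0)) stop("composition entries must be > 0")
  if (abs(sum(composition) - 1) > 1e-9) stop("composition must sum to 1")
  length_range <- as.integer(length_range)
  if (length_range[1] < 2L || length_range[1] > length_range[2]) {
    stop("need 2 <= min length <= max length")
  }
  if (!is.null(coupling)) {
    coupling <- as.matrix(coupling)
    stopifnot(nrow(coupling) == 20L, ncol(coupling) == 20L)
    if (any(abs(rowSums(coupling) - 1) > 1e-9)) {
      stop("coupling rows must sum to 1")
    }
  }
  names(composition) <- AA_ALPHABET20
  structure(list(label = label, composition = composition,
                 length_range = length_range, coupling = coupling),
            class = "class_profile")
}

#' Default synthetic class profiles
#'
#' Seven composition profiles -- one per oxy sub-class plus a background
#' non-oxy profile -- built from database-average residue frequencies with
#' two signature residues enriched per class. The enrichment per signature
#' residue is 0.02 (`weak`), 0.05 (`moderate`) or 0.12 (`strong`)
#' probability mass, so pairwise total-variation distance between class
#' compositions grows with the separation level; `strong` puts the
#' per-residue composition shift at roughly three standard errors of the
#' composition estimate at the shortest default length, i.e. the signal
#' clearly dominates sampling noise. Lengths default to 80--300 residues,
#' matching the 101--200 range that dominates real oxy-protein sets. The
#' function is deterministic.
#'
#' @param separation `"weak"`, `"moderate"` or `"strong"`.
#' @return Named list of seven `class_profile` objects
#'   (`ERY`, `HCY`, `HEME`, `HEMO`, `LEG`, `MYO`, `NONOXY`).
#' @export
default_profiles <- function(separation = c("strong", "moderate", "weak")) {
  separation <- match.arg(separation)
  delta <- switch(separation, weak = 0.02, moderate = 0.05, strong = 0.12)
  base <- BASE_AA_FREQ / sum(BASE_AA_FREQ)
  profs <- lapply(OXY_CLASSES, function(cl) {
    comp <- base
    comp[CLASS_SIGNATURES[[cl]]] <- comp[CLASS_SIGNATURES[[cl]]] + delta
    class_profile(cl, comp / sum(comp))
  })
  names(profs) <- OXY_CLASSES
  profs[[NONOXY_LABEL]] <- class_profile(NONOXY_LABEL, base)
  profs
}

#' Generate random protein sequences from a class profile
#'
#' Lengths are drawn uniformly from the profile's range; residues are
#' i.i.d. draws from the composition, or a first-order Markov chain when
#' the profile carries a coupling matrix (the chain starts from the
#' composition). Output is fully determined by the seed.
#'
#' @param profile A `class_profile`.
#' @param n Number of sequences (`>= 1`).
#' @param seed Integer seed.
#' @return Character vector of `n` residue strings.
#' @export
generate_sequences <- function(profile, n, seed = 1L) {
  stopifnot(inherits(profile, "class_profile"), n >= 1L)
  with_seed(seed, {
    lo <- profile$length_range[1]; hi <- profile$length_range[2]
    lens <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
    vapply(lens, function(L) {
      if (is.null(profile$coupling)) {
        paste(sample(AA_ALPHABET20, L, replace = TRUE,
                     prob = profile$composition), collapse = "")
      } else {
        idx <- integer(L)
        idx[1] <- sample.int(20L, 1L, prob = profile$composition)
        for (i in seq_len(L - 1L)) {
          idx[i + 1L] <- sample.int(20L, 1L, prob = profile$coupling[idx[i], ])
        }
        paste(AA_ALPHABET20[idx], collapse = "")
      }
    }, character(1))
  })
}

#' Build a labeled synthetic benchmark with pseudo-PSSMs
#'
#' Generates `n_per_class` sequences for each of the six oxy sub-classes
#' plus a non-oxy negative set sized `neg_multiplier` times the total
#' positive count (default 1.0, i.e. matched negative-set size), and one
#' pseudo-PSSM per sequence. All randomness derives from `seed`; the
#' returned manifest regenerates the benchmark identically.
#'
#' @param profiles Named list of `class_profile`s as from
#'   [default_profiles()].
#' @param n_per_class Positive sequences per sub-class.
#' @param neg_multiplier Negative-set size as a multiple of total positives.
#' @param seed Integer seed.
#' @param pssm_noise_sd Gaussian noise SD for [pseudo_pssm()].
#' @param make_pssms Set `FALSE` to skip profile synthesis (faster when
#'   only composition features are needed).
#' @return A `synthetic_benchmark`: list with `dataset` (a
#'   `labeled_dataset`), `pssms` (named list or `NULL`), `manifest`.
#' @export
make_benchmark <- function(profiles = default_profiles("strong"),
                           n_per_class = 50L, neg_multiplier = 1,
                           seed = 1L, pssm_noise_sd = 1,
                           make_pssms = TRUE) {
  stopifnot(n_per_class >= 1L)
  n_neg <- as.integer(round(neg_multiplier * 6L * n_per_class))
  labs <- c(OXY_CLASSES, NONOXY_LABEL)
  sizes <- stats::setNames(c(rep(n_per_class, 6L), n_neg), labs)
  # per-class sub-seeds derived once from the master seed
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                          length(labs) + 1L))
  ids <- character(0); seqs <- character(0); labels <- character(0)
  for (i in seq_along(labs)) {
    l <- labs[i]
    if (sizes[l] == 0L) next
    s <- generate_sequences(profiles[[l]], sizes[l], seed = sub_seeds[i])
    ids <- c(ids, sprintf("%s_%04d", l, seq_len(sizes[l])))
    seqs <- c(seqs, s)
    labels <- c(labels, rep(l, sizes[l]))
  }
  dataset <- labeled_dataset(ids, seqs, labels)
  pssms <- NULL
  if (make_pssms) {
    pssm_seeds <- with_seed(sub_seeds[length(labs) + 1L],
                            sample.int(.Machine$integer.max - 1L, length(ids)))
    pssms <- lapply(seq_along(ids), function(i) {
      pseudo_pssm(seqs[i], sequence_id = ids[i],
                  noise_sd = pssm_noise_sd, seed = pssm_seeds[i])
    })
    names(pssms) <- ids
  }
  manifest <- list(seed = as.integer(seed), n_per_class = as.integer(n_per_class),
                   neg_multiplier = neg_multiplier,
                   pssm_noise_sd = pssm_noise_sd,
                   class_sizes = as.list(sizes),
                   profile_labels = names(profiles))
  structure(list(dataset = dataset, pssms = pssms, manifest = manifest),
            class = "synthetic_benchmark")
}

#' Write a synthetic benchmark to disk
#'
#' Emits the same dialects the real pipeline consumes: a FASTA file, a
#' two-column id / label TSV, one ASCII PSSM file per sequence under
#' `pssm/`, and a plain-text key-value manifest.
#'
#' @param bench A `synthetic_benchmark`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "synthetic_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- bench$dataset
  write_fasta(ds$id, ds$seq, file.path(dir, "sequences.fasta"))
  utils::write.table(data.frame(id = ds$id, label = ds$label),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(bench$pssms)) {
    pd <- file.path(dir, "pssm")
    dir.create(pd, showWarnings = FALSE)
    for (id in names(bench$pssms)) {
      write_pssm(bench$pssms[[id]], file.path(pd, paste0(id, ".pssm")))
    }
  }
  mf <- bench$manifest
  flat <- c(seed = mf$seed, n_per_class = mf$n_per_class,
            neg_multiplier = mf$neg_multiplier,
            pssm_noise_sd = mf$pssm_noise_sd,
            stats::setNames(unlist(mf$class_sizes),
                            paste0("n_", names(mf$class_sizes))))
  writeLines(paste0(names(flat), "=", flat), file.path(dir, "manifest.txt"))
  invisible(dir)
}
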