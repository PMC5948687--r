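dc_names <- function() {
  as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, paste0)))
}

#' Amino-acid composition (AC, 20-d)
#'
#' Fraction of each of the 20 residues in the sequence, in alphabet order.
#' Entries are non-negative and sum to 1.
#'
#' @param seq Cleaned residue string, length >= 1.
#' @return Named numeric vector of length 20 with attribute `mode = "AC"`.
#' @export
aa_composition <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  idx <- match(chars, AA_ALPHABET20)
  if (anyNA(idx)) stop("non-canonical residue at position ", which(is.na(idx))[1])
  v <- tabulate(idx, nbins = 20L) / length(chars)
  names(v) <- AA_ALPHABET20
  structure(v, mode = "AC")
}

#' Dipeptide composition (DC, 400-d)
#'
#' Fraction of each ordered residue pair among the L-1 overlapping
#' dipeptides, indexed row-major with the first residue major (entry
#' `20*(i-1)+j` is the pair `aa_i aa_j`). Sums to 1 for any sequence of
#' length >= 2; shorter sequences are an error, not a zero vector.
#'
#' @param seq Cleaned residue string, length >= 2.
#' @return Named numeric vector of length 400 with attribute `mode = "DC"`.
#' @export
dipeptide_composition <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < 2L) stop("dipeptide composition requires length >= 2 (got ", L, ")")
  idx <- match(chars, AA_ALPHABET20)
  if (anyNA(idx)) stop("non-canonical residue at position ", which(is.na(idx))[1])
  pair <- (idx[-L] - 1L) * 20L + idx[-1L]
  v <- tabulate(pair, nbins = 400L) / (L - 1L)
  names(v) <- dc_names()
  structure(v, mode = "DC")
}

#' PSSM composition (PSSM-400)
#'
#' Reduces a normalized L x 20 profile to a fixed 400-d vector: entry
#' `(r, c)` is the sum, over positions whose sequence residue is `r`, of the
#' normalized score in column `c`, divided by L. Every entry lies in
#' `[0, 1]`.
#'
#' A simpler 20-d variant (per-column mean over all positions) is available
#' via `reduced = TRUE`.
#'
#' @param norm A normalized `pssm` object (see [normalize_pssm()]).
#' @param reduced If `TRUE` return the 20-d column-mean variant.
#' @return Named numeric vector of length 400 (or 20) with attribute
#'   `mode = "PSSM"`.
#' @export
pssm_composition <- function(norm, reduced = FALSE) {
  stopifnot(inherits(norm, "pssm"))
  if (!isTRUE(attr(norm, "normalized"))) {
    stop("pssm_composition expects a normalized PSSM; call normalize_pssm() first")
  }
  sc <- norm$scores
  L <- nrow(sc)
  if (reduced) {
    v <- colMeans(sc)
    names(v) <- AA_ALPHABET20
    return(structure(v, mode = "PSSM"))
  }
  idx <- match(strsplit(norm$residues, "")[[1]], AA_ALPHABET20)
  m <- matrix(0, nrow = 20L, ncol = 20L)
  agg <- rowsum(sc, group = idx)
  m[as.integer(rownames(agg)), ] <- agg
  v <- as.vector(t(m)) / L
  names(v) <- paste0(rep(AA_ALPHABET20, each = 20L), ".", AA_ALPHABET20)
  structure(v, mode = "PSSM")
}

#' Hybrid AC-DC composition (420-d)
#'
#' Concatenation of the amino-acid composition (first 20 entries) and the
#' dipeptide composition (remaining 400).
#'
#' @param seq Cleaned residue string, length >= 2.
#' @return Named numeric vector of length 420 with attribute
#'   `mode = "HYBRID"`.
#' @export
hybrid_composition <- function(seq) {
  v <- c(aa_composition(seq), dipeptide_composition(seq))
  structure(v, mode = "HYBRID")
}

feature_dim <- function(mode) {
  switch(mode, AC = 20L, DC = 400L, PSSM = 400L, HYBRID = 420L,
         stop("unknown feature mode: ", mode))
}

#' Encode a dataset into a feature matrix
#'
#' Applies one of the four encoders to every record of a labeled dataset,
#' preserving row order and labels. PSSM mode requires one profile per
#' sequence id in `pssms`; profiles are normalized internally.
#'
#' @param dataset A `labeled_dataset`.
#' @param mode One of `"AC"`, `"DC"`, `"PSSM"`, `"HYBRID"`.
#' @param pssms Named list of `pssm` objects keyed by sequence id (PSSM mode
#'   only; raw or normalized).
#' @return A `feature_matrix`: list with `mode`, numeric matrix `x`
#'   (rownames = ids), and `labels`.
#' @export
encode_dataset <- function(dataset, mode = c("AC", "DC", "PSSM", "HYBRID"),
                           pssms = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  mode <- match.arg(mode)
  n <- nrow(dataset)
  enc <- switch(mode,
    AC = function(i) aa_composition(dataset$seq[i]),
    DC = function(i) dipeptide_composition(dataset$seq[i]),
    HYBRID = function(i) hybrid_composition(dataset$seq[i]),
    PSSM = function(i) {
      id <- dataset$id[i]
      p <- pssms[[id]]
      if (is.null(p)) stop("missing PSSM profile for sequence id: ", id)
      if (!isTRUE(attr(p, "normalized"))) p <- normalize_pssm(p)
      pssm_composition(p)
    })
  rows <- lapply(seq_len(n), enc)
  x <- do.call(rbind, rows)
  rownames(x) <- dataset$id
  structure(list(mode = mode, x = x, labels = dataset$label),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$x), "sequences x", ncol(x$x),
      "features (mode", x$mode, ")\n")
  invisible(x)
}

#' Write a feature matrix as TSV or SVM-light sparse format
#'
#' TSV output carries a header naming every feature (and the dipeptide
#' indexing convention in a comment line). The sparse format is the
#' classic `label index:value` layout with 1-based indices, using +1 for
#' `positive_label` rows and -1 otherwise.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @param format `"tsv"` or `"svmlight"`.
#' @param positive_label Label mapped to +1 in sparse output.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, format = c("tsv", "svmlight"),
                                 positive_label = "OXY") {
  stopifnot(inherits(fm, "feature_matrix"))
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# mode=", fm$mode,
                      " dipeptide_indexing=row-major,first-residue-major,",
                      "alphabet=", paste(AA_ALPHABET20, collapse = "")), con)
    writeLines(paste(c("id", "label", colnames(fm$x)), collapse = "\t"), con)
    lab <- fm$labels %||% rep(NA_character_, nrow(fm$x))
    for (i in seq_len(nrow(fm$x))) {
      writeLines(paste(c(rownames(fm$x)[i], lab[i], fmt_num(fm$x[i, ])),
                       collapse = "\t"), con)
    }
  } else {
    is_pos <- if (identical(positive_label, "OXY")) {
      fm$labels %in% OXY_CLASSES | fm$labels == "OXY"
    } else fm$labels == positive_label
    lines <- vapply(seq_len(nrow(fm$x)), function(i) {
      v <- fm$x[i, ]
      nz <- which(v != 0)
      paste(c(if (is_pos[i]) "+1" else "-1",
              paste0(nz, ":", fmt_num(v[nz]))), collapse = " ")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a feature-matrix TSV written by [write_feature_matrix()]
#'
#' @param path Path to the TSV file.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  mode <- sub("^# mode=([A-Z]+) .*$", "\\1", lines[1])
  df <- utils::read.delim(text = lines[-1], stringsAsFactors = FALSE,
                          check.names = FALSE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(x) <- df$id
  labels <- df$label
  if (all(is.na(labels))) labels <- NULL
  structure(list(mode = mode, x = x, labels = labels),
            class = "feature_matrix")
}

#' Per-class median composition profile and pairwise differences
#'
#' For each class, the per-residue median of amino-acid composition,
#' reported in percent (fractions x 100) -- the standard way composition
#' differences between oxy-protein sub-classes are profiled (e.g. alanine
#' or lysine enrichment in individual sub-classes). Also returns the
#' antisymmetric table of pairwise differences between class medians.
#'
#' @param dataset A `labeled_dataset`.
#' @return List with `medians` (labels x 20 matrix, percent) and `diffs`
#'   (named list, one 20-vector per ordered label pair `"A-B"` equal to
#'   `medians[A,] - medians[B,]`).
#' @export
profile_report <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  labs <- sort(unique(dataset$label))
  ac <- t(vapply(dataset$seq, aa_composition, numeric(20L))) * 100
  med <- do.call(rbind, lapply(labs, function(l) {
    apply(ac[dataset$label == l, , drop = FALSE], 2, stats::median)
  }))
  rownames(med) <- labs
  diffs <- list()
  if (length(labs) > 1L) {
    for (a in labs) for (b in labs) {
      if (a != b) diffs[[paste0(a, "-", b)]] <- med[a, ] - med[b, ]
    }
  }
  list(medians = med, diffs = diffs)
}
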