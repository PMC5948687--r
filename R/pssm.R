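#' Construct a PSSM object
#'
#' An L x 20 position-specific scoring matrix for one sequence, with columns
#' fixed in the package alphabet order `ACDEFGHIKLMNPQRSTVWY` regardless of
#' the order the source file used.
#'
#' @param sequence_id Sequence id the profile belongs to.
#' @param residues Residue string of length L (the query sequence column of
#'   the profile).
#' @param scores Numeric L x 20 matrix in alphabet order.
#' @return An object of class `pssm`.
#' @export
pssm_matrix <- function(sequence_id, residues, scores) {
  residues <- toupper(as.character(residues))
  scores <- as.matrix(scores)
  L <- nchar(residues)
  if (L == 0L) stop("empty residue string")
  if (nrow(scores) != L) stop("row count (", nrow(scores),
                              ") != sequence length (", L, ")")
  if (ncol(scores) != 20L) stop("PSSM must have exactly 20 columns")
  chars <- strsplit(residues, "")[[1]]
  bad <- !(chars %in% AA_ALPHABET20)
  if (any(bad)) stop("non-canonical residue '", chars[which(bad)[1]],
                     "' at position ", which(bad)[1])
  dimnames(scores) <- list(NULL, AA_ALPHABET20)
  structure(list(sequence_id = as.character(sequence_id),
                 residues = residues, scores = scores),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM for", x$sequence_id, "-", nchar(x$residues), "positions",
      if (isTRUE(attr(x, "normalized"))) "(normalized)" else "", "\n")
  invisible(x)
}

# NCBI PSI-BLAST ascii PSSM column order (first score block)
NCBI_PSSM_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Parse an NCBI PSI-BLAST ASCII PSSM file
#'
#' Reads the first 20-column log-odds score block of a
#' `psiblast -out_ascii_pssm` file (files carrying the additional
#' weighted-observed-percentage block are accepted; only the first 20 score
#' columns are used). Columns are remapped from the file's header order to
#' the fixed alphabet `ACDEFGHIKLMNPQRSTVWY`.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence_id Id to attach; defaults to the file name without
#'   extension.
#' @return A [pssm_matrix()] object.
#' @export
parse_pssm <- function(path, sequence_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  # header row: >= 20 single-letter residue tokens
  is_header <- vapply(lines, function(l) {
    toks <- strsplit(trimws(l), "[ \t]+")[[1]]
    sum(toks %in% AA_ALPHABET20 & nchar(toks) == 1L) >= 20L
  }, logical(1), USE.NAMES = FALSE)
  hi <- which(is_header)[1]
  if (is.na(hi)) stop("malformed PSSM header: no residue column header found in ", path)
  header_toks <- strsplit(trimws(lines[hi]), "[ \t]+")[[1]]
  col_order <- header_toks[seq_len(20L)]
  if (!setequal(col_order, AA_ALPHABET20)) {
    stop("malformed PSSM header: first 20 columns are not the 20 amino acids")
  }
  res <- character(0)
  rows <- list()
  for (i in seq(hi + 1L, length(lines))) {
    l <- trimws(lines[i])
    if (l == "" || grepl("^(Lambda|K |Standard|PSI|Gapped)", l)) break
    toks <- strsplit(l, "[ \t]+")[[1]]
    if (length(toks) < 2L || is.na(suppressWarnings(as.integer(toks[1])))) break
    aa <- toks[2]
    if (!(aa %in% AA_ALPHABET20)) {
      stop("line ", i, ": residue '", aa, "' is not canonical")
    }
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (length(vals) < 20L || anyNA(vals[seq_len(20L)])) {
      stop("line ", i, ": truncated or malformed score row (",
           length(vals), " values)")
    }
    res <- c(res, aa)
    rows[[length(rows) + 1L]] <- vals[seq_len(20L)]
  }
  if (length(rows) == 0L) stop("no score rows found in ", path)
  scores <- do.call(rbind, rows)
  colnames(scores) <- col_order
  scores <- scores[, AA_ALPHABET20, drop = FALSE]
  if (is.null(sequence_id)) {
    sequence_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pssm_matrix(sequence_id, paste(res, collapse = ""), scores)
}

#' Write a PSSM in the NCBI ASCII dialect
#'
#' Emits the 20-column score block in the layout [parse_pssm()] reads,
#' using the NCBI column order. Numbers are written in full precision so a
#' write / parse round trip reproduces the matrix exactly.
#'
#' @param p A [pssm_matrix()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(p, path) {
  stopifnot(inherits(p, "pssm"))
  sc <- p$scores[, NCBI_PSSM_ORDER, drop = FALSE]
  chars <- strsplit(p$residues, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("Position-specific scoring matrix for ", p$sequence_id),
               paste(c("", "", NCBI_PSSM_ORDER), collapse = " ")), con)
  for (i in seq_len(nrow(sc))) {
    writeLines(paste(c(i, chars[i], fmt_num(sc[i, ])), collapse = " "), con)
  }
  invisible(path)
}

#' Min-max normalize a PSSM to the unit interval
#'
#' Rescales every score by `(value - min) / (max - min)` with the minimum
#' and maximum taken over the entire matrix, so the smallest score maps to 0
#' and the largest to 1. If all scores are equal the profile is degenerate:
#' all entries are mapped to 0 and a warning is issued rather than an error,
#' so pipelines survive low-complexity sequences.
#'
#' Per-column normalization (min/max within each of the 20 columns) is
#' available via `scope = "column"`.
#'
#' @param p A [pssm_matrix()] object.
#' @param scope `"matrix"` (default) or `"column"`.
#' @return A `pssm` object with values in `[0, 1]`, attributes `normalized`,
#'   `source_min` and `source_max`.
#' @export
normalize_pssm <- function(p, scope = c("matrix", "column")) {
  stopifnot(inherits(p, "pssm"))
  scope <- match.arg(scope)
  sc <- p$scores
  if (length(sc) == 0L) stop("empty matrix")
  rescale <- function(m, lo, hi) {
    if (hi > lo) (m - lo) / (hi - lo)
    else {
      warning("degenerate profile: max == min; mapped to all zeros")
      m * 0
    }
  }
  if (scope == "matrix") {
    lo <- min(sc); hi <- max(sc)
    out <- rescale(sc, lo, hi)
  } else {
    lo <- apply(sc, 2, min); hi <- apply(sc, 2, max)
    out <- sc
    for (j in seq_len(20L)) {
      if (hi[j] > lo[j]) out[, j] <- (sc[, j] - lo[j]) / (hi[j] - lo[j])
      else out[, j] <- 0
    }
    lo <- min(lo); hi <- max(hi)
  }
  q <- pssm_matrix(p$sequence_id, p$residues, out)
  attr(q, "normalized") <- TRUE
  attr(q, "source_min") <- lo
  attr(q, "source_max") <- hi
  q
}

# BLOSUM62 restricted to the 20 canonical residues, alphabet order.
blosum62_20 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA_ALPHABET20, AA_ALPHABET20]
    }
    cache
  }
})

#' Synthesize a pseudo-PSSM for a sequence
#'
#' Stands in for PSI-BLAST output when no profile is available (this package
#' never runs PSI-BLAST): row i is the substitution-matrix row of the
#' residue at position i plus i.i.d. Gaussian noise. This gives a profile
#' whose row pattern carries exactly the residue identity plus noise, which
#' is the signal the PSSM-composition encoder is designed to read.
#'
#' @param seq Residue string (cleaned).
#' @param sequence_id Id to attach.
#' @param sub_matrix 20 x 20 substitution matrix in alphabet order; defaults
#'   to BLOSUM62.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (`>= 0`; 0 gives the substitution rows exactly).
#' @param seed Integer seed; the same seed always yields the same matrix.
#' @return A [pssm_matrix()] object.
#' @export
pseudo_pssm <- function(seq, sequence_id = "synthetic", sub_matrix = NULL,
                        noise_sd = 1, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(sub_matrix)) sub_matrix <- blosum62_20()
  sub_matrix <- as.matrix(sub_matrix)
  stopifnot(nrow(sub_matrix) == 20L, ncol(sub_matrix) == 20L)
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, AA_ALPHABET20)
  if (anyNA(idx)) stop("non-canonical residue at position ", which(is.na(idx))[1])
  base <- sub_matrix[idx, , drop = FALSE]
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(length(base), 0, noise_sd),
                                    nrow = nrow(base)))
    base <- base + noise
  }
  pssm_matrix(sequence_id, seq, base)
}
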