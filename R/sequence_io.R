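#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file. The id of each
#' record is the header text up to the first whitespace; the full header is
#' kept in the `desc` column. Sequence lines are concatenated and uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `desc` and `seq`, one row per
#'   record, in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 myoglobin", "ACDE"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  desc <- names(set)
  id <- vapply(strsplit(desc, "[ \t]+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty) > 0L) {
    stop("FASTA record with empty sequence: ", paste(id[empty], collapse = ", "))
  }
  data.frame(id = id, desc = desc, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param ids Character vector of record ids (written as headers).
#' @param seqs Character vector of residue strings, same length as `ids`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path, width = 60L) {
  stopifnot(length(ids) == length(seqs))
  set <- Biostrings::AAStringSet(as.character(seqs))
  names(set) <- as.character(ids)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Clean a raw residue string to the 20-letter amino-acid alphabet
#'
#' Uppercases the input and handles characters outside the 20 canonical
#' amino-acid letters (ambiguity codes B, J, O, U, X, Z, stop `*`, gaps, and
#' anything else) according to `policy`:
#' * `"strict"`: any non-canonical character is an error, reported with its
#'   position.
#' * `"drop_ambiguous"` (default): non-canonical characters are removed and a
#'   warning reports how many were dropped.
#'
#' The operation is idempotent: cleaning a cleaned sequence is a no-op.
#'
#' @param raw Residue string.
#' @param policy `"drop_ambiguous"` or `"strict"`.
#' @return The cleaned, uppercased residue string.
#' @export
clean_sequence <- function(raw, policy = c("drop_ambiguous", "strict")) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1L || nchar(raw) == 0L) {
    stop("raw must be a non-empty character scalar")
  }
  up <- toupper(raw)
  chars <- strsplit(up, "")[[1]]
  bad <- !(chars %in% AA_ALPHABET20)
  if (!any(bad)) return(up)
  if (policy == "strict") {
    stop("non-canonical residue '", chars[which(bad)[1]],
         "' at position ", which(bad)[1])
  }
  out <- paste(chars[!bad], collapse = "")
  if (nchar(out) == 0L) stop("sequence empty after dropping ambiguous residues")
  warning("dropped ", sum(bad), " non-canonical residue(s)")
  out
}

#' Construct a labeled protein dataset
#'
#' Bundles sequences with class labels and validates the invariants every
#' downstream stage relies on: unique ids, residues restricted to the
#' 20-letter alphabet, and labels drawn from the six oxy-protein sub-classes
#' plus the non-oxy negative class (arbitrary label sets are allowed when
#' `check_labels = FALSE`). Duplicate residue strings are legal but reported
#' with a warning, since the public sequence sets the method targets can
#' contain cross-class duplicates.
#'
#' @param ids Character vector of unique sequence ids.
#' @param seqs Character vector of cleaned residue strings.
#' @param labels Character vector of class labels.
#' @param check_labels If `TRUE`, require labels to be among
#'   `c(OXY_CLASSES, NONOXY_LABEL)`.
#' @return A `labeled_dataset`: a data.frame with columns `id`, `seq`,
#'   `label` and attribute `label_set`.
#' @export
labeled_dataset <- function(ids, seqs, labels, check_labels = TRUE) {
  ids <- as.character(ids); seqs <- as.character(seqs)
  labels <- as.character(labels)
  stopifnot(length(ids) == length(seqs), length(ids) == length(labels))
  if (length(ids) == 0L) stop("empty dataset")
  dup <- duplicated(ids)
  if (any(dup)) stop("duplicate sequence ids: ",
                     paste(unique(ids[dup]), collapse = ", "))
  if (anyNA(labels) || any(labels == "")) stop("missing labels")
  if (check_labels) {
    bad <- setdiff(unique(labels), c(OXY_CLASSES, NONOXY_LABEL))
    if (length(bad) > 0L) stop("unknown label(s): ", paste(bad, collapse = ", "))
  }
  ok <- grepl(paste0("^[", paste(AA_ALPHABET20, collapse = ""), "]+$"), seqs)
  if (!all(ok)) {
    stop("non-canonical residues in sequence(s): ",
         paste(utils::head(ids[!ok], 5L), collapse = ", "))
  }
  if (anyDuplicated(seqs)) {
    warning("dataset contains ", sum(duplicated(seqs)),
            " duplicated residue string(s)")
  }
  out <- data.frame(id = ids, seq = seqs, label = labels,
                    stringsAsFactors = FALSE)
  attr(out, "label_set") <- sort(unique(labels))
  class(out) <- c("labeled_dataset", "data.frame")
  out
}

#' Binary oxygen-binding super-label of each record
#'
#' @param dataset A `labeled_dataset`.
#' @return Character vector, `"OXY"` for records whose label is one of the
#'   six sub-classes and `"NONOXY"` otherwise.
#' @export
binary_labels <- function(dataset) {
  ifelse(dataset$label %in% OXY_CLASSES, "OXY", NONOXY_LABEL)
}

#' Read a two-column id / label TSV companion file
#'
#' @param path Path to a TSV with columns `id` and `label` (header optional;
#'   detected from the first line).
#' @return data.frame with columns `id`, `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  first <- readLines(path, n = 1L)
  header <- grepl("^id\t", first)
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file must have two tab-separated columns")
  names(df)[1:2] <- c("id", "label")
  df[, c("id", "label")]
}

#' Per-class sequence-length histogram
#'
#' Counts sequences per class in half-open length bins
#' `[k*w + 1, (k+1)*w]`, the binning used to profile the length structure of
#' a sequence collection (most oxy-protein sets are dominated by the
#' 101--200 residue range).
#'
#' @param dataset A `labeled_dataset`.
#' @param bin_width Positive integer bin width.
#' @return Integer matrix, one row per label (sorted), one column per
#'   occupied length bin, column names like `"101-200"`. Row sums equal the
#'   per-label record counts.
#' @export
length_histogram <- function(dataset, bin_width = 100L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (nrow(dataset) == 0L) stop("empty dataset")
  bin_width <- as.integer(bin_width)
  if (bin_width < 1L) stop("bin_width must be >= 1")
  len <- nchar(dataset$seq)
  k <- (len - 1L) %/% bin_width          # bin index, 0-based
  kmax <- max(k)
  labs <- sort(unique(dataset$label))
  m <- matrix(0L, nrow = length(labs), ncol = kmax + 1L,
              dimnames = list(labs, paste0(0:kmax * bin_width + 1L, "-",
                                           (0:kmax + 1L) * bin_width)))
  tab <- table(factor(dataset$label, levels = labs),
               factor(k, levels = 0:kmax))
  m[] <- as.integer(tab)
  m
}
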