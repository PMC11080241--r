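# Sequence encodings: character-level label encoding for proteins and SMILES,
# BLOSUM row encoding for proteins, and scaling into the generator's tanh range.

#' Build a character vocabulary from a sequence corpus
#'
#' Characters observed anywhere in the corpus are collected, sorted, and
#' assigned contiguous integer indices starting at 1. Index 0 is reserved for
#' padding and one extra index (\code{unknown_index = n_symbols + 1}) absorbs
#' characters never seen in the corpus. Sorted assignment makes the mapping
#' deterministic across runs and corpus orderings.
#'
#' @param corpus non-empty character vector of non-empty sequences.
#' @param kind \code{"protein"} or \code{"smiles"}; recorded for provenance.
#' @return an object of class \code{seq_vocabulary} with fields
#'   \code{symbol_to_index} (named integer vector), \code{unknown_index},
#'   \code{pad_index} (always 0) and \code{kind}.
#' @export
build_vocabulary <- function(corpus, kind = c("protein", "smiles")) {
  kind <- match.arg(kind)
  check_that(is.character(corpus) && length(corpus) > 0, "corpus must be a non-empty character vector")
  check_that(all(nzchar(corpus)), "corpus sequences must be non-empty")
  symbols <- sort(unique(unlist(strsplit(corpus, "", fixed = TRUE))))
  idx <- seq_along(symbols)
  names(idx) <- symbols
  structure(list(kind = kind, symbol_to_index = idx,
                 unknown_index = length(symbols) + 1L, pad_index = 0L),
            class = "seq_vocabulary")
}

#' @export
print.seq_vocabulary <- function(x, ...) {
  cat(sprintf("<seq_vocabulary: %s, %d symbols + pad(0) + unknown(%d)>\n",
              x$kind, length(x$symbol_to_index), x$unknown_index))
  invisible(x)
}

#' Label-encode a sequence to a fixed-length integer vector
#'
#' Each character maps to its vocabulary index; characters outside the
#' vocabulary map to \code{unknown_index}. The sequence keeps its prefix when
#' longer than \code{max_len} and is right-padded with 0 when shorter.
#'
#' @param seq a single character string.
#' @param vocab a \code{seq_vocabulary}.
#' @param max_len fixed output length (>= 1).
#' @return integer vector of length \code{max_len} with attribute
#'   \code{original_length} (pre-truncation length).
#' @export
label_encode <- function(seq, vocab, max_len) {
  check_that(inherits(vocab, "seq_vocabulary"), "vocab must be a seq_vocabulary")
  check_that(is.numeric(max_len) && length(max_len) == 1 && max_len >= 1,
             "max_len must be >= 1", "gandta_config_error")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  v <- unname(vocab$symbol_to_index[chars])
  v[is.na(v)] <- vocab$unknown_index
  out <- integer(max_len)
  keep <- min(n, max_len)
  if (keep > 0) out[seq_len(keep)] <- v[seq_len(keep)]
  structure(as.integer(out), original_length = n)
}

#' Decode a label-encoded vector back to a string
#'
#' Drops padding; in-vocabulary indices map back to their characters, the
#' unknown index renders as \code{"?"}.
#' @param encoded integer vector from \code{\link{label_encode}}.
#' @param vocab the vocabulary used to encode.
#' @return a character string.
#' @export
label_decode <- function(encoded, vocab) {
  v <- encoded[encoded != vocab$pad_index]
  syms <- names(vocab$symbol_to_index)[v]
  syms[v == vocab$unknown_index] <- "?"
  paste(syms, collapse = "")
}

# Encode many sequences into an n x max_len integer matrix (rows = sequences).
#' Label-encode a set of sequences into a matrix
#' @inheritParams label_encode
#' @param seqs character vector.
#' @return integer matrix (length(seqs) x max_len).
#' @export
label_encode_matrix <- function(seqs, vocab, max_len) {
  out <- matrix(0L, length(seqs), max_len)
  for (i in seq_along(seqs)) out[i, ] <- label_encode(seqs[i], vocab, max_len)
  rownames(out) <- names(seqs)
  out
}

#' Affinely scale label encodings into the generator's tanh range
#'
#' The GAN generator ends in tanh, so real inputs must live in [-1, 1]. The
#' map is x -> 2 x / unknown_index - 1: padding (0) lands exactly on -1 and
#' the unknown index exactly on +1.
#'
#' @param encoded integer vector or matrix of label encodings.
#' @param vocab the vocabulary that produced them.
#' @return numeric object of the same shape with values in [-1, 1].
#' @export
scale_to_gan_range <- function(encoded, vocab) {
  check_that(all(encoded >= 0 & encoded <= vocab$unknown_index),
             "encoded values must lie in [0, unknown_index]")
  2 * encoded / vocab$unknown_index - 1
}

#' Load a substitution matrix from a plain-text fixture
#'
#' The bundled file \code{blosum62_25.txt} is BLOSUM62 extended to a 25-letter
#' alphabet (20 standard residues plus B, Z, X, U, O) and is the single source
#' of truth for the alphabet order. Format: '#' comment lines, a header row of
#' symbols, then one row per symbol.
#'
#' @param path path to the matrix file; default: the bundled BLOSUM62.
#' @return an object of class \code{blosum_matrix}: a symmetric 25 x 25 integer
#'   matrix with row/column names giving the alphabet.
#' @export
blosum_matrix <- function(path = system.file("extdata", "blosum62_25.txt", package = "gandta")) {
  check_that(nzchar(path) && file.exists(path), "matrix file not found")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  alphabet <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- length(alphabet)
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  check_that(length(rows) == n, "matrix row count does not match header")
  m <- matrix(0L, n, n, dimnames = list(alphabet, alphabet))
  for (r in rows) m[r[1], ] <- as.integer(r[-1])
  check_that(isSymmetric(unname(m)), "substitution matrix must be symmetric")
  check_that(!anyDuplicated(alphabet), "alphabet symbols must be distinct")
  structure(m, class = c("blosum_matrix", class(m)))
}

#' BLOSUM-encode a protein as a 25 x max_len matrix
#'
#' Column j holds the substitution-matrix row of residue j (its evolutionary
#' feature vector). Residues outside the matrix alphabet use the 'X' row.
#' Columns beyond the sequence length are all-zero; sequences longer than
#' \code{max_len} keep their prefix.
#'
#' @param protein a protein sequence string.
#' @param matrix a \code{\link{blosum_matrix}}.
#' @param max_len fixed number of columns (>= 1).
#' @return numeric 25 x max_len matrix with attribute \code{original_length}.
#' @export
blosum_encode <- function(protein, matrix = blosum_matrix(), max_len) {
  check_that(is.numeric(max_len) && length(max_len) == 1 && max_len >= 1,
             "max_len must be >= 1", "gandta_config_error")
  alphabet <- rownames(matrix)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- matrix(0, length(alphabet), max_len)
  keep <- min(n, max_len)
  if (keep > 0) {
    idx <- match(chars[seq_len(keep)], alphabet)
    idx[is.na(idx)] <- match("X", alphabet)
    out[, seq_len(keep)] <- t(unclass(matrix)[idx, , drop = FALSE])
  }
  rownames(out) <- alphabet
  structure(out, original_length = n)
}

# Stack BLOSUM encodings as an (n, max_len, 25) array, channels-last, for the
# network branches. scale = TRUE min-max rescales into [-1, 1] using the
# matrix's global range (GAN input on BLOSUM channels); raw integers otherwise.
#' BLOSUM-encode a set of proteins into a 3-d array
#' @inheritParams blosum_encode
#' @param proteins character vector of sequences.
#' @param scale if TRUE, min-max scale scores into [-1, 1] for GAN input.
#' @return numeric array (length(proteins), max_len, 25).
#' @export
blosum_encode_array <- function(proteins, matrix = blosum_matrix(), max_len, scale = FALSE) {
  n <- length(proteins)
  out <- array(0, c(n, max_len, nrow(matrix)))
  for (i in seq_len(n)) out[i, , ] <- t(blosum_encode(proteins[i], matrix, max_len))
  if (scale) {
    lo <- min(matrix); hi <- max(matrix)
    out <- 2 * (out - lo) / (hi - lo) - 1
  }
  out
}
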