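# Readers and writers for the plain-text formats the pipeline touches:
# FASTA, one-SMILES-per-line text, and TSV tables (tab-separated, UTF-8,
# '#' comment lines ignored). Readers reject malformed input rather than
# silently coercing it.

read_tsv_checked <- function(path, required) {
  check_that(file.exists(path), paste("file not found:", path))
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character",
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  check_that(length(missing) == 0,
             paste0(path, ": missing column(s) ", paste(missing, collapse = ", ")),
             "gandta_format_error")
  df
}

parse_numeric_column <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(!is.finite(v))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-numeric %s '%s' on row %d", path, col, df[[col]][bad[1]], bad[1]),
          "gandta_format_error")
  }
  v
}

#' Read a FASTA file
#'
#' Parsing is delegated to \code{Biostrings::readBStringSet}; the wrapper
#' enforces the format contract: the first non-blank line must be a header,
#' every record must have a non-empty sequence, wrapped sequence lines are
#' concatenated, record order is preserved, and the id is the first
#' whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file.
#' @return named character vector (id -> sequence).
#' @export
read_fasta <- function(path) {
  check_that(file.exists(path), paste("file not found:", path))
  lines <- readLines(path)
  nonblank <- lines[nzchar(trimws(lines))]
  check_that(length(nonblank) > 0, paste0(path, ": empty file"), "gandta_format_error")
  check_that(startsWith(nonblank[1], ">"),
             paste0(path, ": first non-blank line is not a '>' header"), "gandta_format_error")
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  check_that(all(nzchar(seqs)), paste0(path, ": record with empty sequence"),
             "gandta_format_error")
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a SMILES text file
#'
#' One SMILES per line, optionally followed by a tab- or space-separated
#' identifier (.smi convention). Missing identifiers become D001, D002, ...
#' '#' comment and blank lines are skipped.
#'
#' @param path path to the file.
#' @return named character vector (id -> SMILES).
#' @export
read_smiles <- function(path) {
  check_that(file.exists(path), paste("file not found:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  check_that(length(lines) > 0, paste0(path, ": no SMILES records"), "gandta_format_error")
  parts <- strsplit(trimws(lines), "\\s+")
  smi <- vapply(parts, `[`, "", 1)
  ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  if (anyNA(ids)) ids <- sprintf("D%03d", seq_along(smi))
  names(smi) <- ids
  smi
}

#' Read an affinity pair table
#'
#' TSV with header columns \code{drug_id}, \code{protein_id} and
#' \code{affinity} (pKd). Non-numeric affinities are rejected with the
#' offending row number.
#'
#' @param path path to the TSV.
#' @return data.frame of records.
#' @export
read_affinity_table <- function(path) {
  df <- read_tsv_checked(path, c("drug_id", "protein_id", "affinity"))
  data.frame(drug_id = df$drug_id, protein_id = df$protein_id,
             affinity = parse_numeric_column(df, "affinity", path),
             stringsAsFactors = FALSE)
}

#' Read a per-drug logP table
#'
#' TSV with header columns \code{drug_id} and \code{logp}; duplicate ids and
#' non-numeric values are format errors.
#'
#' @param path path to the TSV.
#' @return named numeric vector (drug_id -> logP).
#' @export
read_logp_table <- function(path) {
  df <- read_tsv_checked(path, c("drug_id", "logp"))
  dup <- df$drug_id[duplicated(df$drug_id)]
  check_that(length(dup) == 0,
             paste0(path, ": duplicate drug_id ", dup[1]), "gandta_format_error")
  v <- parse_numeric_column(df, "logp", path)
  names(v) <- df$drug_id
  v
}

#' Read a fixture bundle into an affinity dataset
#'
#' Expects the layout written by \code{\link{write_fixture_bundle}}:
#' \code{proteins.fasta}, \code{drugs.smi}, \code{affinities.tsv} and an
#' optional \code{logp.tsv}.
#'
#' @param dir bundle directory.
#' @return an \code{\link{affinity_dataset}}.
#' @export
read_fixture_bundle <- function(dir) {
  check_that(dir.exists(dir), paste("directory not found:", dir))
  proteins <- read_fasta(file.path(dir, "proteins.fasta"))
  drugs <- read_smiles(file.path(dir, "drugs.smi"))
  records <- read_affinity_table(file.path(dir, "affinities.tsv"))
  lp_path <- file.path(dir, "logp.tsv")
  logp <- if (file.exists(lp_path)) read_logp_table(lp_path) else NULL
  affinity_dataset(records, drugs, proteins, logp = logp)
}
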