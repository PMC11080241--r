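# Desk-scale synthetic corpora and labeled affinity datasets with a planted,
# recoverable drug x protein interaction signal.
#
# The planted signal is affinity = mu + beta * count(motif in protein) *
# indicator(pharmacophore in drug SMILES) + Gaussian noise, clipped to a
# pKd-like range. A motif-count x substring-indicator interaction is learnable
# by the kernel-8/4 convolutions, invisible to a mean predictor, and destroyed
# by label shuffling -- exactly the structure the straw-model controls need.

SMILES_ATOMS <- c("C", "N", "O", "c", "n", "o")

#' Synthetic dataset configuration
#'
#' Defaults describe the stated desk-scale world: 2000 labeled pairs over 60
#' proteins and 100 drugs, protein lengths 48-64 over the 25-letter residue
#' alphabet, SMILES-like strings of length 24-40, a planted interaction with
#' effect size beta = 2 on a baseline of pKd 5.5, Gaussian noise sd 0.3, and
#' affinities clipped to [4, 11] (straddling the binarization threshold 7).
#'
#' @param n_proteins,n_drugs,n_pairs entity and record counts
#'   (\code{n_pairs <= n_proteins * n_drugs}).
#' @param protein_len_range,smiles_len_range inclusive length intervals.
#' @param motif protein substring planted as the target-side signal carrier.
#' @param pharmacophore SMILES substring (atom tokens only) planted as the
#'   drug-side signal carrier.
#' @param beta interaction effect size (pKd units per motif copy).
#' @param mu baseline pKd.
#' @param sigma Gaussian noise standard deviation.
#' @param affinity_clip clipping interval for generated pKd.
#' @param seed RNG seed.
#' @return an object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_proteins = 60L, n_drugs = 100L, n_pairs = 2000L,
                             protein_len_range = c(48L, 64L),
                             smiles_len_range = c(24L, 40L),
                             motif = "WKHFWK", pharmacophore = "NCNO",
                             beta = 2, mu = 5.5, sigma = 0.3,
                             affinity_clip = c(4, 11), seed = 1L) {
  check_that(n_pairs <= n_proteins * n_drugs, "n_pairs exceeds n_proteins * n_drugs",
             "gandta_config_error")
  check_that(sigma >= 0, "sigma must be >= 0", "gandta_config_error")
  check_that(diff(protein_len_range) >= 0 && diff(smiles_len_range) >= 0,
             "length ranges must be non-empty", "gandta_config_error")
  check_that(all(strsplit(pharmacophore, "")[[1]] %in% c(SMILES_ATOMS, "=")),
             "pharmacophore may only use atom/bond tokens", "gandta_config_error")
  structure(list(n_proteins = as.integer(n_proteins), n_drugs = as.integer(n_drugs),
                 n_pairs = as.integer(n_pairs),
                 protein_len_range = as.integer(protein_len_range),
                 smiles_len_range = as.integer(smiles_len_range),
                 motif = motif, pharmacophore = pharmacophore,
                 beta = beta, mu = mu, sigma = sigma,
                 affinity_clip = affinity_clip, seed = as.integer(seed)),
            class = "synthetic_config")
}

protein_alphabet <- function() rownames(blosum_matrix())

# One syntactically well-formed SMILES-like string of exact length L:
# atoms from the fixed token set, '=' only after an atom, balanced
# parentheses (depth <= 2), matched ring-closure digits 1 and 2.
random_smiles <- function(L) {
  out <- character(L)
  pos <- 0L
  depth <- 0L
  open_rings <- integer(0)
  last_atom <- FALSE
  emit <- function(tok) { pos <<- pos + 1L; out[pos] <<- tok }
  while (pos < L) {
    remaining <- L - pos
    need_close <- depth + length(open_rings)
    if (remaining <= need_close) {
      if (depth > 0L) { emit(")"); depth <- depth - 1L }
      else { emit(as.character(open_rings[1])); open_rings <- open_rings[-1] }
      next
    }
    r <- stats::runif(1)
    if (last_atom && r < 0.08 && remaining > need_close + 1L) {
      emit("="); last_atom <- FALSE
    } else if (last_atom && r < 0.16 && depth < 2L && remaining > need_close + 2L) {
      emit("("); depth <- depth + 1L; last_atom <- FALSE
    } else if (last_atom && r < 0.26 && depth > 0L) {
      emit(")"); depth <- depth - 1L
    } else if (last_atom && r < 0.32 && length(open_rings) < 2L && remaining > need_close + 2L) {
      d <- setdiff(1:2, open_rings)[1]
      emit(as.character(d)); open_rings <- c(open_rings, d)
    } else if (last_atom && r < 0.38 && length(open_rings) > 0L) {
      emit(as.character(open_rings[1])); open_rings <- open_rings[-1]
    } else {
      emit(sample(SMILES_ATOMS, 1L)); last_atom <- TRUE
    }
  }
  paste(out, collapse = "")
}

#' Generate an unlabeled sequence corpus
#'
#' Proteins are drawn uniformly over the 25-letter residue alphabet; SMILES
#' strings come from the fixed token set \{C, N, O, c, n, o, =, (, ), 1, 2\}
#' with balanced parentheses and matched ring digits. Lengths are uniform over
#' \code{len_range}. Deterministic given \code{seed}.
#'
#' @param kind \code{"protein"} or \code{"smiles"}.
#' @param n number of sequences (>= 1).
#' @param len_range inclusive integer interval of lengths.
#' @param seed RNG seed.
#' @return character vector of length n.
#' @export
generate_corpus <- function(kind = c("protein", "smiles"), n, len_range, seed = 1L) {
  kind <- match.arg(kind)
  check_that(is.numeric(n) && length(n) == 1 && n >= 1, "n must be >= 1", "gandta_config_error")
  set.seed(derive_seed(seed, paste0("corpus_", kind)))
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  if (kind == "protein") {
    ab <- protein_alphabet()
    vapply(lens, function(L) paste(sample(ab, L, replace = TRUE), collapse = ""), "")
  } else {
    vapply(lens, random_smiles, "")
  }
}

# Substitute `sub` over a same-length slice. For SMILES the slice must be a
# run of atom/bond tokens so parenthesis/ring balance is preserved; proteins
# have no structural constraints.
plant_substring <- function(seq, sub, smiles = FALSE) {
  k <- nchar(sub)
  n <- nchar(seq)
  if (n < k) return(seq)
  if (smiles) {
    chars <- strsplit(seq, "")[[1]]
    plain <- chars %in% c(SMILES_ATOMS, "=")
    ok <- which(vapply(seq_len(n - k + 1L), function(i) all(plain[i:(i + k - 1L)]), TRUE))
    if (length(ok) == 0) return(NA_character_)
    pos <- ok[sample.int(length(ok), 1L)]
  } else {
    pos <- sample.int(n - k + 1L, 1L)
  }
  paste0(substr(seq, 1, pos - 1L), sub, substr(seq, pos + k, n))
}

count_substring <- function(s, sub) {
  lengths(regmatches(s, gregexpr(sub, s, fixed = TRUE)))
}

#' Deterministic logP-like surrogate from a SMILES string
#'
#' A transparent lipophilicity stand-in for cold-start splitting:
#' 0.5 x #carbons (C, c) - 0.3 x #oxygens (O, o) - 0.3 x #nitrogens (N, n).
#' It rewards carbon content and penalizes heteroatoms, loosely mimicking how
#' octanol/water partitioning scales with hydrophobic surface.
#'
#' @param smiles non-empty SMILES string (vectorized).
#' @return numeric surrogate logP.
#' @export
compute_logp_surrogate <- function(smiles) {
  check_that(is.character(smiles) && length(smiles) >= 1 && all(nzchar(smiles)),
             "smiles must be non-empty strings")
  cnt <- function(s, chars) {
    vapply(strsplit(s, ""), function(v) sum(v %in% chars), 0)
  }
  0.5 * cnt(smiles, c("C", "c")) - 0.3 * cnt(smiles, c("O", "o")) -
    0.3 * cnt(smiles, c("N", "n"))
}

#' Generate a labeled synthetic affinity dataset
#'
#' Builds protein and drug corpora, plants the motif into a controlled
#' fraction of proteins (40\% none, 40\% one copy, 20\% two copies) and the
#' pharmacophore into half the drugs, samples \code{n_pairs} distinct
#' (drug, protein) combinations and assigns
#' \code{affinity = mu + beta * count(motif) * has_pharmacophore + noise},
#' clipped to \code{affinity_clip}. A surrogate logP is attached per drug.
#' Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return an \code{\link{affinity_dataset}} whose records carry an extra
#'   \code{signal} column (the noiseless planted term, for diagnostics).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  check_that(inherits(config, "synthetic_config"), "config must be a synthetic_config",
             "gandta_config_error")
  proteins <- generate_corpus("protein", config$n_proteins, config$protein_len_range,
                              seed = config$seed)
  drugs <- generate_corpus("smiles", config$n_drugs, config$smiles_len_range,
                           seed = config$seed)
  set.seed(derive_seed(config$seed, "plant_and_label"))
  # plant motif copies: 40% none / 40% one / 20% two
  copies <- sample(c(0L, 1L, 2L), config$n_proteins, replace = TRUE, prob = c(.4, .4, .2))
  for (i in seq_len(config$n_proteins)) {
    for (j in seq_len(copies[i])) proteins[i] <- plant_substring(proteins[i], config$motif)
  }
  # plant pharmacophore into half the drugs; re-draw strings lacking a
  # substitutable atom run (rare at these lengths)
  has_pharm <- sample(c(TRUE, FALSE), config$n_drugs, replace = TRUE)
  for (i in which(has_pharm)) {
    planted <- plant_substring(drugs[i], config$pharmacophore, smiles = TRUE)
    while (is.na(planted)) {
      drugs[i] <- random_smiles(nchar(drugs[i]))
      planted <- plant_substring(drugs[i], config$pharmacophore, smiles = TRUE)
    }
    drugs[i] <- planted
  }
  names(proteins) <- sprintf("P%03d", seq_len(config$n_proteins))
  names(drugs) <- sprintf("D%03d", seq_len(config$n_drugs))
  # sample distinct pairs
  all_pairs <- expand.grid(d = seq_len(config$n_drugs), p = seq_len(config$n_proteins))
  pick <- all_pairs[sample.int(nrow(all_pairs), config$n_pairs), ]
  # signal recomputed from the emitted sequences (planting may overlap chance
  # occurrences, so counts are measured, not assumed)
  motif_count <- count_substring(proteins, config$motif)
  pharm_ind <- as.integer(count_substring(drugs, config$pharmacophore) > 0)
  signal <- config$beta * motif_count[pick$p] * pharm_ind[pick$d]
  affinity <- config$mu + signal + stats::rnorm(config$n_pairs, 0, config$sigma)
  affinity <- pmin(pmax(affinity, config$affinity_clip[1]), config$affinity_clip[2])
  records <- data.frame(drug_id = names(drugs)[pick$d],
                        protein_id = names(proteins)[pick$p],
                        affinity = affinity, signal = signal,
                        stringsAsFactors = FALSE)
  logp <- compute_logp_surrogate(drugs)
  names(logp) <- names(drugs)
  ds <- affinity_dataset(records, drugs, proteins, logp = logp)
  ds$config <- config
  ds
}

#' Write a synthetic dataset as a standard fixture bundle
#'
#' Emits \code{proteins.fasta}, \code{drugs.smi} (SMILES, id per line),
#' \code{affinities.tsv} (drug_id, protein_id, affinity),
#' \code{logp.tsv} (drug_id, logp) and \code{manifest.json} with the
#' generating parameters.
#'
#' @param dataset an \code{\link{affinity_dataset}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_fixture_bundle <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$protein_seqs, file.path(dir, "proteins.fasta"))
  writeLines(paste(dataset$drug_seqs, names(dataset$drug_seqs), sep = "\t"),
             file.path(dir, "drugs.smi"))
  utils::write.table(dataset$records[, c("drug_id", "protein_id", "affinity")],
                     file.path(dir, "affinities.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$logp)) {
    utils::write.table(data.frame(drug_id = names(dataset$logp), logp = dataset$logp),
                       file.path(dir, "logp.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- if (!is.null(dataset$config)) unclass(dataset$config) else list()
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
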