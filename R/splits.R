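# Affinity dataset container and data-splitting strategies: warm-start k-fold
# cross-validation at the pair level, logP-based cold-start drug exclusion,
# and shuffled-label straw-model controls.

#' Construct an affinity dataset
#'
#' Bundles (drug_id, protein_id, pKd) records with the sequence lookup tables
#' and an optional per-drug logP map. Every record id must resolve and all
#' affinities must be finite.
#'
#' @param records data.frame with columns \code{drug_id}, \code{protein_id},
#'   \code{affinity}.
#' @param drug_seqs named character vector: drug_id -> SMILES.
#' @param protein_seqs named character vector: protein_id -> sequence.
#' @param logp optional named numeric vector: drug_id -> logP.
#' @return an object of class \code{affinity_dataset}.
#' @export
affinity_dataset <- function(records, drug_seqs, protein_seqs, logp = NULL) {
  check_that(is.data.frame(records) &&
               all(c("drug_id", "protein_id", "affinity") %in% names(records)),
             "records needs columns drug_id, protein_id, affinity")
  check_that(all(is.finite(records$affinity)), "affinities must be finite")
  check_that(all(records$drug_id %in% names(drug_seqs)), "unresolved drug_id in records")
  check_that(all(records$protein_id %in% names(protein_seqs)), "unresolved protein_id in records")
  if (!is.null(logp)) check_that(all(is.finite(logp)), "logP values must be finite")
  records$drug_id <- as.character(records$drug_id)
  records$protein_id <- as.character(records$protein_id)
  rownames(records) <- NULL
  structure(list(records = records, drug_seqs = drug_seqs,
                 protein_seqs = protein_seqs, logp = logp),
            class = "affinity_dataset")
}

#' @export
print.affinity_dataset <- function(x, ...) {
  cat(sprintf("<affinity_dataset: %d pairs, %d drugs, %d proteins%s>\n",
              nrow(x$records), length(x$drug_seqs), length(x$protein_seqs),
              if (is.null(x$logp)) "" else ", with logP"))
  invisible(x)
}

new_split <- function(train, test, rule, params) {
  structure(list(train = as.integer(train), test = as.integer(test),
                 provenance = c(list(rule = rule), params)),
            class = "split_result")
}

#' Warm-start k-fold cross-validation splits
#'
#' Random record-level (pair-level) partition into k folds of sizes differing
#' by at most one; drugs and proteins may recur across folds (warm start).
#' Fold i serves as the held-out set, the remaining folds as training.
#' Deterministic given \code{seed}.
#'
#' @param dataset an \code{\link{affinity_dataset}}.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return list of k \code{split_result}s (train/test index vectors with
#'   provenance).
#' @export
kfold_split <- function(dataset, k = 5, seed = 1L) {
  n <- nrow(dataset$records)
  check_that(k >= 2, "k must be >= 2", "gandta_config_error")
  check_that(k <= n, sprintf("k = %d exceeds the %d records", k, n), "gandta_config_error")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  lapply(seq_len(k), function(i) {
    new_split(which(fold != i), which(fold == i), "kfold",
              list(k = k, fold = i, seed = seed))
  })
}

#' Cold-start split by drug lipophilicity (logP)
#'
#' Every record whose drug's logP falls in the half-open interval [lo, hi)
#' goes to the test side; all other records train. No drug appears on both
#' sides, so test drugs are never seen during training (cold start on the
#' physicochemical axis).
#'
#' @param dataset an \code{\link{affinity_dataset}}.
#' @param interval numeric [lo, hi); use \code{Inf} for an open upper end.
#'   Alternatively a string \code{"top<q>"} (e.g. \code{"top20"}) selecting the
#'   drugs in the upper q percent of the logP distribution (interval
#'   [quantile, Inf)).
#' @param logp optional named numeric vector overriding \code{dataset$logp}.
#' @return a \code{split_result}; provenance records the resolved interval.
#' @export
cold_start_logp_split <- function(dataset, interval, logp = NULL) {
  if (is.null(logp)) logp <- dataset$logp
  check_that(!is.null(logp), "no logP table available")
  drugs <- unique(dataset$records$drug_id)
  missing <- setdiff(drugs, names(logp))
  check_that(length(missing) == 0,
             paste("missing logP for drugs:", paste(utils::head(missing, 5), collapse = ", ")))
  if (is.character(interval)) {
    check_that(grepl("^top[0-9.]+$", interval), "interval string must look like 'top20'",
               "gandta_config_error")
    q <- as.numeric(sub("^top", "", interval)) / 100
    interval <- c(unname(stats::quantile(logp[drugs], 1 - q)), Inf)
  }
  check_that(is.numeric(interval) && length(interval) == 2 && interval[1] < interval[2],
             "interval must be numeric [lo, hi) with lo < hi", "gandta_config_error")
  lp <- logp[dataset$records$drug_id]
  in_test <- lp >= interval[1] & lp < interval[2]
  if (!any(in_test) || all(in_test)) {
    abort("degenerate cold-start split: empty train or test side", "gandta_degenerate_split")
  }
  new_split(which(!in_test), which(in_test), "cold_start_logp",
            list(lo = interval[1], hi = interval[2]))
}

#' Shuffled-affinity straw-model copies
#'
#' Returns a copy of the dataset in which affinity values inside the selected
#' partition(s) of a split are permuted uniformly at random (independent
#' permutations for train and test under \code{mode = "both"}). Drug/protein
#' assignments are untouched and the multiset of affinities in each partition
#' is preserved, so any retained predictive performance on the shuffled copy
#' signals leakage or artifacts.
#'
#' @param dataset an \code{\link{affinity_dataset}}.
#' @param split a \code{split_result}; if NULL, the whole record set is
#'   treated as the single partition (mode must be \code{"train"}).
#' @param mode which partition(s) to shuffle: \code{"train"}, \code{"test"} or
#'   \code{"both"}.
#' @param seed RNG seed; same seed, same permutation.
#' @return an \code{affinity_dataset} with permuted affinities.
#' @export
shuffle_straw <- function(dataset, split = NULL, mode = c("train", "test", "both"), seed = 1L) {
  check_that(is.character(mode) && mode[1] %in% c("train", "test", "both"),
             paste0("invalid straw mode '", mode[1], "'"), "gandta_config_error")
  mode <- mode[1]
  if (is.null(split)) {
    check_that(mode == "train", "without a split only mode='train' (whole set) is defined",
               "gandta_config_error")
    split <- new_split(seq_len(nrow(dataset$records)), integer(0), "all", list())
  }
  set.seed(seed)
  out <- dataset
  permute <- function(idx) {
    check_that(length(idx) > 0, "target partition is empty")
    out$records$affinity[idx] <<- out$records$affinity[sample(idx)]
  }
  if (mode %in% c("train", "both")) permute(split$train)
  if (mode %in% c("test", "both")) permute(split$test)
  out
}

#' Serialize / read a set of splits as TSV plus JSON provenance
#'
#' Writes \code{splits.tsv} with columns (record_index, role, fold) and
#' \code{splits.json} with each split's provenance; \code{read_splits}
#' round-trips exactly.
#'
#' @param splits a \code{split_result} or list of them.
#' @param dir output directory.
#' @return \code{dir} invisibly (write); list of \code{split_result}s (read).
#' @export
write_splits <- function(splits, dir) {
  if (inherits(splits, "split_result")) splits <- list(splits)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(seq_along(splits), function(i) {
    s <- splits[[i]]
    data.frame(record_index = c(s$train, s$test),
               role = c(rep("train", length(s$train)), rep("test", length(s$test))),
               fold = i)
  }))
  utils::write.table(rows, file.path(dir, "splits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(lapply(splits, function(s) s$provenance),
                       file.path(dir, "splits.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_splits
#' @export
read_splits <- function(dir) {
  rows <- utils::read.delim(file.path(dir, "splits.tsv"))
  prov <- jsonlite::read_json(file.path(dir, "splits.json"), simplifyVector = TRUE)
  lapply(sort(unique(rows$fold)), function(i) {
    r <- rows[rows$fold == i, ]
    s <- new_split(r$record_index[r$role == "train"], r$record_index[r$role == "test"], "", list())
    s$provenance <- as.list(if (is.data.frame(prov)) prov[i, ] else prov[[i]])
    s
  })
}
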