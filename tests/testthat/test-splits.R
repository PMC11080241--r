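make_toy_dataset <- function(n_drugs = 6, n_prot = 4) {
  drugs <- setNames(replicate(n_drugs, paste(sample(c("C", "N", "O"), 8, TRUE), collapse = "")),
                    paste0("d", seq_len(n_drugs)))
  prots <- setNames(replicate(n_prot, paste(sample(LETTERS[1:20], 12, TRUE), collapse = "")),
                    paste0("p", seq_len(n_prot)))
  grid <- expand.grid(drug_id = names(drugs), protein_id = names(prots),
                      stringsAsFactors = FALSE)
  grid$affinity <- round(runif(nrow(grid), 4, 10), 2)
  affinity_dataset(grid, drugs, prots,
                   logp = setNames(seq_len(n_drugs) * 0.5, names(drugs)))
}

test_that("affinity_dataset validates ids and affinities", {
  set.seed(1)
  ds <- make_toy_dataset()
  expect_s3_class(ds, "affinity_dataset")
  bad <- ds$records
  bad$drug_id[1] <- "nope"
  expect_error(affinity_dataset(bad, ds$drug_seqs, ds$protein_seqs),
               class = "gandta_input_error")
  bad2 <- ds$records
  bad2$affinity[2] <- NaN
  expect_error(affinity_dataset(bad2, ds$drug_seqs, ds$protein_seqs),
               class = "gandta_input_error")
})

test_that("kfold_split partitions records evenly and reproducibly", {
  set.seed(2)
  ds <- make_toy_dataset()  # 24 records
  n <- nrow(ds$records)
  folds <- kfold_split(ds, k = 5, seed = 9)
  expect_length(folds, 5)
  test_sizes <- vapply(folds, function(s) length(s$test), 0L)
  expect_lte(diff(range(test_sizes)), 1)
  all_tests <- unlist(lapply(folds, `[[`, "test"))
  expect_identical(sort(all_tests), seq_len(n))  # each record exactly once
  for (s in folds) {
    expect_length(intersect(s$train, s$test), 0)
    expect_identical(sort(c(s$train, s$test)), seq_len(n))
  }
  expect_identical(kfold_split(ds, k = 5, seed = 9), folds)
  expect_false(identical(kfold_split(ds, k = 5, seed = 10), folds))
  expect_error(kfold_split(ds, k = n + 1, seed = 1), class = "gandta_config_error")
  expect_error(kfold_split(ds, k = 1, seed = 1), class = "gandta_config_error")
})

test_that("cold_start_logp_split sends the interval's drugs to test, disjointly", {
  set.seed(3)
  ds <- make_toy_dataset()  # logp d1..d6 = 0.5..3.0
  sp <- cold_start_logp_split(ds, c(2.5, Inf))  # d5, d6
  test_drugs <- unique(ds$records$drug_id[sp$test])
  train_drugs <- unique(ds$records$drug_id[sp$train])
  expect_setequal(test_drugs, c("d5", "d6"))
  expect_length(intersect(train_drugs, test_drugs), 0)
  expect_identical(sort(c(sp$train, sp$test)), seq_len(nrow(ds$records)))
  # half-open: a drug exactly at hi stays in train
  sp2 <- cold_start_logp_split(ds, c(1.0, 2.0))  # d2 (1.0), d3 (1.5); d4 (2.0) excluded
  expect_setequal(unique(ds$records$drug_id[sp2$test]), c("d2", "d3"))
  expect_error(cold_start_logp_split(ds, c(100, 200)), class = "gandta_degenerate_split")
  ds2 <- ds; ds2$logp <- ds$logp[-1]
  expect_error(cold_start_logp_split(ds2, c(2.5, Inf)), class = "gandta_input_error")
})

test_that("cold_start_logp_split understands quantile shorthand", {
  set.seed(4)
  ds <- make_toy_dataset(n_drugs = 10)
  sp <- cold_start_logp_split(ds, "top20")
  test_drugs <- unique(ds$records$drug_id[sp$test])
  expect_lte(length(test_drugs), 3)
  expect_gte(length(test_drugs), 1)
  expect_true(all(ds$logp[test_drugs] >= sp$provenance$lo))
})

test_that("shuffle_straw permutes affinities within partitions only", {
  set.seed(5)
  ds <- make_toy_dataset()
  sp <- kfold_split(ds, k = 4, seed = 2)[[1]]
  for (mode in c("train", "test", "both")) {
    sh <- shuffle_straw(ds, sp, mode = mode, seed = 33)
    # multiset preserved inside each partition
    for (part in c("train", "test")) {
      idx <- sp[[part]]
      touched <- mode %in% c(part, "both")
      expect_identical(sort(sh$records$affinity[idx]), sort(ds$records$affinity[idx]))
      if (!touched) expect_identical(sh$records$affinity[idx], ds$records$affinity[idx])
    }
    # sequences and pairing columns untouched
    expect_identical(sh$records$drug_id, ds$records$drug_id)
    expect_identical(sh$drug_seqs, ds$drug_seqs)
    # deterministic
    expect_identical(shuffle_straw(ds, sp, mode = mode, seed = 33)$records,
                     sh$records)
  }
  sh_tr <- shuffle_straw(ds, sp, mode = "train", seed = 33)
  expect_false(identical(sh_tr$records$affinity[sp$train], ds$records$affinity[sp$train]))
  expect_error(shuffle_straw(ds, sp, mode = "validation"), class = "gandta_config_error")
})

test_that("splits serialize round-trip exactly", {
  set.seed(6)
  ds <- make_toy_dataset()
  folds <- kfold_split(ds, k = 3, seed = 17)
  dir <- withr::local_tempdir()
  write_splits(folds, dir)
  back <- read_splits(dir)
  for (i in seq_along(folds)) {
    expect_identical(sort(back[[i]]$train), sort(folds[[i]]$train))
    expect_identical(sort(back[[i]]$test), sort(folds[[i]]$test))
    expect_equal(back[[i]]$provenance$seed, 17)
  }
})
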