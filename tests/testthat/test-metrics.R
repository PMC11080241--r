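test_that("step_h implements the three-branch step function", {
  expect_equal(step_h(0.3), 1)
  expect_equal(step_h(0), 0.5)
  expect_equal(step_h(-2), 0)
  expect_equal(step_h(c(-1, 0, 2)), c(0, 0.5, 1))
  expect_error(step_h(Inf), class = "gandta_input_error")
})

test_that("concordance_index matches hand-worked examples", {
  expect_equal(as.numeric(concordance_index(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(as.numeric(concordance_index(c(1, 2, 3), c(3, 2, 1))), 0)
  expect_equal(as.numeric(concordance_index(c(1, 2, 3), c(1, 3, 2))), 2 / 3)
  # prediction ties exercise the h(0) = 0.5 branch: frozen from enumeration
  ci <- concordance_index(c(1, 2, 3, 4), c(1, 2, 2, 3))
  expect_equal(as.numeric(ci), 11 / 12)
  expect_identical(attr(ci, "z"), 6)
  expect_error(concordance_index(c(2, 2, 2), c(1, 2, 3)),
               class = "gandta_undefined_statistic")
})

test_that("concordance_index equals the brute-force oracle on random vectors", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(3:25, 1)
    y <- sample(seq(4, 10, by = 0.5), n, replace = TRUE)   # ties in y
    f <- round(rnorm(n, y, 2), 1)                          # ties in predictions
    if (length(unique(y)) == 1) next
    o <- ci_oracle(y, f)
    ci <- concordance_index(y, f)
    expect_identical(as.numeric(ci), o$ci)
    expect_identical(attr(ci, "z"), o$z)
  }
})

test_that("CI is symmetric under prediction negation and monotone-invariant", {
  set.seed(7)
  y <- rnorm(40)
  f <- rnorm(40)  # continuous -> tie-free
  expect_equal(as.numeric(concordance_index(y, f)) +
                 as.numeric(concordance_index(y, -f)), 1)
  # strictly increasing transform leaves CI unchanged
  expect_equal(as.numeric(concordance_index(y, exp(2 * f + 1))),
               as.numeric(concordance_index(y, f)))
})

test_that("mean_squared_error matches the definition", {
  expect_equal(mean_squared_error(c(1, 2), c(1, 2)), 0)
  expect_equal(mean_squared_error(c(1, 3), c(0, 0)), 5)
  expect_error(mean_squared_error(c(1, 2), c(1, 2, 3)), class = "gandta_input_error")
})

test_that("binarize_affinities uses >= at the threshold", {
  expect_identical(binarize_affinities(c(6.9, 7.0, 7.1), 7), c(0L, 1L, 1L))
  expect_identical(binarize_affinities(c(1, 2), 7), c(0L, 0L))
  expect_identical(binarize_affinities(c(1, 2), -1e9), c(1L, 1L))
})

test_that("aupr is step-integrated average precision", {
  expect_equal(aupr(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(aupr(c(0, 1), c(0.9, 0.1)), 0.5)
  # frozen from explicit PR-curve enumeration
  expect_equal(aupr(c(1, 0, 1, 1, 0, 0), c(.9, .8, .7, .6, .5, .4)), 29 / 36)
  expect_error(aupr(c(1, 1), c(0.2, 0.3)), class = "gandta_undefined_statistic")
  # tied scores collapse into one threshold
  expect_equal(aupr(c(1, 0), c(0.5, 0.5)), 0.5)
})

test_that("rm_squared matches the through-origin oracle", {
  # p = y: all three metrics are 1
  y <- c(1, 2, 3, 5)
  expect_equal(rm_squared(y, y)$rm2, 1)
  # perfectly correlated but rescaled: r2 = 1, r0 drops, rm2 < 1
  r <- rm_squared(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$r2, 1)
  expect_equal(r$r02, 1)  # through-origin fit is exact for p = y/2
  expect_equal(r$rm2, 1)
  # frozen from an independent evaluation of the formulas (lm/cor)
  r2 <- rm_squared(c(5.1, 6.2, 7.3, 8.4, 6.8, 7.7), c(5.5, 6.0, 7.8, 8.1, 6.5, 7.2))
  expect_equal(r2$r2, 0.8775347062, tolerance = 1e-9)
  expect_equal(r2$r02, 0.8752385753, tolerance = 1e-9)
  expect_equal(r2$rm2, 0.8354850332, tolerance = 1e-9)
  expect_error(rm_squared(c(1, 2, 3), c(2, 2, 2)), class = "gandta_undefined_statistic")
})

test_that("r_m^2 never exceeds r^2 and equals it when r0^2 >= r^2", {
  set.seed(11)
  for (rep in 1:50) {
    y <- rnorm(20, 7, 1.5)
    p <- y + rnorm(20, 0, runif(1, 0.1, 2))
    r <- rm_squared(y, p)
    expect_lte(r$rm2, r$r2 + 1e-12)
    if (r$r02 >= r$r2) expect_equal(r$rm2, r$r2)
  }
})

test_that("monotone transforms preserve CI/AUPR/rm2-inputs but not MSE", {
  set.seed(3)
  y <- rnorm(30, 7, 1.5)
  p <- y + rnorm(30, 0, 0.8)
  tr <- 3 * p + 2  # strictly increasing
  expect_equal(as.numeric(concordance_index(y, tr)), as.numeric(concordance_index(y, p)))
  lab <- binarize_affinities(y, 7)
  expect_equal(aupr(lab, tr), aupr(lab, p))
  expect_false(isTRUE(all.equal(mean_squared_error(y, tr), mean_squared_error(y, p))))
})

test_that("evaluate aggregates the component metrics", {
  set.seed(21)
  y <- rnorm(40, 7, 1.5)
  p <- y + rnorm(40, 0, 0.5)
  rep <- evaluate(y, p, threshold = 7)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(rep$ci, as.numeric(concordance_index(y, p)))
  expect_equal(rep$mse, mean_squared_error(y, p))
  expect_equal(rep$aupr, aupr(binarize_affinities(y, 7), p))
  expect_equal(rep$rm2, rm_squared(y, p)$rm2)
  expect_identical(rep$z, ci_oracle(y, p)$z)  # brute-force comparable pairs
  expect_identical(rep$positives, sum(y >= 7))
  # perfect predictions, mixed classes
  perfect <- evaluate(y, y)
  expect_equal(perfect$ci, 1)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$aupr, 1)
  expect_equal(perfect$rm2, 1)
  expect_error(evaluate(rep(7, 5), rnorm(5)), class = "gandta_undefined_statistic")
  # single-class labels: AUPR recorded as NA, rest intact
  ylow <- runif(10, 4, 6)
  expect_true(is.na(evaluate(ylow, ylow + rnorm(10, 0, .1))$aupr))
})

test_that("evaluation reports serialize to JSON and TSV", {
  y <- c(5, 6, 7, 8); p <- c(5.2, 6.1, 6.8, 8.3)
  rep <- evaluate(y, p)
  paths <- write_evaluation_report(rep, file.path(withr::local_tempdir(), "report"))
  j <- jsonlite::read_json(paths[1], simplifyVector = TRUE)
  expect_equal(j$ci, rep$ci)
  expect_equal(j$rm2, rep$rm2)
  tsv <- read.delim(paths[2])
  expect_equal(tsv$mse, rep$mse)
})
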