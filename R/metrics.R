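# Evaluation statistics for affinity regression: concordance index, MSE,
# area under the precision-recall curve after pKd binarization, and the
# external-validation QSAR metric r_m^2.

#' Step function used by the concordance index
#'
#' h(x) = 1 for x > 0, 0.5 for x = 0, 0 for x < 0; vectorized.
#' @param x finite numeric vector.
#' @return numeric vector over \{0, 0.5, 1\}.
#' @export
step_h <- function(x) {
  check_that(is.numeric(x) && all(is.finite(x)), "x must be finite numeric")
  0.5 * (x == 0) + (x > 0)
}

#' Concordance index
#'
#' CI = (1/Z) * sum over ordered pairs with y_i > y_j of h(f_i - f_j), where Z
#' is the number of such strictly comparable pairs and h is
#' \code{\link{step_h}}: the probability-like score that predictions order
#' pairs the same way as the true affinities (ties in predictions count 0.5).
#' Tied true affinities contribute no comparable pairs.
#'
#' Exact, including tie handling; evaluated by sorting on y and summing the
#' step function blockwise.
#'
#' @param y true affinities (length >= 2, not all equal).
#' @param f predicted affinities, same length.
#' @return CI in [0, 1], with attribute \code{z} (comparable-pair count).
#' @export
concordance_index <- function(y, f) {
  check_that(length(y) == length(f), "y and f must have equal length")
  check_that(length(y) >= 2, "need at least 2 observations")
  check_that(all(is.finite(y)) && all(is.finite(f)), "inputs must be finite")
  n <- length(y)
  # group indices by y; pairs are comparable iff y-groups differ
  ry <- rank(y, ties.method = "min")
  tab <- table(ry)
  z <- (n * (n - 1) / 2) - sum(tab * (tab - 1) / 2)
  if (z == 0) abort("concordance index undefined: all true values are tied",
                    "gandta_undefined_statistic")
  s <- 0
  o <- order(y)
  ys <- y[o]; fs <- f[o]
  for (i in seq_len(n - 1)) {
    larger <- which(ys > ys[i])  # indices after i with strictly larger y
    if (length(larger)) s <- s + sum(step_h(fs[larger] - fs[i]))
  }
  structure(s / z, z = z)
}

#' Mean squared error
#' @param Y ground-truth vector.
#' @param P prediction vector of the same length.
#' @return mean((P - Y)^2).
#' @export
mean_squared_error <- function(Y, P) {
  check_that(length(Y) == length(P), "Y and P must have equal length")
  check_that(length(Y) >= 1, "need at least 1 observation")
  mean((P - Y)^2)
}

#' Binarize affinities at a pKd threshold
#'
#' Labels pairs as interacting (1) when pKd >= threshold (the boundary value
#' counts as positive), else 0. Default threshold 7.
#' @param y finite affinity vector.
#' @param threshold pKd cutoff.
#' @return integer 0/1 vector.
#' @export
binarize_affinities <- function(y, threshold = 7) {
  check_that(all(is.finite(y)), "affinities must be finite")
  as.integer(y >= threshold)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-function integration of the precision-recall curve over descending
#' unique score thresholds: AP = sum_k (R_k - R_{k-1}) P_k. No trapezoidal
#' interpolation (interpolated PR areas are biased upward).
#'
#' @param labels 0/1 vector with at least one positive and one negative.
#' @param scores real-valued scores, higher = more likely positive.
#' @return AUPR in (0, 1].
#' @export
aupr <- function(labels, scores) {
  check_that(length(labels) == length(scores), "labels and scores must have equal length")
  check_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  npos <- sum(labels == 1)
  if (npos == 0 || npos == length(labels)) {
    abort("AUPR undefined: labels contain a single class", "gandta_undefined_statistic")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  # thresholds at the last index of each tied score block
  cut <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  prec <- tp[cut] / (tp[cut] + fp[cut])
  rec <- tp[cut] / npos
  sum(diff(c(0, rec)) * prec)
}

#' Squared correlation metrics r^2, r0^2 and r_m^2
#'
#' r^2 is the squared Pearson correlation of (y, p). r0^2 is the
#' through-origin counterpart in Roy's convention with predictions on the
#' abscissa: slope k = sum(y p) / sum(p^2), r0^2 = 1 - sum((y - k p)^2) /
#' sum((y - mean(y))^2). Then r_m^2 = r^2 (1 - sqrt(max(0, r^2 - r0^2)));
#' the difference is clamped at 0 before the square root so r0^2 > r^2 gives
#' r_m^2 = r^2. A model is conventionally deemed satisfactory when
#' r_m^2 > 0.5.
#'
#' @param y true affinities (length >= 3, non-constant).
#' @param p predictions (non-constant).
#' @return list with elements \code{r2}, \code{r02}, \code{rm2}.
#' @export
rm_squared <- function(y, p) {
  check_that(length(y) == length(p) && length(y) >= 3, "need equal lengths >= 3")
  if (stats::sd(y) == 0 || stats::sd(p) == 0) {
    abort("r_m^2 undefined for constant inputs", "gandta_undefined_statistic")
  }
  r2 <- stats::cor(y, p)^2
  k <- sum(y * p) / sum(p * p)
  r02 <- 1 - sum((y - k * p)^2) / sum((y - mean(y))^2)
  rm2 <- r2 * (1 - sqrt(max(0, r2 - r02)))
  list(r2 = r2, r02 = r02, rm2 = rm2)
}

#' Full evaluation report
#'
#' Aggregates the four statistics on one (truth, prediction) pair: CI, MSE,
#' AUPR at the binarization threshold, and r_m^2. AUPR is recorded as NA when
#' binarization yields a single class.
#'
#' @param Y true affinities.
#' @param P predictions.
#' @param threshold pKd binarization cutoff for AUPR (default 7).
#' @return object of class \code{evaluation_report}: list with \code{ci},
#'   \code{mse}, \code{aupr}, \code{rm2}, \code{r2}, \code{r02}, \code{n},
#'   \code{z}, \code{threshold}, \code{positives}.
#' @export
evaluate <- function(Y, P, threshold = 7) {
  ci <- concordance_index(Y, P)
  labels <- binarize_affinities(Y, threshold)
  au <- tryCatch(aupr(labels, P), gandta_undefined_statistic = function(e) NA_real_)
  rm <- rm_squared(Y, P)
  structure(list(ci = as.numeric(ci), mse = mean_squared_error(Y, P), aupr = au,
                 rm2 = rm$rm2, r2 = rm$r2, r02 = rm$r02,
                 n = length(Y), z = attr(ci, "z"),
                 threshold = threshold, positives = sum(labels)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Affinity evaluation (n = %d, %d positives at pKd >= %g)\n",
              x$n, x$positives, x$threshold))
  cat(sprintf("  CI    %.4f   (Z = %d comparable pairs)\n", x$ci, x$z))
  cat(sprintf("  MSE   %.4f\n", x$mse))
  cat(sprintf("  AUPR  %s\n", ifelse(is.na(x$aupr), "undefined (single class)",
                                     sprintf("%.4f", x$aupr))))
  cat(sprintf("  r_m^2 %.4f   (r^2 = %.4f, r0^2 = %.4f)\n", x$rm2, x$r2, x$r02))
  invisible(x)
}

#' Write an evaluation report as JSON and one-row TSV
#' @param report an \code{evaluation_report}.
#' @param path output path without extension; writes \code{<path>.json} and
#'   \code{<path>.tsv}.
#' @return the two paths, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  check_that(inherits(report, "evaluation_report"), "need an evaluation_report")
  jsonlite::write_json(unclass(report), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  df <- as.data.frame(unclass(report))
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paste0(path, ".json"), paste0(path, ".tsv")))
}
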