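# Internal helpers: argument checks, deterministic seed fan-out, fingerprints.

abort <- function(msg, class) {
  stop(structure(class = c(class, "gandta_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_that <- function(ok, msg, class = "gandta_input_error") {
  if (!isTRUE(ok)) abort(msg, class)
  invisible(TRUE)
}

#' Derive a stage-specific seed from a global seed
#'
#' One global seed fans out deterministically to per-stage seeds so each
#' pipeline stage (corpus generation, GAN pre-training, fold assignment,
#' predictor training, straw shuffles) is independently reproducible. The
#' derivation is a polynomial rolling hash of the stage label folded into the
#' seed, reduced modulo 2^31 - 2 (R seeds are 32-bit integers).
#'
#' @param seed integer global seed.
#' @param stage character label of the pipeline stage.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage) {
  check_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "seed must be a single finite number")
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(as.character(stage))) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 1) + 1)
}

# Cheap deterministic fingerprint of a character vector (corpus provenance).
fingerprint_strings <- function(x) {
  m <- 2147483647
  h <- length(x) %% m
  for (s in x) {
    h <- (h * 131 + nchar(s)) %% m
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
  }
  sprintf("%08x", as.integer(h))
}

# %.17g round-trips doubles exactly; used by all text checkpoint writers.
format_full <- function(x) sprintf("%.17g", x)
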