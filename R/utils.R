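#' Run an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the state afterwards, so simulation internals never disturb the
#' session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-volume seed from a master seed
#'
#' Deterministic mixing of the study master seed with scanner, setting and
#' repeat indices. Result is a positive 32-bit integer.
#'
#' @param master_seed integer master seed.
#' @param scanner_idx scanner position (1 or 2).
#' @param setting_idx setting position within the scanner (1-based).
#' @param repeat_idx 0 for the initial scan, 1 for the re-scan.
#' @return integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master_seed, scanner_idx, setting_idx, repeat_idx) {
  # double arithmetic is exact well past these magnitudes; fold into 31 bits
  h <- (as.numeric(master_seed) %% 2147483647) * 100003 +
    scanner_idx * 9176 + setting_idx * 131 + repeat_idx * 17 + 1
  as.integer(h %% 2147483646) + 1L
}

# sample skewness (m3 / m2^1.5); 0 for a constant sample
skewness0 <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

# excess kurtosis (m4 / m2^2 - 3); 0 for a constant sample
kurtosis0 <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}

# Shannon entropy in bits of a probability vector; 0 log 0 == 0
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}
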