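# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions never perturb the user's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
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

# Hamming distance between equal-length strings (vectorised over y).
hammingDist <- function(x, y) {
  xv <- strsplit(x, "", fixed = TRUE)[[1L]]
  vapply(strsplit(y, "", fixed = TRUE),
         function(v) sum(v != xv), integer(1L))
}

# Random DNA string of length n using the current RNG stream.
randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Round half-up (R's round() is half-even, which disagrees with the
# screening arithmetic convention used throughout the stats module).
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
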