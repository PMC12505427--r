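# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Printed percentages and GC values follow the "half away from zero"
#' convention rather than R's banker's rounding.
#'
#' @param x numeric vector
#' @param digits integer, decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single non-missing number")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# IUPAC nucleotide codes accepted in genome sequences.
IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Reverse complement of a plain character string (IUPAC-aware).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' GC content over unambiguous bases
#'
#' Fraction of G+C among A, C, G and T only; IUPAC ambiguity codes are
#' excluded from both numerator and denominator so the statistic is
#' deterministic on partially ambiguous assemblies.
#'
#' @param seq DNA sequence as a character string
#' @return fraction in [0, 1]; NaN when no unambiguous base is present
#' @export
gc_content <- function(seq) {
  counts <- table(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  gc <- sum(counts[c("G", "C")], na.rm = TRUE)
  at <- sum(counts[c("A", "T")], na.rm = TRUE)
  gc / (gc + at)
}

# Split a string into consecutive codons (length must be divisible by 3).
split_codons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

stopifnot_scalar_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name))
  }
}
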