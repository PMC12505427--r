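# Bacterial genetic code (translation table 11). The amino-acid assignments
# of table 11 are identical to the standard code; the tables differ only in
# their permitted initiation codons, which do not matter for translation of
# an already-annotated CDS.

.code11 <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
})

#' Translate a coding sequence (bacterial code)
#'
#' Translates an in-frame CDS under translation table 11 and reports every
#' internal stop codon.  The terminal stop codon, when present, is dropped
#' from the returned protein; internal stops are kept as \code{*} characters
#' so the split structure of interrupted genes remains visible.  Codons
#' containing IUPAC ambiguity codes translate to \code{X}.
#'
#' @param cds DNA sequence (character string), length divisible by 3
#' @param table genetic code identifier; only the bacterial table
#'   \code{11} is supported
#' @return list with elements \code{protein} (character string) and
#'   \code{internal_stops}, a data.frame with columns \code{codon_index}
#'   (0-based index within the CDS) and \code{codon} (TAA/TAG/TGA)
#' @examples
#' translate_cds("ATGAAATAA")          # MK, no internal stop
#' translate_cds("ATGTGAAAATAA")       # M*K with internal TGA at codon 1
#' @export
translate_cds <- function(cds, table = 11) {
  if (!identical(as.integer(table), 11L)) {
    stop("only genetic code table 11 (bacterial) is supported")
  }
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) {
    stop(sprintf("CDS length %d is not divisible by 3 (remainder %d)",
                 n, n %% 3))
  }
  codons <- split_codons(cds)
  aa <- unname(.code11[codons])
  aa[is.na(aa)] <- "X"  # any codon containing an ambiguity code
  n_cod <- length(aa)
  is_stop <- aa == "*"
  terminal <- n_cod > 0 && is_stop[n_cod]
  internal_idx <- which(is_stop & seq_along(aa) != n_cod)
  protein <- paste(aa[seq_len(if (terminal) n_cod - 1 else n_cod)],
                   collapse = "")
  list(
    protein = protein,
    internal_stops = data.frame(
      codon_index = internal_idx - 1L,
      codon = codons[internal_idx],
      stringsAsFactors = FALSE
    ),
    has_terminal_stop = terminal,
    terminal_codon = if (n_cod > 0) codons[n_cod] else NA_character_
  )
}
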