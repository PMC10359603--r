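# Internal sequence helpers shared across modules.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# All 61 sense codons, fixed order (used for uniform sampling).
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(sort(all), STOP_CODONS)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ATGC")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate DNA to protein
#'
#' Standard genetic code; trailing partial codons are dropped; fuzzy
#' codons (containing N) translate to `X`; stop codons to `*`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of protein sequences.
#' @export
translate_dna <- function(x) {
  x <- substr(x, 1L, (nchar(x) %/% 3L) * 3L)
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(x[nz]),
      if.fuzzy.codon = "X", no.init.codon = TRUE
    ))
  }
  out
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): unequal lengths")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# i.i.d. background DNA at a given GC fraction.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# One random sense codon per element of `aa`; if `aa` is NULL, uniform
# over all sense codons.
random_codons <- function(n, aa = NULL) {
  cods <- sense_codons()
  if (is.null(aa)) return(sample(cods, n, replace = TRUE))
  tab <- split(names(Biostrings::GENETIC_CODE),
               unname(Biostrings::GENETIC_CODE))
  vapply(strsplit(aa, "")[[1]], function(a) {
    syn <- setdiff(tab[[a]], STOP_CODONS)
    if (length(syn) == 1L) syn else sample(syn, 1L)
  }, character(1), USE.NAMES = FALSE)
}

is_dna <- function(x) {
  all(grepl("^[ACGTN]+$", x))
}

# Split a DNA string into codons starting at `from` (1-based).
codons_of <- function(seq, from = 1L) {
  s <- substr(seq, from, nchar(seq))
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
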