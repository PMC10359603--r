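# Six-frame ORF finding on nucleotide loci.

as_locus <- function(locus) {
  if (is.list(locus) && !is.null(locus$sequence)) {
    return(list(id = locus$id %||% "locus", sequence = toupper(locus$sequence)))
  }
  if (methods::is(locus, "DNAStringSet")) {
    stopifnot(length(locus) == 1L)
    return(list(id = names(locus) %||% "locus",
                sequence = as.character(locus[[1L]])))
  }
  if (is.character(locus) && length(locus) == 1L) {
    return(list(id = names(locus) %||% "locus", sequence = toupper(locus)))
  }
  stop("locus must be a single sequence (character, list, or DNAStringSet)")
}

empty_orf_frame <- function() {
  data.frame(locus_id = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(), has_start = logical(),
             stop_terminated = logical(), local_start = integer(),
             local_end = integer(), translation = character())
}

#' Find open reading frames in all six frames
#'
#' Scans both strands in all three frames. Reading frames are split at
#' stop codons; each stop-to-stop segment containing an ATG is reported
#' as an ORF running from its first ATG through the end of its stop
#' codon (or the last complete codon when the frame runs off the
#' sequence end). With `include_startless = TRUE`, segments without an
#' ATG are also reported from their first codon (open 5' end), which
#' models loci whose true start codon is missing or misannotated.
#'
#' @param locus a single sequence: character string, `list(id, sequence)`,
#'   or a length-1 [Biostrings::DNAStringSet]. Alphabet `{A,C,G,T,N}`.
#' @param min_len_codons minimum translation length in residues.
#' @param include_startless also report ATG-less stop-to-stop segments.
#' @return data.frame with one row per ORF: `start`, `end` (0-based
#'   half-open, forward-strand coordinates), `strand`, `frame`
#'   (strand-local), `has_start`, `stop_terminated`, `local_start`,
#'   `local_end` (strand-local coordinates used by [detect_prf()]), and
#'   `translation`. If the sequence is more than 50% `N`, the result
#'   carries attribute `n_dense = TRUE`.
#' @export
find_orfs <- function(locus, min_len_codons = 30L, include_startless = FALSE) {
  locus <- as_locus(locus)
  if (min_len_codons < 1L) stop("min_len_codons must be >= 1")
  if (!is_dna(locus$sequence)) stop("locus sequence must be over {A,C,G,T,N}")
  n <- nchar(locus$sequence)
  res <- list()
  for (strand in c("+", "-")) {
    S <- if (strand == "+") locus$sequence else revcomp(locus$sequence)
    for (f in 0:2) {
      cods <- codons_of(S, from = f + 1L)
      k <- length(cods)
      if (k == 0L) next
      stops <- which(cods %in% STOP_CODONS)
      seg_start <- c(1L, stops + 1L)
      seg_stop <- c(stops, NA_integer_)   # NA: segment runs off the end
      drop <- seg_start > k               # nothing after a terminal stop
      seg_start <- seg_start[!drop]
      seg_stop <- seg_stop[!drop]
      seg_end <- ifelse(is.na(seg_stop), k, seg_stop - 1L)
      for (s in seq_along(seg_start)) {
        cs <- seg_start[s]
        ce <- seg_end[s]
        if (ce < cs) next
        terminated <- !is.na(seg_stop[s])
        atg <- which(cods[cs:ce] == "ATG")
        has_start <- length(atg) > 0L
        a <- if (has_start) cs + atg[1L] - 1L else if (include_startless) cs
          else next
        aa_len <- ce - a + 1L
        if (aa_len < min_len_codons) next
        ls <- f + 3L * (a - 1L)
        le <- f + 3L * (if (terminated) ce + 1L else ce)
        fwd <- if (strand == "+") c(ls, le) else c(n - le, n - ls)
        res[[length(res) + 1L]] <- data.frame(
          locus_id = locus$id, start = fwd[1L], end = fwd[2L],
          strand = strand, frame = f, has_start = has_start,
          stop_terminated = terminated, local_start = ls, local_end = le,
          translation = paste(
            Biostrings::GENETIC_CODE[cods[a:ce]] |>
              (\(x) ifelse(is.na(x), "X", x))(), collapse = ""))
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else empty_orf_frame()
  out <- out[order(out$strand, out$frame, out$start), , drop = FALSE]
  rownames(out) <- NULL
  n_frac <- sum(strsplit(locus$sequence, "")[[1]] == "N") / max(n, 1L)
  if (n_frac > 0.5) attr(out, "n_dense") <- TRUE
  out
}
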