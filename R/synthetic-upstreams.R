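# Synthetic promoter upstream windows carrying a planted inverted
# repeat (IR) with spacer 15 or 16 bp, emulating FseA-box operators.

#' Default position frequency matrix for one IR hexamer
#'
#' Probability matrix (rows A,C,G,T; 6 columns) for sampling hexamer 1
#' of a planted IR. The two central positions are nearly invariant and
#' the flanks are moderately conserved, emulating operator hexamers
#' whose two central nucleobases are highly conserved. Hexamer 2 is
#' sampled from the reverse-complemented matrix (see [revcomp_pfm()]).
#'
#' @param consensus hexamer consensus sequence.
#' @param p_flank,p_core probability of the consensus base at flanking
#'   and central positions. `p_flank = p_core = 1` gives an invariant
#'   (perfect) IR.
#' @return 4 x 6 numeric matrix with rownames `A,C,G,T`, columns
#'   summing to 1.
#' @export
ir_default_pfm <- function(consensus = IR_CONSENSUS_HEX, p_flank = 0.85,
                           p_core = 0.99) {
  stopifnot(nchar(consensus) == 6L, is_dna(consensus))
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(consensus, "")[[1]]
  p <- c(p_flank, p_flank, p_core, p_core, p_flank, p_flank)
  m <- vapply(seq_len(6L), function(j) {
    col <- rep((1 - p[j]) / 3, 4L)
    col[match(cons[j], bases)] <- p[j]
    col
  }, numeric(4))
  rownames(m) <- bases
  m
}

#' Reverse-complement a position frequency/probability matrix
#'
#' @param pfm 4 x W matrix with rownames `A,C,G,T`.
#' @return the matrix with columns reversed and rows complemented.
#' @export
revcomp_pfm <- function(pfm) {
  stopifnot(identical(rownames(pfm), c("A", "C", "G", "T")))
  out <- pfm[c("T", "G", "C", "A"), rev(seq_len(ncol(pfm))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

sample_pfm <- function(pfm) {
  bases <- rownames(pfm)
  paste(vapply(seq_len(ncol(pfm)), function(j)
    sample(bases, 1L, prob = pfm[, j]), character(1)), collapse = "")
}

#' Generate upstream windows with one planted inverted repeat each
#'
#' Each fixed-length window carries exactly one planted IR: hexamer 1
#' sampled from `pfm`, hexamer 2 from the reverse-complemented `pfm`,
#' separated by a spacer of 15 or 16 bp drawn from `spacer_probs`.
#' Windows are rejection-sampled so that the background contains no
#' spurious perfect IR: at `max_mismatch = 0` the planted box (when
#' perfect) is the unique hit.
#'
#' @param n number of windows (> 0).
#' @param spacer_probs named numeric, probabilities of spacers 15 and 16
#'   (names `"15"`, `"16"`); must sum to 1.
#' @param pfm 4 x 6 probability matrix for hexamer 1 (default
#'   [ir_default_pfm()]).
#' @param seed integer RNG seed.
#' @param window_len window length in nt (must hold 6 + 16 + 6).
#' @param gc background GC fraction.
#' @return list with `windows` (named [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame: id, hex1_start, hex2_start (0-based), spacer).
#' @export
gen_upstreams <- function(n, spacer_probs = c("15" = 0.5, "16" = 0.5),
                          pfm = ir_default_pfm(), seed = 1L,
                          window_len = 80L, gc = 0.5) {
  if (length(n) != 1L || !is.finite(n) || n <= 0)
    stop("n must be a positive count")
  stopifnot(nrow(pfm) == 4L, ncol(pfm) == 6L)
  spacers <- as.integer(names(spacer_probs))
  if (abs(sum(spacer_probs) - 1) > 1e-8)
    stop("spacer_probs must sum to 1")
  if (window_len < 2L * 6L + max(spacers))
    stop("window_len too short to hold the IR")
  set.seed(seed)
  rpfm <- revcomp_pfm(pfm)
  ids <- sprintf("win_%04d", seq_len(n))
  seqs <- character(n)
  truth <- data.frame(id = ids, hex1_start = NA_integer_,
                      hex2_start = NA_integer_, spacer = NA_integer_)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      spacer <- spacers[sample.int(length(spacers), 1L,
                                   prob = spacer_probs)]
      span <- 12L + spacer
      pos <- sample.int(window_len - span + 1L, 1L) - 1L
      hex1 <- sample_pfm(pfm)
      hex2 <- sample_pfm(rpfm)
      w <- paste0(random_dna(pos, gc), hex1, random_dna(spacer, gc), hex2,
                  random_dna(window_len - pos - span, gc))
      hits <- scan_ir(w, max_mismatch = 0L, spacers = spacers)
      planted_perfect <- hex2 == revcomp(hex1)
      ok <- if (planted_perfect) {
        nrow(hits) == 1L && hits$hex1_start == pos && hits$spacer == spacer
      } else nrow(hits) == 0L
      if (ok) break
      if (try == 100L) stop("gen_upstreams(): rejection sampling failed")
    }
    seqs[i] <- w
    truth$hex1_start[i] <- pos
    truth$hex2_start[i] <- pos + 6L + spacer
    truth$spacer[i] <- spacer
  }
  list(windows = Biostrings::DNAStringSet(setNames(seqs, ids)), truth = truth)
}
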