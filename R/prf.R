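# +1 programmed-ribosomal-frameshift (PRF) detection and ORF fusion.
#
# An FseA-like gene is encoded by two ORFs overlapping in the +1 frame;
# a slippery site (coding-strand TGGGGG, mRNA UGGGGG) near the 3' end of
# the upstream ORF lets the ribosome slip forward one nucleotide, fusing
# the two coding sequences into one polypeptide.

empty_call_frame <- function() {
  data.frame(locus_id = character(), strand = character(),
             up_start = integer(), up_end = integer(),
             down_start = integer(), down_end = integer(),
             motif_start = integer(), motif_start_fwd = integer(),
             motif_seq = character(), motif_mismatches = integer(),
             shift = character(), overlap_nt = integer(),
             up_local_start = integer(), up_local_end = integer(),
             down_local_start = integer(), down_local_end = integer())
}

#' Detect +1 PRF sites joining overlapping ORF pairs
#'
#' Considers every ORF pair on the same strand whose downstream member
#' lies in the +1 frame relative to the upstream member
#' (`frame_down == (frame_up + 1) %% 3`) and overlaps it by at least
#' 1 nt. A pair is called when the upstream ORF contains the slippery
#' motif (within `max_mismatch` mismatches) ending on one of its codon
#' boundaries, within `window_nt` of its stop codon. When several motif
#' occurrences qualify for a pair, the one with fewest mismatches and
#' then closest to the stop (3'-most) is taken; the returned calls are
#' sorted by (mismatches, ascending motif position).
#'
#' @param locus sequence accepted by [find_orfs()].
#' @param orfs ORF table from [find_orfs()] on the same locus; computed
#'   automatically when `NULL`.
#' @param motif slippery-site DNA 6-mer on the coding strand.
#' @param max_mismatch maximum Hamming mismatches in the motif.
#' @param window_nt how far upstream of the stop codon the motif may
#'   end.
#' @param min_len_codons passed to [find_orfs()] when `orfs` is `NULL`.
#' @return data.frame of PRF site calls (possibly empty): forward-strand
#'   ORF coordinates, `motif_start` (strand-local 0-based),
#'   `motif_start_fwd` (forward-strand 0-based), observed `motif_seq`,
#'   `motif_mismatches`, `shift = "+1"`, `overlap_nt`, and the
#'   strand-local ORF coordinates used by [fuse_prf()].
#' @export
detect_prf <- function(locus, orfs = NULL, motif = "TGGGGG",
                       max_mismatch = 0L, window_nt = 45L,
                       min_len_codons = 30L) {
  locus <- as_locus(locus)
  if (nchar(motif) != 6L || !is_dna(motif)) stop("motif must be a DNA 6-mer")
  if (is.null(orfs)) orfs <- find_orfs(locus, min_len_codons = min_len_codons)
  if (nrow(orfs) < 2L) return(empty_call_frame())
  n <- nchar(locus$sequence)
  calls <- list()
  for (i in seq_len(nrow(orfs))) {
    for (j in seq_len(nrow(orfs))) {
      if (i == j) next
      u <- orfs[i, ]
      d <- orfs[j, ]
      if (u$strand != d$strand) next
      if (d$frame != (u$frame + 1L) %% 3L) next
      if (d$local_end <= u$local_end) next       # must extend 3' of upstream
      ov <- min(u$local_end, d$local_end) - max(u$local_start, d$local_start)
      if (ov < 1L) next
      S <- if (u$strand == "+") locus$sequence else revcomp(locus$sequence)
      stop_start <- if (u$stop_terminated) u$local_end - 3L else u$local_end
      p_lo <- max(u$local_start, stop_start - window_nt)
      if (stop_start - 6L < u$local_start) next
      cand <- seq.int(u$local_start, stop_start - 6L, by = 3L)
      cand <- cand[cand >= p_lo]
      if (length(cand) == 0L) next
      obs <- substring(S, cand + 1L, cand + 6L)
      mm <- vapply(obs, hamming, integer(1), b = motif, USE.NAMES = FALSE)
      ok <- which(mm <= max_mismatch)
      if (length(ok) == 0L) next
      best <- ok[order(mm[ok], -cand[ok])][1L]
      p <- cand[best]
      calls[[length(calls) + 1L]] <- data.frame(
        locus_id = locus$id, strand = u$strand,
        up_start = u$start, up_end = u$end,
        down_start = d$start, down_end = d$end,
        motif_start = p,
        motif_start_fwd = if (u$strand == "+") p else n - (p + 6L),
        motif_seq = obs[best], motif_mismatches = mm[best],
        shift = "+1", overlap_nt = ov,
        up_local_start = u$local_start, up_local_end = u$local_end,
        down_local_start = d$local_start, down_local_end = d$local_end)
    }
  }
  if (length(calls) == 0L) return(empty_call_frame())
  out <- do.call(rbind, calls)
  out <- out[order(out$motif_mismatches, out$motif_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fuse an ORF pair across a +1 PRF site
#'
#' Translation proceeds in the upstream frame through the final
#' nucleotide of the slippery motif, then resumes one nucleotide 3'
#' (the +1 edit) in the downstream frame through the downstream stop.
#' With the canonical codon-aligned `TGG|GGG` site this reads `W`,`G`
#' across the junction. An internal stop after the edit signals a false
#' PRF call and raises a fusion error carrying the offending
#' strand-local coordinate.
#'
#' @param locus sequence accepted by [find_orfs()].
#' @param call one row of a [detect_prf()] call table, or `NULL`.
#' @param orf when `call` is `NULL`, a single ORF row ([find_orfs()])
#'   to translate directly (provenance `SINGLE_ORF`).
#' @return a `reconstructed_protein`: list with `sequence`,
#'   `provenance` (`"PRF_FUSED"` or `"SINGLE_ORF"`), `junction_residue`
#'   (1-based index of the last residue encoded before the frame edit;
#'   `NA` for single-ORF), and `locus_id`.
#' @export
fuse_prf <- function(locus, call, orf = NULL) {
  locus <- as_locus(locus)
  if (is.null(call)) {
    if (is.null(orf)) stop("either a PRF call or an ORF is required")
    prot <- sub("\\*$", "", orf$translation)
    return(structure(list(sequence = prot, provenance = "SINGLE_ORF",
                          junction_residue = NA_integer_,
                          locus_id = locus$id),
                     class = "reconstructed_protein"))
  }
  stopifnot(nrow(call) == 1L)
  S <- if (call$strand == "+") locus$sequence else revcomp(locus$sequence)
  p <- call$motif_start
  part1 <- substr(S, call$up_local_start + 1L, p + 6L)
  resume <- p + 7L                       # 0-based: skip one nt after motif
  stop_start <- call$down_local_end - 3L
  part2 <- substr(S, resume + 1L, stop_start)
  aa1 <- translate_dna(part1)
  aa2 <- translate_dna(part2)
  bad <- regexpr("*", paste0(aa1, aa2), fixed = TRUE)
  if (bad > 0L) {
    coord <- if (bad <= nchar(aa1)) call$up_local_start + 3L * (bad - 1L)
      else resume + 3L * (bad - nchar(aa1) - 1L)
    stop(errorCondition(
      sprintf("internal stop at strand-local position %d after +1 edit: likely a false PRF call", coord),
      class = "dufscout_fusion_error", coordinate = coord))
  }
  structure(list(sequence = paste0(aa1, aa2), provenance = "PRF_FUSED",
                 junction_residue = nchar(aa1), locus_id = locus$id),
            class = "reconstructed_protein")
}

#' @export
print.reconstructed_protein <- function(x, ...) {
  cat(sprintf("<reconstructed_protein> %s [%s] %d aa%s\n", x$locus_id,
              x$provenance, nchar(x$sequence),
              if (!is.na(x$junction_residue))
                sprintf(", junction at residue %d", x$junction_residue)
              else ""))
  invisible(x)
}

#' Reconstruct one protein per locus
#'
#' Runs [find_orfs()] and [detect_prf()] on each locus and emits the
#' fused polypeptide of the best PRF call (fewest mismatches, then
#' 3'-most motif), or the translation of the longest ORF when no pair
#' qualifies.
#'
#' @param loci named character vector or [Biostrings::DNAStringSet].
#' @inheritParams detect_prf
#' @return data.frame: `id`, `sequence`, `provenance`,
#'   `junction_residue`, `prf_pos` (strand-local motif start or `NA`).
#' @export
reconstruct_proteins <- function(loci, motif = "TGGGGG", max_mismatch = 0L,
                                 window_nt = 45L, min_len_codons = 30L) {
  if (methods::is(loci, "DNAStringSet")) {
    loci <- setNames(as.character(loci), names(loci))
  }
  ids <- names(loci) %||% sprintf("locus_%03d", seq_along(loci))
  if (length(loci) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      provenance = character(),
                      junction_residue = integer(), prf_pos = integer()))
  }
  rows <- lapply(seq_along(loci), function(i) {
    locus <- list(id = ids[i], sequence = loci[[i]])
    orfs <- find_orfs(locus, min_len_codons = min_len_codons)
    calls <- detect_prf(locus, orfs, motif = motif,
                        max_mismatch = max_mismatch, window_nt = window_nt)
    if (nrow(calls) > 0L) {
      rp <- fuse_prf(locus, calls[1L, ])
      data.frame(id = ids[i], sequence = rp$sequence,
                 provenance = rp$provenance,
                 junction_residue = rp$junction_residue,
                 prf_pos = calls$motif_start[1L])
    } else if (nrow(orfs) > 0L) {
      longest <- orfs[which.max(nchar(orfs$translation)), ]
      rp <- fuse_prf(locus, NULL, orf = longest)
      data.frame(id = ids[i], sequence = rp$sequence,
                 provenance = rp$provenance, junction_residue = NA_integer_,
                 prf_pos = NA_integer_)
    } else {
      data.frame(id = ids[i], sequence = NA_character_,
                 provenance = NA_character_, junction_residue = NA_integer_,
                 prf_pos = NA_integer_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
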