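# Homologue curation: AWEFLRRN motif search, activator/antiactivator
# classification, and the staged filtering used to build a curated
# FseA/QseM homologue database.

# Best Hamming hit of `motif` within residues 1..region_end of `protein`
# (whole match inside the region). Ties broken toward the N-terminus.
# Returns list(start, mismatches, match) or NULL.
motif_best_hit <- function(protein, motif, max_mismatch, region_end) {
  w <- nchar(motif)
  lim <- min(nchar(protein), region_end) - w + 1L
  if (lim < 1L) return(NULL)
  mvec <- strsplit(motif, "")[[1]]
  pvec <- strsplit(substr(protein, 1L, lim + w - 1L), "")[[1]]
  mm <- vapply(seq_len(lim), function(s)
    sum(pvec[s:(s + w - 1L)] != mvec), integer(1))
  best <- which.min(mm)
  if (mm[best] > max_mismatch) return(NULL)
  list(start = best, mismatches = mm[best],
       match = substr(protein, best, best + w - 1L))
}

#' Find the DUF6499-diagnostic AWEFLRRN motif
#'
#' Best (fewest-mismatch, then most N-terminal) ungapped Hamming match
#' of the motif within residues `1..region_end`. In FseA the motif sits
#' at residues 31-38, on the alpha-2 helix of the DUF6499 domain; its
#' presence upstream distinguishes activator-like (DUF6499+DUF2285)
#' proteins from lone-DUF2285 antiactivators.
#'
#' @param protein protein sequence (character). Case and terminal
#'   whitespace are ignored.
#' @param motif motif to search (default `"AWEFLRRN"`).
#' @param max_mismatch maximum Hamming mismatches (default 2).
#' @param region_end last residue of the search region (default 60).
#' @return list with `start` (1-based residue), `mismatches`, `match`,
#'   or `NULL` when no qualifying match exists.
#' @export
find_motif <- function(protein, motif = "AWEFLRRN", max_mismatch = 2L,
                       region_end = 60L) {
  protein <- toupper(trimws(protein))
  if (nchar(protein) == 0L) stop("protein must be non-empty")
  motif_best_hit(protein, toupper(motif), max_mismatch, region_end)
}

#' Classify candidate proteins as activator-like or antiactivator-like
#'
#' `FSEA_LIKE` iff an upstream AWEFLRRN-like motif is found
#' ([find_motif()]); `QSEM_LIKE` otherwise. Curation filters
#' ([curate()]) may later reject either class.
#'
#' @param candidates data.frame with columns `id`, `sequence`, and
#'   optionally `provenance` (`"PRF_FUSED"`/`"SINGLE_ORF"`).
#' @inheritParams find_motif
#' @return the input with added columns `label`, `motif_start`,
#'   `motif_mismatches`.
#' @export
classify_homologs <- function(candidates, motif = "AWEFLRRN",
                              max_mismatch = 2L, region_end = 60L) {
  stopifnot(is.data.frame(candidates),
            all(c("id", "sequence") %in% names(candidates)))
  n <- nrow(candidates)
  candidates$label <- character(n)
  candidates$motif_start <- rep(NA_integer_, n)
  candidates$motif_mismatches <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hit <- find_motif(candidates$sequence[i], motif, max_mismatch, region_end)
    if (!is.null(hit)) {
      candidates$label[i] <- "FSEA_LIKE"
      candidates$motif_start[i] <- hit$start
      candidates$motif_mismatches[i] <- hit$mismatches
    } else {
      candidates$label[i] <- "QSEM_LIKE"
    }
  }
  candidates
}

# Anchored motif-column consensus across FSEA_LIKE candidates: stack the
# 8-mer windows at each sequence's best motif hit and take the majority
# letter per column. Stand-in for checking motif distinctness in a full
# multiple sequence alignment.
anchored_consensus <- function(seqs, starts, width) {
  if (length(seqs) == 0L) return(NULL)
  mat <- do.call(rbind, lapply(seq_along(seqs), function(i)
    strsplit(substr(seqs[i], starts[i], starts[i] + width - 1L), "")[[1]]))
  apply(mat, 2L, function(col) names(which.max(table(col))))
}

#' Curate a classified homologue candidate set
#'
#' Applies, in `stage_order`, the database-curation filters: removal of
#' lone-DUF6499 duplicate records (`DUPLICATE_DUF6499`), of proteins
#' longer than `max_len` residues (`TOO_LONG`), of sequences whose
#' anchored motif window deviates from the motif-column consensus by
#' more than `max_mismatch` (`NO_MOTIF_POST_ALIGN`; a stand-in for
#' motif validation in a full alignment -- supply `msa` to use an
#' externally produced alignment instead), and of sequences containing
#' ambiguous residues `X` (`AMBIGUOUS`). Filter predicates are computed
#' once from the full input, so permuting `stage_order` changes only the
#' attribution of removals, never the kept set.
#'
#' @param candidates output of [classify_homologs()] (columns `id`,
#'   `sequence`, `label`; optional `provenance`).
#' @param lone_duf6499_ids ids of records that are lone-DUF6499 loci
#'   already represented by a kept activator record.
#' @param max_len maximum protein length (default 400).
#' @param max_mismatch tolerance for the post-alignment motif check.
#' @param motif motif validated in stage `NO_MOTIF_POST_ALIGN`.
#' @param msa optional named character vector (or path to a FASTA) of an
#'   externally produced MSA covering the candidates; when given, the
#'   motif check is performed on the ungapped motif columns of that
#'   alignment instead of the internal anchor.
#' @param stage_order permutation of
#'   `c("DUPLICATE_DUF6499","TOO_LONG","NO_MOTIF_POST_ALIGN","AMBIGUOUS")`.
#' @return list with `kept` (surviving rows, plus `reject_reason =
#'   "NONE"`), `removed` (rejected rows with their `reject_reason`), and
#'   `report`: input count, per-stage removal counts, surviving count,
#'   `fraction_prf_fused` (among kept `FSEA_LIKE`), `fraction_surviving`.
#' @export
curate <- function(candidates, lone_duf6499_ids = character(),
                   max_len = 400L, max_mismatch = 2L, motif = "AWEFLRRN",
                   msa = NULL,
                   stage_order = c("DUPLICATE_DUF6499", "TOO_LONG",
                                   "NO_MOTIF_POST_ALIGN", "AMBIGUOUS")) {
  stages <- c("DUPLICATE_DUF6499", "TOO_LONG", "NO_MOTIF_POST_ALIGN",
              "AMBIGUOUS")
  stopifnot(setequal(stage_order, stages))
  n <- nrow(candidates)
  if (n == 0L) {
    rep0 <- list(input = 0L, removed = setNames(rep(0L, 4L), stages),
                 surviving = 0L, fraction_prf_fused = NA_real_,
                 fraction_surviving = NA_real_)
    return(list(kept = candidates, removed = candidates, report = rep0))
  }
  if (!"label" %in% names(candidates)) {
    candidates <- classify_homologs(candidates, motif = motif)
  }
  seqs <- toupper(trimws(candidates$sequence))
  flag <- list()
  flag$DUPLICATE_DUF6499 <- candidates$id %in% lone_duf6499_ids
  flag$TOO_LONG <- nchar(seqs) > max_len
  flag$AMBIGUOUS <- grepl("X", seqs, fixed = TRUE)
  is_fsea <- candidates$label == "FSEA_LIKE"
  fail_align <- rep(FALSE, n)
  idx <- which(is_fsea & !is.na(candidates$motif_start))
  if (length(idx) > 0L) {
    if (is.null(msa)) {
      cons <- anchored_consensus(seqs[idx], candidates$motif_start[idx],
                                 nchar(motif))
      fail_align[idx] <- vapply(idx, function(i) {
        win <- strsplit(substr(seqs[i], candidates$motif_start[i],
                               candidates$motif_start[i] + nchar(motif) - 1L),
                        "")[[1]]
        sum(win != cons) > max_mismatch
      }, logical(1))
    } else {
      fail_align <- msa_motif_check(candidates, msa, motif, max_mismatch)
    }
  }
  flag$NO_MOTIF_POST_ALIGN <- fail_align
  reason <- rep("NONE", n)
  for (st in stage_order) {
    reason[reason == "NONE" & flag[[st]]] <- st
  }
  removed_counts <- setNames(vapply(stage_order, function(st)
    sum(reason == st), integer(1)), stage_order)
  kept <- candidates[reason == "NONE", , drop = FALSE]
  kept$reject_reason <- "NONE"
  removed <- candidates[reason != "NONE", , drop = FALSE]
  removed$reject_reason <- reason[reason != "NONE"]
  kept_fsea <- kept[kept$label == "FSEA_LIKE", , drop = FALSE]
  frac_prf <- if ("provenance" %in% names(kept) && nrow(kept_fsea) > 0L)
    mean(kept_fsea$provenance == "PRF_FUSED") else NA_real_
  report <- list(input = n, removed = as.list(removed_counts),
                 surviving = nrow(kept),
                 fraction_prf_fused = frac_prf,
                 fraction_surviving = nrow(kept) / n)
  stopifnot(report$input == report$surviving + sum(removed_counts))
  list(kept = kept, removed = removed, report = report)
}

# Motif check against an externally produced MSA: locate the motif
# columns from the consensus of the alignment and compare each
# candidate's (ungapped) residues in those columns.
msa_motif_check <- function(candidates, msa, motif, max_mismatch) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa)) {
    aln <- Biostrings::readAAStringSet(msa)
    msa <- setNames(as.character(aln), names(aln))
  }
  n <- nrow(candidates)
  fail <- rep(FALSE, n)
  have <- candidates$id %in% names(msa)
  if (!any(have)) return(fail)
  rows <- do.call(rbind, strsplit(toupper(unname(msa[candidates$id[have]])),
                                  ""))
  cons <- apply(rows, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) "-" else names(which.max(table(col)))
  })
  hit <- motif_best_hit(paste(cons[cons != "-"], collapse = ""),
                        motif, nchar(motif), nchar(paste(cons, collapse = "")))
  if (is.null(hit)) return(fail)
  unng <- which(cons != "-")
  cols <- unng[hit$start:(hit$start + nchar(motif) - 1L)]
  mvec <- strsplit(toupper(motif), "")[[1]]
  fail[have] <- apply(rows[, cols, drop = FALSE], 1L,
                      function(r) sum(r != mvec) > max_mismatch)
  fail
}
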