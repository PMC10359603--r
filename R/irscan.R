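# Inverted-repeat (FseA-box style) scanning and split-anchor
# conservation profiling of promoter upstream windows.

#' Scan a window for inverted-repeat boxes
#'
#' Tests every (position, spacer) pair for a box of two `hexamer_len`
#' half-sites in which the downstream half-site equals the reverse
#' complement of the upstream half-site within `max_mismatch`
#' mismatches. An IR is its own reverse complement as a pair, so each
#' hit is reported once, not once per strand.
#'
#' @param window DNA string (length >= `2*hexamer_len + max(spacers)`).
#' @param hexamer_len half-site length (default 6).
#' @param spacers admissible spacer lengths in bp (default 15 and 16).
#' @param max_mismatch maximum mismatches between the downstream
#'   half-site and the reverse complement of the upstream half-site.
#' @return data.frame sorted by (mismatches, position): `hex1_start`,
#'   `hex2_start` (0-based), `hexamer_len`, `spacer`, `mismatches`,
#'   `total_span` (`2*hexamer_len + spacer`), `hex1`, `hex2`.
#' @export
scan_ir <- function(window, hexamer_len = 6L, spacers = c(15L, 16L),
                    max_mismatch = 1L) {
  window <- toupper(as.character(window))
  if (!is_dna(window)) stop("window must be DNA over {A,C,G,T,N}")
  L <- nchar(window)
  if (L < 2L * hexamer_len + max(spacers))
    stop("window shorter than 2*hexamer_len + max(spacers)")
  w <- strsplit(window, "")[[1]]
  wc <- chartr("ACGTN", "TGCAN", w)             # per-base complement
  hits <- list()
  for (spacer in sort(as.integer(spacers))) {
    span <- 2L * hexamer_len + spacer
    if (span > L) next
    for (p in 0:(L - span)) {
      # hex2 vs revcomp(hex1): compare hex2[j] with complement of the
      # mirrored hex1 base
      h1 <- (p + 1L):(p + hexamer_len)
      h2 <- (p + hexamer_len + spacer + 1L):(p + span)
      mm <- sum(w[h2] != wc[rev(h1)])
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1L]] <- data.frame(
          hex1_start = p, hex2_start = p + hexamer_len + spacer,
          hexamer_len = hexamer_len, spacer = spacer, mismatches = mm,
          total_span = span,
          hex1 = paste(w[h1], collapse = ""),
          hex2 = paste(w[h2], collapse = ""))
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(hex1_start = integer(), hex2_start = integer(),
                      hexamer_len = integer(), spacer = integer(),
                      mismatches = integer(), total_span = integer(),
                      hex1 = character(), hex2 = character()))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$mismatches, out$hex1_start, out$spacer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy redundancy filtering of equal-length windows
#'
#' In input order, a window is kept iff its ungapped identity (exact
#' position-wise matches / length) to every previously kept window is
#' strictly below `threshold`.
#'
#' @param windows character vector (or [Biostrings::DNAStringSet]) of
#'   equal-length sequences.
#' @param threshold identity threshold in `[0, 1]` (default 0.90).
#' @return the kept subset, in input order (same type as input names
#'   preserved).
#' @export
redundancy_filter <- function(windows, threshold = 0.90) {
  if (methods::is(windows, "XStringSet"))
    windows <- setNames(as.character(windows), names(windows))
  if (length(windows) == 0L) return(windows)
  len <- unique(nchar(windows))
  if (length(len) != 1L) stop("windows must all have equal length")
  mats <- do.call(rbind, strsplit(toupper(windows), ""))
  keep <- integer(0)
  for (i in seq_along(windows)) {
    ok <- TRUE
    for (k in keep) {
      if (mean(mats[i, ] == mats[k, ]) >= threshold) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  windows[keep]
}

#' Split-anchor conservation profile around inverted-repeat boxes
#'
#' Stacks windows in two independently anchored blocks to avoid the
#' smearing that mixed 15/16-bp spacers cause in a fixed-coordinate
#' stack: the upstream block is aligned on the *end of half-site 1*
#' (its `flank_up` preceding columns plus the half-site), the
#' downstream block on the *start of half-site 2* (the half-site plus
#' `flank_down` following columns). Per-column information content is
#' `2 - H` bits with Shannon entropy `H` in log2, no small-sample
#' correction and (by default) no pseudocounts.
#'
#' @param windows character vector or [Biostrings::DNAStringSet].
#' @param boxes data.frame with one anchor box per window: columns
#'   `hex1_start`, `hex2_start`, `hexamer_len` (e.g. the best
#'   [scan_ir()] hit, or generator truth). Rows align with `windows`;
#'   windows with a missing (`NA`) anchor are skipped and counted.
#' @param flank_up,flank_down flanking columns included on each side;
#'   `NULL` takes the largest width available in every window.
#' @param pseudocount added to every base count (default 0).
#' @return object of class `conservation_profile`: list with `counts`
#'   (4 x W matrix, rows `A,C,G,T`), `information` (bits per column),
#'   `n_sequences`, `anchor` (`"split"`), `block` (per-column block
#'   tag), `offsets` (per-column position relative to its anchor),
#'   `n_skipped`.
#' @export
split_profile <- function(windows, boxes, flank_up = NULL, flank_down = NULL,
                          pseudocount = 0) {
  if (methods::is(windows, "XStringSet"))
    windows <- setNames(as.character(windows), names(windows))
  stopifnot(length(windows) == nrow(boxes))
  windows <- toupper(windows)
  ok <- !is.na(boxes$hex1_start) & !is.na(boxes$hex2_start)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    warning(sprintf("split_profile(): %d window(s) without anchor skipped",
                    n_skipped))
  windows <- windows[ok]
  boxes <- boxes[ok, , drop = FALSE]
  if (length(windows) == 0L) stop("no anchored windows")
  hl <- unique(boxes$hexamer_len)
  stopifnot(length(hl) == 1L)
  hex1_end <- boxes$hex1_start + hl           # 0-based, exclusive
  avail_up <- min(hex1_end) - hl              # columns before half-site 1
  avail_down <- min(nchar(windows) - boxes$hex2_start) - hl
  if (is.null(flank_up)) flank_up <- avail_up
  if (is.null(flank_down)) flank_down <- avail_down
  stopifnot(flank_up <= avail_up, flank_down <= avail_down)
  up_w <- flank_up + hl
  down_w <- hl + flank_down
  n <- length(windows)
  up_block <- vapply(seq_len(n), function(i)
    substr(windows[i], hex1_end[i] - up_w + 1L, hex1_end[i]), character(1))
  down_block <- vapply(seq_len(n), function(i)
    substr(windows[i], boxes$hex2_start[i] + 1L,
           boxes$hex2_start[i] + down_w), character(1))
  count_block <- function(block) {
    m <- do.call(rbind, strsplit(block, ""))
    vapply(seq_len(ncol(m)), function(j)
      c(A = sum(m[, j] == "A"), C = sum(m[, j] == "C"),
        G = sum(m[, j] == "G"), T = sum(m[, j] == "T")), numeric(4))
  }
  counts <- cbind(count_block(up_block), count_block(down_block))
  counts <- counts + pseudocount
  freqs <- sweep(counts, 2L, colSums(counts), "/")
  info <- apply(freqs, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  structure(list(
    counts = counts, information = info, n_sequences = n,
    anchor = "split",
    block = rep(c("upstream_hex1", "hex2_down"), c(up_w, down_w)),
    offsets = c(seq_len(up_w) - up_w - 1L + hl, seq_len(down_w) - 1L),
    n_skipped = n_skipped), class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d columns, n = %d (split-anchored)\n",
              ncol(x$counts), x$n_sequences))
  cat("information (bits):",
      paste(sprintf("%.2f", x$information), collapse = " "), "\n")
  invisible(x)
}

#' Write a conservation profile
#'
#' `write_profile_meme` emits the position frequency matrix in MEME
#' minimal format; `write_profile_tsv` the per-column counts and
#' information track.
#'
#' @param profile a `conservation_profile`.
#' @param path output file.
#' @param name motif name for the MEME header.
#' @return invisibly, `path`.
#' @export
write_profile_meme <- function(profile, path, name = "IR_box") {
  freqs <- sweep(profile$counts, 2L, colSums(profile$counts), "/")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               sprintf("MOTIF %s", name),
               sprintf(
                 "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                 ncol(freqs), profile$n_sequences)), con)
  writeLines(apply(freqs, 2L, function(p)
    sprintf(" %8.6f %8.6f %8.6f %8.6f", p[1], p[2], p[3], p[4])), con)
  invisible(path)
}

#' @rdname write_profile_meme
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(column = seq_len(ncol(profile$counts)),
                   block = profile$block, offset = profile$offsets,
                   t(profile$counts),
                   information_bits = profile$information)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
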