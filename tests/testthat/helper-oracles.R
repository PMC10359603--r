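# Independent brute-force reference implementations used as oracles.
# These deliberately take different code paths from the package.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# ORF finder oracle: translate every frame with Biostrings, split the
# protein on stops, locate the first M per segment.
oracle_find_orfs <- function(seq, min_len_codons, include_startless = FALSE) {
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    S <- if (strand == "+") seq else oracle_revcomp(seq)
    for (f in 0:2) {
      sub <- substr(S, f + 1L, f + 3L * ((n - f) %/% 3L))
      if (nchar(sub) < 3L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X",
        no.init.codon = TRUE))
      # segment boundaries between stops
      stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
      stops <- stops[stops > 0]
      bounds <- c(0L, stops, if (length(stops) == 0L ||
                                 max(stops) < nchar(aa)) nchar(aa) + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        cs <- bounds[b] + 1L
        ce <- bounds[b + 1L] - 1L
        if (ce < cs) next
        terminated <- bounds[b + 1L] <= nchar(aa)
        seg <- substr(aa, cs, ce)
        mpos <- regexpr("M", seg, fixed = TRUE)
        has_start <- mpos > 0L
        a <- if (has_start) cs + mpos - 1L else if (include_startless) cs
          else next
        if (ce - a + 1L < min_len_codons) next
        ls <- f + 3L * (a - 1L)
        le <- f + 3L * (ce + as.integer(terminated))
        fwd <- if (strand == "+") c(ls, le) else c(n - le, n - ls)
        out[[length(out) + 1L]] <- data.frame(
          start = fwd[1L], end = fwd[2L], strand = strand, frame = f,
          has_start = has_start, stop_terminated = terminated,
          translation = substr(aa, a, ce))
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      has_start = logical(), stop_terminated = logical(),
                      translation = character()))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$strand, df$frame, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Motif oracle: all-offsets Hamming scan via integer codes.
oracle_find_motif <- function(protein, motif = "AWEFLRRN",
                              max_mismatch = 2L, region_end = 60L) {
  p <- utf8ToInt(protein)
  m <- utf8ToInt(motif)
  w <- length(m)
  lim <- min(length(p), region_end) - w + 1L
  if (lim < 1L) return(NULL)
  best <- NULL
  for (s in seq_len(lim)) {
    mm <- sum(p[s:(s + w - 1L)] != m)
    if (is.null(best) || mm < best$mismatches) {
      best <- list(start = s, mismatches = mm,
                   match = substr(protein, s, s + w - 1L))
    }
  }
  if (best$mismatches > max_mismatch) return(NULL)
  best
}

# IR scan oracle: double loop with Biostrings mismatch counting.
oracle_scan_ir <- function(window, hexamer_len = 6L, spacers = c(15L, 16L),
                           max_mismatch = 1L) {
  L <- nchar(window)
  hits <- list()
  for (spacer in sort(spacers)) {
    span <- 2L * hexamer_len + spacer
    if (span > L) next
    for (p in 0:(L - span)) {
      h1 <- substr(window, p + 1L, p + hexamer_len)
      h2 <- substr(window, p + hexamer_len + spacer + 1L, p + span)
      rc1 <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(h1)))
      mm <- Biostrings::neditStartingAt(Biostrings::DNAString(h2),
                                        Biostrings::DNAString(rc1),
                                        starting.at = 1L)
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1L]] <- data.frame(
          hex1_start = p, spacer = spacer, mismatches = mm)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(hex1_start = integer(), spacer = integer(),
                      mismatches = integer()))
  df <- do.call(rbind, hits)
  df[order(df$mismatches, df$hex1_start, df$spacer), , drop = FALSE]
}

# Quadratic redundancy-filter reference.
oracle_redundancy <- function(windows, threshold = 0.90) {
  keep <- character(0)
  keep_idx <- integer(0)
  for (i in seq_along(windows)) {
    ident <- vapply(keep, function(k) {
      a <- strsplit(windows[i], "")[[1]]
      b <- strsplit(k, "")[[1]]
      sum(a == b) / length(a)
    }, numeric(1))
    if (all(ident < threshold)) {
      keep <- c(keep, windows[i])
      keep_idx <- c(keep_idx, i)
    }
  }
  windows[keep_idx]
}

# Residue-counting charge oracle.
oracle_net_charge <- function(seq, count_n = FALSE, count_c = FALSE) {
  r <- strsplit(seq, "")[[1]]
  z <- sum(r == "R") + sum(r == "K") - sum(r == "D") - sum(r == "E")
  z + as.integer(count_n) - as.integer(count_c)
}

# Rotation from a unit quaternion.
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3L, byrow = TRUE)
}

rmsd_under_rot <- function(a0, b0, R) {
  d <- a0 %*% t(R) - b0
  sqrt(sum(d^2) / nrow(a0))
}

# Brute-force superposition: random quaternion sampling followed by
# local grid refinement.
oracle_superpose_rmsd <- function(a, b, n_coarse = 600L, n_refine = 40L) {
  a0 <- sweep(a, 2L, colMeans(a))
  b0 <- sweep(b, 2L, colMeans(b))
  qs <- matrix(rnorm(4L * n_coarse), ncol = 4L)
  vals <- apply(qs, 1L, function(q) rmsd_under_rot(a0, b0, quat_to_rot(q)))
  best_q <- qs[which.min(vals), ]
  best <- min(vals)
  scale <- 0.5
  for (it in seq_len(n_refine)) {
    cand <- matrix(rnorm(4L * 30L, mean = rep(best_q, each = 30L),
                         sd = scale), ncol = 4L)
    v <- apply(cand, 1L, function(q) rmsd_under_rot(a0, b0, quat_to_rot(q)))
    if (min(v) < best) {
      best <- min(v)
      best_q <- cand[which.min(v), ]
    }
    scale <- scale * 0.7
  }
  best
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
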