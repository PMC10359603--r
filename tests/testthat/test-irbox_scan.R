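# Inverted-repeat scanning, redundancy filtering, split-anchor profiles.

planted_window <- function(hex1 = "TGACGT", spacer = 16, pre = 20,
                           post = 22, seed = 1) {
  set.seed(seed)
  paste0(random_dna_str(pre), hex1, random_dna_str(spacer), revcomp(hex1),
         random_dna_str(post))
}

test_that("scan_ir reports the planted box with the stated geometry", {
  w <- planted_window(spacer = 16)
  hits <- scan_ir(w, max_mismatch = 0)
  perfect <- hits[hits$mismatches == 0, ]
  expect_equal(nrow(perfect), 1L)
  expect_equal(perfect$hex1_start, 20L)
  expect_equal(perfect$spacer, 16L)
  expect_equal(perfect$total_span, 28L)
  expect_identical(perfect$hex2, revcomp(perfect$hex1))
})

test_that("scan_ir trivia: homopolymers and input validation", {
  w <- strrep("A", 60)
  expect_equal(nrow(scan_ir(w, max_mismatch = 0)), 0L)
  expect_error(scan_ir("ACGT"), "shorter")
})

test_that("scan_ir agrees with the brute-force double-loop oracle", {
  set.seed(7)
  for (i in 1:30) {
    w <- random_dna_str(sample(40:90, 1))
    mm <- sample(0:2, 1)
    got <- scan_ir(w, max_mismatch = mm)
    ref <- oracle_scan_ir(w, max_mismatch = mm)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(got) > 0) {
      expect_identical(got[, c("hex1_start", "spacer", "mismatches")],
                       `rownames<-`(ref, NULL))
    }
  }
})

test_that("scan_ir is translation-equivariant", {
  w <- planted_window(spacer = 15, seed = 3)
  k <- 13L
  ext <- paste0(random_dna_str(k, gc = 0.5), w)
  h0 <- scan_ir(w, max_mismatch = 1)
  h1 <- scan_ir(ext, max_mismatch = 1)
  h1 <- h1[h1$hex1_start >= k, , drop = FALSE]
  h1$hex1_start <- h1$hex1_start - k
  h1$hex2_start <- h1$hex2_start - k
  o0 <- h0[order(h0$hex1_start, h0$spacer), ]
  o1 <- h1[order(h1$hex1_start, h1$spacer), ]
  rownames(o0) <- rownames(o1) <- NULL
  expect_identical(o0, o1)
})

test_that("redundancy_filter keeps/removes per the greedy identity rule", {
  w <- planted_window()
  expect_equal(length(redundancy_filter(c(w, w))), 1L)
  # two windows at 85% identity survive a 90% threshold
  w2 <- w
  pos <- seq(1, by = 5, length.out = ceiling(0.15 * nchar(w)))
  for (p in pos) substr(w2, p, p) <- chartr("ACGT", "CGTA",
                                            substr(w2, p, p))
  # ensure true identity < 0.9
  id <- mean(strsplit(w, "")[[1]] == strsplit(w2, "")[[1]])
  expect_lt(id, 0.9)
  expect_equal(length(redundancy_filter(c(w, w2), 0.9)), 2L)
  expect_error(redundancy_filter(c("ACGT", "ACGTA")), "equal length")
})

test_that("redundancy_filter agrees with the quadratic oracle", {
  set.seed(21)
  for (i in 1:10) {
    base <- random_dna_str(50)
    ws <- vapply(1:30, function(j) {
      w <- base
      nmut <- sample(0:20, 1)
      for (p in sample(50, nmut)) {
        substr(w, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      w
    }, character(1))
    expect_identical(redundancy_filter(ws, 0.9), oracle_redundancy(ws, 0.9))
  }
})

test_that("split_profile: identical windows give 2 bits everywhere", {
  w <- planted_window(spacer = 16)
  ws <- rep(w, 10)
  boxes <- data.frame(hex1_start = rep(20L, 10), hex2_start = rep(42L, 10),
                      hexamer_len = 6L)
  prof <- split_profile(ws, boxes)
  expect_true(all(abs(prof$information - 2) < 1e-12))
  expect_true(all(colSums(prof$counts) == 10))
})

test_that("split_profile recovers planted conservation structure (n = 500)", {
  # invariant central two bases per hexamer, all other positions uniform
  pfm <- ir_default_pfm(p_flank = 0.25, p_core = 1)
  ups <- gen_upstreams(500, pfm = pfm, seed = 17)
  boxes <- ups$truth
  boxes$hexamer_len <- 6L
  prof <- split_profile(as.character(ups$windows), boxes)
  hex1_cols <- which(prof$block == "upstream_hex1")
  hex1_cols <- tail(hex1_cols, 6)
  hex2_cols <- which(prof$block == "hex2_down")[1:6]
  core <- c(hex1_cols[3:4], hex2_cols[3:4])
  non_core <- setdiff(c(hex1_cols, hex2_cols), core)
  expect_true(all(prof$information[core] > 1.9))
  expect_true(all(prof$information[non_core] < 0.1))
  expect_true(all(colSums(prof$counts) == prof$n_sequences))
})

test_that("anchored stacking removes spacer smearing that a naive stack shows", {
  pfm <- ir_default_pfm(p_flank = 1, p_core = 1)  # invariant hexamers
  ups <- gen_upstreams(200, spacer_probs = c("15" = 0.5, "16" = 0.5),
                       pfm = pfm, seed = 23)
  ws <- as.character(ups$windows)
  boxes <- ups$truth
  boxes$hexamer_len <- 6L
  prof <- split_profile(ws, boxes)
  hex2_cols <- which(prof$block == "hex2_down")[1:6]
  expect_true(all(prof$information[hex2_cols] == 2))
  # naive fixed-coordinate stack of the hexamer-2 region smears 15/16 mixes
  naive <- vapply(seq_along(ws), function(i)
    substr(ws[i], boxes$hex1_start[i] + 23, boxes$hex1_start[i] + 28),
    character(1))  # fixed offset assumes spacer 16
  counts <- vapply(1:6, function(j) {
    col <- substr(naive, j, j)
    c(sum(col == "A"), sum(col == "C"), sum(col == "G"), sum(col == "T"))
  }, numeric(4))
  freqs <- sweep(counts, 2, colSums(counts), "/")
  naive_info <- apply(freqs, 2, function(p) {
    p <- p[p > 0]; 2 + sum(p * log2(p))
  })
  expect_lt(min(naive_info), 1.5)
})

test_that("reverse-complementing every window mirrors the profile", {
  ups <- gen_upstreams(120, seed = 31)
  ws <- as.character(ups$windows)
  boxes <- ups$truth
  boxes$hexamer_len <- 6L
  prof <- split_profile(ws, boxes)
  rc_ws <- revcomp(ws)
  L <- nchar(ws[1])
  rc_boxes <- data.frame(
    hex1_start = L - boxes$hex2_start - 6L,
    hex2_start = L - boxes$hex1_start - 6L,
    hexamer_len = 6L)
  rc_prof <- split_profile(rc_ws, rc_boxes)
  mirrored <- rc_prof$counts[c("T", "G", "C", "A"),
                             rev(seq_len(ncol(rc_prof$counts)))]
  rownames(mirrored) <- c("A", "C", "G", "T")
  expect_equal(unname(prof$counts), unname(mirrored))
  expect_equal(prof$information, rev(rc_prof$information))
})

test_that("split_profile skips windows without an anchor, with a warning", {
  ups <- gen_upstreams(5, seed = 2)
  boxes <- ups$truth
  boxes$hexamer_len <- 6L
  boxes$hex1_start[2] <- NA
  expect_warning(prof <- split_profile(as.character(ups$windows), boxes),
                 "without anchor")
  expect_equal(prof$n_sequences, 4L)
  expect_equal(prof$n_skipped, 1L)
})
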