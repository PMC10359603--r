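# ORF finding, +1 PRF detection and fusion.

test_that("find_orfs handles hand-translatable cases and strand symmetry", {
  orfs <- find_orfs("ATGAAATAA", min_len_codons = 2)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$translation, "MK")
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$end, 9L)
  expect_true(orfs$stop_terminated)
  # reverse complement: same ORF on the minus strand, same translation
  rc <- revcomp("ATGAAATAA")
  orfs_rc <- find_orfs(rc, min_len_codons = 2)
  expect_equal(nrow(orfs_rc), 1L)
  expect_equal(orfs_rc$strand, "-")
  expect_equal(orfs_rc$translation, "MK")
  expect_equal(c(orfs_rc$start, orfs_rc$end), c(0L, 9L))
})

test_that("find_orfs agrees with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:8) {
    s <- random_dna_str(sample(300:900, 1), gc = runif(1, 0.3, 0.7))
    for (min_len in c(5, 20)) {
      got <- find_orfs(s, min_len_codons = min_len)
      ref <- oracle_find_orfs(s, min_len_codons = min_len)
      cols <- c("start", "end", "strand", "frame", "has_start",
                "stop_terminated", "translation")
      expect_identical(got[, cols], ref[, cols])
      got2 <- find_orfs(s, min_len_codons = min_len,
                        include_startless = TRUE)
      ref2 <- oracle_find_orfs(s, min_len_codons = min_len,
                               include_startless = TRUE)
      expect_identical(got2[, cols], ref2[, cols])
    }
  }
})

test_that("find_orfs flags N-dense sequences without failing", {
  s <- paste0(strrep("N", 80), "ATGAAAAAAAAATAA")
  out <- find_orfs(s, min_len_codons = 2)
  expect_true(isTRUE(attr(out, "n_dense")))
  expect_gte(nrow(out), 1L)
})

test_that("detect_prf calls planted sites and respects mismatch limits", {
  spec <- sim_locus_spec(seed = 3, n_fsea_like = 3, n_qsem_like = 2,
                         n_decoys = 0, mutation_rate = 0)
  sim <- gen_loci(spec)
  for (i in which(sim$truth$class == "FSEA_LIKE")) {
    loc <- list(id = sim$truth$id[i],
                sequence = as.character(sim$loci[[i]]))
    calls <- detect_prf(loc)
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$motif_start, sim$truth$prf_pos[i])
    expect_equal(calls$motif_mismatches, 0L)
    # the reported downstream ORF may start at an ATG upstream of the
    # planted one (same +1-frame segment), so the observed overlap is
    # the planted one plus a multiple of 3
    expect_gte(calls$overlap_nt, spec$overlap_nt)
    expect_equal((calls$overlap_nt - spec$overlap_nt) %% 3L, 0L)
  }
  for (i in which(sim$truth$class == "QSEM_LIKE")) {
    loc <- list(id = sim$truth$id[i],
                sequence = as.character(sim$loci[[i]]))
    expect_equal(nrow(detect_prf(loc)), 0L)
  }
  # mutate one motif base (G -> C at motif position 3, frame-neutral)
  i <- which(sim$truth$class == "FSEA_LIKE")[1]
  s <- as.character(sim$loci[[i]])
  p <- sim$truth$prf_pos[i]
  substr(s, p + 3, p + 3) <- "C"
  loc <- list(id = "mut", sequence = s)
  expect_equal(nrow(detect_prf(loc, max_mismatch = 0)), 0L)
  calls1 <- detect_prf(loc, max_mismatch = 1)
  expect_equal(nrow(calls1), 1L)
  expect_equal(calls1$motif_mismatches, 1L)
  expect_equal(calls1$motif_start, p)
})

test_that("fuse_prf reproduces planted fusions, junction and length arithmetic", {
  spec <- sim_locus_spec(seed = 5, n_fsea_like = 4, n_qsem_like = 0,
                         n_decoys = 0, mutation_rate = 0)
  sim <- gen_loci(spec)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    loc <- list(id = tr$id, sequence = as.character(sim$loci[[i]]))
    call <- detect_prf(loc)[1, ]
    rp <- fuse_prf(loc, call)
    expect_identical(rp$sequence, tr$protein)
    expect_equal(rp$provenance, "PRF_FUSED")
    expect_equal(rp$junction_residue, tr$junction_residue)
    # junction reads W,G (TGG|GGG across the edit)
    expect_equal(substr(rp$sequence, rp$junction_residue - 1,
                        rp$junction_residue), "WG")
    # length = upstream codons to motif end + downstream codons after edit
    up_cod <- (call$motif_start + 6 - call$up_local_start) / 3
    down_cod <- (call$down_local_end - 3 - (call$motif_start + 7)) / 3
    expect_equal(nchar(rp$sequence), up_cod + down_cod)
  }
})

test_that("fuse_prf identity case and fusion error", {
  orfs <- find_orfs("ATGAAATGGAAATAA", min_len_codons = 2)
  rp <- fuse_prf("ATGAAATGGAAATAA", NULL, orf = orfs[1, ])
  expect_equal(rp$sequence, "MKWK")
  expect_equal(rp$provenance, "SINGLE_ORF")
  expect_true(is.na(rp$junction_residue))
  # hand-built call whose downstream frame hits a stop right after the
  # +1 edit: motif ends at position 12, one base skipped, then TAA
  s <- paste0("ATGAAATGGGGG", "G", "TAA", "GCTAAATAA")
  call <- data.frame(locus_id = "x", strand = "+", up_start = 0,
                     up_end = 18, down_start = 7, down_end = 25,
                     motif_start = 6L, motif_start_fwd = 6L,
                     motif_seq = "TGGGGG", motif_mismatches = 0L,
                     shift = "+1", overlap_nt = 5L, up_local_start = 0L,
                     up_local_end = 18L, down_local_start = 7L,
                     down_local_end = 25L)
  expect_error(fuse_prf(s, call), class = "dufscout_fusion_error")
})

test_that("strand invariance: reverse-complemented loci give identical proteins", {
  spec <- sim_locus_spec(seed = 8, n_fsea_like = 5, n_qsem_like = 3,
                         n_decoys = 2, mutation_rate = 0)
  sim <- gen_loci(spec)
  fwd <- reconstruct_proteins(sim$loci)
  rc <- setNames(revcomp(as.character(sim$loci)), names(sim$loci))
  rev <- reconstruct_proteins(rc)
  expect_identical(fwd$sequence, rev$sequence)
  expect_identical(fwd$provenance, rev$provenance)
})

test_that("round trip recovers every planted fusion at mutation_rate 0", {
  spec <- sim_locus_spec(seed = 2, n_fsea_like = 10, n_qsem_like = 4,
                         n_decoys = 2, mutation_rate = 0)
  sim <- gen_loci(spec)
  rec <- reconstruct_proteins(sim$loci)
  fsea <- sim$truth$class == "FSEA_LIKE"
  expect_identical(rec$sequence[fsea], sim$truth$protein[fsea])
  expect_true(all(rec$provenance[fsea] == "PRF_FUSED"))
  expect_identical(rec$prf_pos[fsea], sim$truth$prf_pos[fsea])
  # non-PRF loci yield single-ORF translations, and the planted gene is
  # always among the ORFs found (the longest ORF reported may be a
  # spurious reverse-strand ORF on short decoys)
  other <- which(!fsea)
  expect_true(all(rec$provenance[other] == "SINGLE_ORF"))
  for (i in other) {
    orfs <- find_orfs(list(id = sim$truth$id[i],
                           sequence = as.character(sim$loci[[i]])))
    expect_true(sim$truth$protein[i] %in% sub("\\*$", "", orfs$translation))
  }
})
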