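# Shared fixture builders (constructed in code; no stored data).

# Candidate protein set with planted curation outcomes: motif-bearing
# keepers, motif-free antiactivator-like keepers, over-length records,
# records with ambiguous residues, and lone-DUF6499 duplicates.
make_curation_set <- function(n_fsea = 30, n_qsem = 10, n_long = 3,
                              n_ambig = 3, n_dup = 2, prf_frac = 0.5,
                              seed = 1) {
  set.seed(seed)
  fsea <- as.character(replicate(n_fsea,
    paste0(random_protein(30), "AWEFLRRN", random_protein(150))))
  qsem <- as.character(replicate(n_qsem, {
    repeat {
      s <- random_protein(100)
      if (is.null(find_motif(s))) break
    }
    s
  }))
  long <- as.character(replicate(n_long,
    paste0(random_protein(30), "AWEFLRRN", random_protein(380))))
  ambig <- as.character(replicate(n_ambig,
    paste0(random_protein(30), "AWEFLRRN", "X", random_protein(100))))
  dup <- as.character(replicate(n_dup,
    paste0(random_protein(30), "AWEFLRRN", random_protein(120))))
  df <- data.frame(
    id = sprintf("c%03d", seq_len(n_fsea + n_qsem + n_long + n_ambig +
                                    n_dup)),
    sequence = c(fsea, qsem, long, ambig, dup),
    truth = rep(c("KEEP_FSEA", "KEEP_QSEM", "TOO_LONG", "AMBIGUOUS",
                  "DUPLICATE_DUF6499"),
                c(n_fsea, n_qsem, n_long, n_ambig, n_dup)))
  df$provenance <- ifelse(
    df$truth == "KEEP_FSEA" &
      seq_len(nrow(df)) <= round(prf_frac * n_fsea),
    "PRF_FUSED", "SINGLE_ORF")
  df
}
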