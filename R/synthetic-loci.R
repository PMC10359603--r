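# Synthetic locus generator: plants FseA-like two-ORF +1-PRF genes,
# QseM-like single-ORF genes, and decoy ORFs, with full ground truth.

#' Specification for the synthetic locus generator
#'
#' Bundles all tunable parameters of [gen_loci()]. Defaults emulate an
#' FseA-like gene pair: a ~160-codon upstream ORF carrying the
#' `AWEFLRRN` motif at residues 31-38, a downstream ORF overlapping it
#' in the +1 frame, joined at a `TGGGGG` slippery site near the
#' upstream stop.
#'
#' @param seed integer RNG seed; identical spec + seed reproduces
#'   identical bytes.
#' @param n_fsea_like,n_qsem_like,n_decoys counts of each planted class.
#' @param orf1_len_codons,orf2_len_codons coding lengths (excluding the
#'   stop codon) of the upstream and downstream ORFs.
#' @param overlap_nt overlap between the two ORFs in nucleotides. The
#'   +1 frame relation with a codon-aligned downstream ATG forces
#'   `overlap_nt %% 3 == 2` and `overlap_nt >= 8`; other values raise a
#'   construction error.
#' @param slippery_motif DNA 6-mer at which the +1 shift occurs
#'   (coding strand; mRNA UGGGGG).
#' @param background_gc GC fraction of flanking background sequence.
#' @param mutation_rate per-site substitution probability applied to the
#'   finished locus (truth records keep the unmutated values).
#' @return object of class `sim_locus_spec`.
#' @export
sim_locus_spec <- function(seed = 1L, n_fsea_like = 10L, n_qsem_like = 5L,
                           n_decoys = 5L, orf1_len_codons = 160L,
                           orf2_len_codons = 110L, overlap_nt = 8L,
                           slippery_motif = "TGGGGG", background_gc = 0.6,
                           mutation_rate = 0) {
  spec <- list(seed = as.integer(seed), n_fsea_like = as.integer(n_fsea_like),
               n_qsem_like = as.integer(n_qsem_like),
               n_decoys = as.integer(n_decoys),
               orf1_len_codons = as.integer(orf1_len_codons),
               orf2_len_codons = as.integer(orf2_len_codons),
               overlap_nt = as.integer(overlap_nt),
               slippery_motif = toupper(slippery_motif),
               background_gc = background_gc, mutation_rate = mutation_rate)
  validate_sim_locus_spec(spec)
  structure(spec, class = "sim_locus_spec")
}

validate_sim_locus_spec <- function(spec) {
  stopifnot(spec$n_fsea_like >= 0L, spec$n_qsem_like >= 0L,
            spec$n_decoys >= 0L)
  if (nchar(spec$slippery_motif) != 6L || !is_dna(spec$slippery_motif))
    stop("slippery_motif must be a DNA 6-mer")
  if (spec$overlap_nt < 1L)
    stop("overlap_nt must be >= 1")
  if (spec$overlap_nt >= 3L * min(spec$orf1_len_codons, spec$orf2_len_codons))
    stop("overlap_nt must be < 3 * min(orf1_len_codons, orf2_len_codons)")
  if (spec$background_gc < 0 || spec$background_gc > 1)
    stop("background_gc must lie in [0, 1]")
  if (spec$mutation_rate < 0 || spec$mutation_rate > 1)
    stop("mutation_rate must lie in [0, 1]")
  invisible(spec)
}

# Hexamer consensus used for the IR planted upstream of FSEA_LIKE loci.
# The operator hexamer sequence itself is a free choice of the
# generator's stated world (non-palindromic, two central bases are the
# conserved core by default in gen_upstreams()).
IR_CONSENSUS_HEX <- "TGACGT"
FSEA_MOTIF <- "AWEFLRRN"

signal_construction_error <- function(msg) {
  stop(errorCondition(msg, class = "dufscout_construction_error"))
}

# Build one FSEA_LIKE gene (relative coords). Returns list(gene = chr
# vector of nt, layout = list of relative 0-based coordinates).
build_fsea_gene <- function(L1, L2, v, slippery, max_try = 500L) {
  if (L1 < 45L)
    signal_construction_error("orf1_len_codons must be >= 45 to hold ATG, AWEFLRRN (residues 31-38) and the slippery site")
  if (L2 < 5L)
    signal_construction_error("orf2_len_codons must be >= 5")
  if (v %% 3L != 2L || v < 8L)
    signal_construction_error(paste0(
      "overlap_nt = ", v, " is geometrically impossible: a codon-aligned ",
      "downstream ATG in the +1 frame requires overlap_nt >= 8 and ",
      "overlap_nt %% 3 == 2"))
  a2 <- 3L * L1 + 3L - v                 # ORF2 ATG, relative 0-based
  motif_start <- 3L * L1 - 18L           # slippery site spans 2 codons
  if (a2 < 114L || (a2 < motif_start + 6L && a2 + 3L > motif_start))
    signal_construction_error(
      "overlap_nt places the downstream ATG over the AWEFLRRN or slippery-site codons")
  resume <- 3L * L1 - 11L                # first nt read after the +1 edit
  glen <- a2 + 3L * L2 + 3L
  for (i in seq_len(max_try)) {
    orf1 <- character(L1)
    orf1[1L] <- "ATG"
    orf1[2:30] <- random_codons(29L)
    orf1[31:38] <- random_codons(8L, FSEA_MOTIF)
    if (L1 > 39L) orf1[39:L1] <- random_codons(L1 - 38L)
    orf1[L1 - 5L] <- substr(slippery, 1L, 3L)
    orf1[L1 - 4L] <- substr(slippery, 4L, 6L)
    g <- strsplit(paste0(paste(orf1, collapse = ""), "TAA"), "")[[1]]
    # the 3' extension carries ORF2 in the +1 frame: one free base
    # completes the codon straddling the ORF1 stop (AA_x, never a stop),
    # then sense codons to the ORF2 stop
    n_fill_codons <- (a2 + 3L * L2 - (3L * L1 + 4L)) %/% 3L
    g <- c(g, sample(c("A", "C", "G", "T"), 1L),
           strsplit(paste(random_codons(n_fill_codons), collapse = ""),
                    "")[[1]],
           c("T", "A", "A"))
    stopifnot(length(g) == glen)
    g[(a2 + 1L):(a2 + 3L)] <- c("A", "T", "G")
    seqstr <- paste(g, collapse = "")
    # frame-0 integrity of ORF1 (ATG overwrite cannot create a stop, but
    # keep the check cheap and explicit)
    if (any(codons_of(substr(seqstr, 1L, 3L * L1)) %in% STOP_CODONS)) next
    # +1 frame must be stop-free from min(resume, ATG) to the ORF2 stop
    q <- min(resume, a2)
    f1 <- codons_of(substr(seqstr, q + 1L, a2 + 3L * L2))
    if (any(f1 %in% STOP_CODONS)) next
    # the planted slippery site must be the only codon-aligned occurrence
    # in the upstream ORF's 3' window, so a PRF caller lands on it
    win_lo <- max(0L, 3L * L1 - 45L)
    aligned <- seq.int(win_lo, 3L * L1 - 6L, by = 3L)
    hits <- aligned[vapply(aligned, function(p)
      substr(seqstr, p + 1L, p + 6L) == slippery, logical(1))]
    if (!identical(hits, motif_start)) next
    return(list(gene = seqstr,
                layout = list(orf1_start = 0L, orf1_end = 3L * L1 + 3L,
                              orf2_start = a2, orf2_end = a2 + 3L * L2 + 3L,
                              motif_start = motif_start, resume = resume)))
  }
  signal_construction_error(
    "could not construct an FSEA_LIKE gene satisfying all frame constraints")
}

# Single-ORF gene whose protein has no AWEFLRRN-like hit (Hamming <= 2)
# in its first 60 residues, so planted classes are unambiguous.
build_single_orf_gene <- function(len_codons, max_try = 200L) {
  for (i in seq_len(max_try)) {
    cod <- c("ATG", random_codons(len_codons - 1L))
    seqstr <- paste0(paste(cod, collapse = ""), "TAA")
    prot <- translate_dna(substr(seqstr, 1L, 3L * len_codons))
    if (is.null(motif_best_hit(prot, FSEA_MOTIF, 2L, 60L))) {
      return(seqstr)
    }
  }
  signal_construction_error("could not construct a motif-free single-ORF gene")
}

mutate_seq <- function(seqstr, rate) {
  if (rate <= 0) return(seqstr)
  g <- strsplit(seqstr, "")[[1]]
  hit <- runif(length(g)) < rate
  if (any(hit)) {
    g[hit] <- vapply(g[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
      USE.NAMES = FALSE)
  }
  paste(g, collapse = "")
}

#' Generate synthetic loci with planted PRF genes and ground truth
#'
#' Emulates a database of FseA-like loci: each `FSEA_LIKE` locus carries
#' two ORFs overlapping in the +1 frame, joined at a slippery site whose
#' +1 edit yields the recorded fusion protein; `QSEM_LIKE` loci carry a
#' single motif-free ORF; decoys are random ORFs. An FseA-box-like
#' inverted repeat is planted in the 5' flank of each `FSEA_LIKE` locus.
#'
#' @param spec a [sim_locus_spec()].
#' @param flank_nt length of background flanks (default 60).
#' @return list with elements `loci` (named [Biostrings::DNAStringSet]),
#'   `annotations` ([GenomicRanges::GRanges] of CDS features, importable
#'   as GFF3), and `truth` (data.frame: one row per locus with class,
#'   planted protein, 0-based PRF motif start, junction residue, ORF and
#'   IR coordinates, and the pre-mutation sequence in `sequence_clean`).
#'   Coordinates in `truth` are 0-based half-open;
#'   `annotations` follow GFF3 1-based inclusive convention.
#' @param misannotate if `TRUE`, the ORF1 (upstream) annotation is
#'   omitted from `annotations`, emulating the misannotated loci in
#'   public databases; sequences and truth are unchanged.
#' @export
gen_loci <- function(spec, flank_nt = 60L, misannotate = FALSE) {
  validate_sim_locus_spec(spec)
  set.seed(spec$seed)
  n_tot <- spec$n_fsea_like + spec$n_qsem_like + spec$n_decoys
  ids <- sprintf("locus_%03d", seq_len(max(n_tot, 1L)))[seq_len(n_tot)]
  classes <- rep(c("FSEA_LIKE", "QSEM_LIKE", "DECOY"),
                 c(spec$n_fsea_like, spec$n_qsem_like, spec$n_decoys))
  seqs <- character(n_tot)
  truth <- vector("list", n_tot)
  ann <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    id <- ids[i]
    if (classes[i] == "FSEA_LIKE") {
      # plant an operator-like IR in the 5' flank
      spacer <- sample(c(15L, 16L), 1L)
      ir_rel <- 10L
      flank5 <- paste0(
        random_dna(ir_rel, spec$background_gc),
        IR_CONSENSUS_HEX,
        random_dna(spacer, spec$background_gc),
        revcomp(IR_CONSENSUS_HEX),
        random_dna(flank_nt - ir_rel - 12L - spacer, spec$background_gc))
      # in-frame stop just before the gene, so the planted ATG is the
      # first start of its stop-to-stop segment
      substr(flank5, flank_nt - 2L, flank_nt) <- "TAA"
      built <- build_fsea_gene(spec$orf1_len_codons, spec$orf2_len_codons,
                               spec$overlap_nt, spec$slippery_motif)
      off <- nchar(flank5)
      lay <- lapply(built$layout, function(p) p + off)
      seqstr <- paste0(flank5, built$gene,
                       random_dna(flank_nt, spec$background_gc))
      part1 <- substr(seqstr, lay$orf1_start + 1L, lay$motif_start + 6L)
      part2 <- substr(seqstr, lay$resume + 1L, lay$orf2_end - 3L)
      prot <- paste0(translate_dna(part1), translate_dna(part2))
      stopifnot(!grepl("\\*", prot))
      truth[[i]] <- data.frame(
        id = id, class = "FSEA_LIKE", protein = prot,
        prf_pos = lay$motif_start, junction_residue = nchar(part1) %/% 3L,
        orf1_start = lay$orf1_start, orf1_end = lay$orf1_end,
        orf2_start = lay$orf2_start, orf2_end = lay$orf2_end,
        ir_start = ir_rel, ir_spacer = spacer,
        sequence_clean = seqstr)
      ann[[i]] <- data.frame(
        seqnames = id,
        start = c(lay$orf1_start, lay$orf2_start) + 1L,
        end = c(lay$orf1_end, lay$orf2_end),
        type = "CDS", orf = c("orf1", "orf2"),
        ID = paste0(id, c(".orf1", ".orf2")))
      if (misannotate) ann[[i]] <- ann[[i]][-1L, , drop = FALSE]
    } else {
      len <- if (classes[i] == "QSEM_LIKE") spec$orf2_len_codons else
        sample(30:80, 1L)
      gene <- build_single_orf_gene(len)
      flank5 <- random_dna(flank_nt, spec$background_gc)
      substr(flank5, flank_nt - 2L, flank_nt) <- "TAA"
      seqstr <- paste0(flank5, gene, random_dna(flank_nt, spec$background_gc))
      prot <- translate_dna(substr(seqstr, flank_nt + 1L, flank_nt + 3L * len))
      truth[[i]] <- data.frame(
        id = id, class = classes[i], protein = prot, prf_pos = NA_integer_,
        junction_residue = NA_integer_,
        orf1_start = flank_nt, orf1_end = flank_nt + 3L * len + 3L,
        orf2_start = NA_integer_, orf2_end = NA_integer_,
        ir_start = NA_integer_, ir_spacer = NA_integer_,
        sequence_clean = seqstr)
      ann[[i]] <- data.frame(
        seqnames = id, start = flank_nt + 1L, end = flank_nt + 3L * len + 3L,
        type = "CDS", orf = "orf1", ID = paste0(id, ".orf1"))
    }
    seqs[i] <- mutate_seq(seqstr, spec$mutation_rate)
  }
  truth <- if (n_tot) do.call(rbind, truth) else
    data.frame(id = character(), class = character(), protein = character())
  anndf <- if (n_tot) do.call(rbind, ann) else NULL
  loci <- Biostrings::DNAStringSet(setNames(seqs, ids))
  gr <- if (!is.null(anndf) && nrow(anndf)) {
    g <- GenomicRanges::GRanges(
      seqnames = anndf$seqnames,
      ranges = IRanges::IRanges(anndf$start, anndf$end),
      strand = "+")
    S4Vectors::mcols(g)$type <- anndf$type
    S4Vectors::mcols(g)$phase <- 0L
    S4Vectors::mcols(g)$ID <- anndf$ID
    S4Vectors::mcols(g)$orf <- anndf$orf
    GenomeInfoDb_safe_seqlevels(g, ids)
  } else GenomicRanges::GRanges()
  list(loci = loci, annotations = gr, truth = truth)
}

# keep all locus ids as seqlevels so empty loci round-trip through GFF3
GenomeInfoDb_safe_seqlevels <- function(gr, ids) {
  GenomeInfoDb::seqlevels(gr) <- unique(c(GenomeInfoDb::seqlevels(gr), ids))
  gr
}

#' Write a simulated locus set to disk
#'
#' Emits `loci.fa` (FASTA), `orfs.gff3` (GFF3, 1-based inclusive),
#' and `truth.json`.
#'
#' @param sim result of [gen_loci()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim_loci <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "loci.fa")
  gff <- file.path(dir, "orfs.gff3")
  js <- file.path(dir, "truth.json")
  Biostrings::writeXStringSet(sim$loci, fa)
  rtracklayer::export(sim$annotations, gff, format = "gff3")
  jsonlite::write_json(sim$truth, js, dataframe = "rows", na = "null",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(c(fasta = fa, gff3 = gff, truth = js))
}
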