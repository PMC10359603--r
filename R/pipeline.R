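# End-to-end orchestration with a single flat config, reproducible
# seeds, and a provenance manifest.

#' Default pipeline configuration
#'
#' One flat document with per-stage sections; every threshold carries
#' the documented default. CLI flags and user configs override fields.
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "dufscout_run",
    stages = c("simulate", "reconstruct", "curate", "irscan", "charge",
               "emsafit"),
    inputs = list(loci_fasta = NULL, windows_fasta = NULL, emsa_tsv = NULL),
    simulate = list(n_fsea_like = 10L, n_qsem_like = 5L, n_decoys = 5L,
                    orf1_len_codons = 160L, orf2_len_codons = 110L,
                    overlap_nt = 8L, slippery_motif = "TGGGGG",
                    background_gc = 0.6, mutation_rate = 0,
                    misannotate = FALSE, n_upstreams = 50L,
                    emsa_concentrations = c(4, 12, 30, 60, 125, 250, 500),
                    emsa_kd = 30, emsa_hill = 1.5, emsa_bmax = 1,
                    emsa_noise_sd = 0.05, emsa_constant_unbound_frac = 0.2,
                    emsa_n_reps = 3L),
    reconstruct = list(motif = "TGGGGG", max_mismatch = 0L, window_nt = 45L,
                       min_len_codons = 30L),
    curate = list(max_len = 400L, max_mismatch = 2L, motif = "AWEFLRRN",
                  region_end = 60L),
    irscan = list(hexamer_len = 6L, spacers = c(15L, 16L), max_mismatch = 1L,
                  redundancy_threshold = 0.90),
    charge = list(window = 20L, count_n_terminus = FALSE,
                  count_c_terminus = TRUE),
    emsafit = list(cv_threshold = 0.10, response = "fraction"))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the discovery pipeline end to end
#'
#' Executes the enabled stages in order, writing per-stage outputs and
#' a provenance manifest (`manifest.json`: config hash, package
#' version, per-stage record counts) into `out_dir`. Identical config
#' and inputs yield byte-identical outputs. Any stage error halts the
#' run with the stage name attached.
#'
#' @param config a (partial) configuration list merged over
#'   [default_config()], or a path to a JSON file of one.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- merge_config(default_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  counts <- list()
  stage <- "init"
  truth <- NULL
  result <- tryCatch({
    loci <- NULL
    windows <- NULL
    lanes <- NULL
    if ("simulate" %in% cfg$stages) {
      stage <- "simulate"
      s <- cfg$simulate
      spec <- sim_locus_spec(seed = cfg$seed, n_fsea_like = s$n_fsea_like,
                             n_qsem_like = s$n_qsem_like,
                             n_decoys = s$n_decoys,
                             orf1_len_codons = s$orf1_len_codons,
                             orf2_len_codons = s$orf2_len_codons,
                             overlap_nt = s$overlap_nt,
                             slippery_motif = s$slippery_motif,
                             background_gc = s$background_gc,
                             mutation_rate = s$mutation_rate)
      sim <- gen_loci(spec, misannotate = isTRUE(s$misannotate))
      write_sim_loci(sim, cfg$out_dir)
      truth <- sim$truth
      loci <- sim$loci
      ups <- gen_upstreams(s$n_upstreams, seed = cfg$seed + 1L)
      Biostrings::writeXStringSet(ups$windows,
                                  file.path(cfg$out_dir, "upstreams.fa"))
      windows <- ups$windows
      lanes <- gen_emsa(s$emsa_concentrations, kd = s$emsa_kd,
                        hill = s$emsa_hill, bmax = s$emsa_bmax,
                        noise_sd = s$emsa_noise_sd,
                        constant_unbound_frac = s$emsa_constant_unbound_frac,
                        n_reps = s$emsa_n_reps, seed = cfg$seed + 2L)
      write_emsa_tsv(lanes, file.path(cfg$out_dir, "emsa.tsv"))
      counts$simulate <- list(loci = length(loci),
                              upstream_windows = length(windows),
                              emsa_lanes = nrow(lanes))
    } else {
      if (!is.null(cfg$inputs$loci_fasta))
        loci <- Biostrings::readDNAStringSet(cfg$inputs$loci_fasta)
      if (!is.null(cfg$inputs$windows_fasta))
        windows <- Biostrings::readDNAStringSet(cfg$inputs$windows_fasta)
      if (!is.null(cfg$inputs$emsa_tsv))
        lanes <- read_emsa_tsv(cfg$inputs$emsa_tsv)
    }
    proteins <- NULL
    if ("reconstruct" %in% cfg$stages && !is.null(loci)) {
      stage <- "reconstruct"
      r <- cfg$reconstruct
      proteins <- reconstruct_proteins(loci, motif = r$motif,
                                       max_mismatch = r$max_mismatch,
                                       window_nt = r$window_nt,
                                       min_len_codons = r$min_len_codons)
      write_proteins_fasta(proteins,
                           file.path(cfg$out_dir, "proteins.fa"))
      calls <- do.call(rbind, lapply(names(loci), function(id)
        detect_prf(list(id = id, sequence = as.character(loci[[id]])),
                   motif = r$motif, max_mismatch = r$max_mismatch,
                   window_nt = r$window_nt,
                   min_len_codons = r$min_len_codons)))
      if (is.null(calls)) calls <- empty_call_frame()
      write.table(calls, file.path(cfg$out_dir, "prf_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_prf_gff3(calls, file.path(cfg$out_dir, "prf_sites.gff3"),
                     seqlevels = names(loci))
      counts$reconstruct <- list(proteins = nrow(proteins),
                                 prf_calls = nrow(calls),
                                 prf_fused = sum(proteins$provenance ==
                                                   "PRF_FUSED"))
    }
    if ("curate" %in% cfg$stages && !is.null(proteins)) {
      stage <- "curate"
      cu <- cfg$curate
      cand <- data.frame(id = proteins$id, sequence = proteins$sequence,
                         provenance = proteins$provenance)
      cand <- cand[!is.na(cand$sequence), , drop = FALSE]
      cls <- classify_homologs(cand, motif = cu$motif,
                               max_mismatch = cu$max_mismatch,
                               region_end = cu$region_end)
      res <- curate(cls, max_len = cu$max_len,
                    max_mismatch = cu$max_mismatch, motif = cu$motif)
      tab <- rbind(res$kept, res$removed)
      write.table(tab, file.path(cfg$out_dir, "classification.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(res$report,
                           file.path(cfg$out_dir, "curation_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      counts$curate <- list(input = res$report$input,
                            kept = res$report$surviving)
      proteins <- proteins[proteins$id %in% res$kept$id, , drop = FALSE]
    }
    if ("irscan" %in% cfg$stages && !is.null(windows)) {
      stage <- "irscan"
      ir <- cfg$irscan
      kept_windows <- redundancy_filter(windows,
                                        threshold = ir$redundancy_threshold)
      boxes <- lapply(as.character(kept_windows), function(w) {
        h <- scan_ir(w, hexamer_len = ir$hexamer_len, spacers = ir$spacers,
                     max_mismatch = ir$max_mismatch)
        if (nrow(h) > 0L) h[1L, ] else
          data.frame(hex1_start = NA_integer_, hex2_start = NA_integer_,
                     hexamer_len = ir$hexamer_len, spacer = NA_integer_,
                     mismatches = NA_integer_, total_span = NA_integer_,
                     hex1 = NA_character_, hex2 = NA_character_)
      })
      boxdf <- cbind(window = names(kept_windows), do.call(rbind, boxes))
      write.table(boxdf, file.path(cfg$out_dir, "irboxes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      anchored <- !is.na(boxdf$hex1_start)
      if (sum(anchored) > 0L) {
        prof <- split_profile(as.character(kept_windows)[anchored],
                              boxdf[anchored, , drop = FALSE])
        write_profile_meme(prof, file.path(cfg$out_dir, "profile_pfm.meme"))
        write_profile_tsv(prof, file.path(cfg$out_dir, "profile_info.tsv"))
      }
      counts$irscan <- list(windows_in = length(windows),
                            windows_kept = length(kept_windows),
                            boxes = sum(anchored))
    }
    if ("charge" %in% cfg$stages && !is.null(proteins)) {
      stage <- "charge"
      ch <- cfg$charge
      rule <- charge_rule(count_n_terminus = isTRUE(ch$count_n_terminus),
                          count_c_terminus = isTRUE(ch$count_c_terminus))
      ok <- !is.na(proteins$sequence)
      chg <- data.frame(
        id = proteins$id[ok],
        length = nchar(proteins$sequence[ok]),
        net_charge = vapply(proteins$sequence[ok], net_charge,
                            numeric(1), rule = rule, USE.NAMES = FALSE))
      write.table(chg, file.path(cfg$out_dir, "charge.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      counts$charge <- list(proteins = nrow(chg))
    }
    if ("emsafit" %in% cfg$stages && !is.null(lanes)) {
      stage <- "emsafit"
      ef <- cfg$emsafit
      corrected <- exclude_constant_unbound(lanes,
                                            cv_threshold = ef$cv_threshold)
      fit <- fit_hill(corrected, response = ef$response)
      jsonlite::write_json(
        list(kd_nM = fit$kd, hill = fit$hill, bmax = fit$bmax, rss = fit$rss,
             converged = fit$converged, n_points = fit$n_points,
             excluded_baseline = attr(corrected, "excluded_baseline")),
        file.path(cfg$out_dir, "fit.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      write.table(fit$fitted, file.path(cfg$out_dir, "fitted_curve.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      counts$emsafit <- list(lanes = nrow(lanes),
                             converged = fit$converged)
    }
    TRUE
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  manifest <- list(
    tool = "dufscout",
    version = as.character(utils::packageVersion("dufscout")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    stages = cfg$stages,
    counts = counts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# FASTA with provenance-carrying headers: >id provenance=... junction=...
write_proteins_fasta <- function(proteins, path) {
  ok <- !is.na(proteins$sequence)
  seqs <- Biostrings::AAStringSet(proteins$sequence[ok])
  names(seqs) <- sprintf("%s provenance=%s junction=%s", proteins$id[ok],
                         proteins$provenance[ok],
                         ifelse(is.na(proteins$junction_residue[ok]), ".",
                                proteins$junction_residue[ok]))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

write_prf_gff3 <- function(calls, path, seqlevels = NULL) {
  if (is.null(calls) || nrow(calls) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = calls$locus_id,
    ranges = IRanges::IRanges(calls$motif_start_fwd + 1L,
                              calls$motif_start_fwd + 6L),
    strand = calls$strand)
  S4Vectors::mcols(gr)$type <- "sequence_feature"
  S4Vectors::mcols(gr)$Note <- sprintf("+1 PRF slippery site (%s, %d mm)",
                                       calls$motif_seq,
                                       calls$motif_mismatches)
  if (!is.null(seqlevels))
    GenomeInfoDb::seqlevels(gr) <- unique(c(GenomeInfoDb::seqlevels(gr),
                                            seqlevels))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
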