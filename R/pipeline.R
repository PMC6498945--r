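#' Run the full profiling pipeline
#'
#' Chains the whole analysis: spike-in calibration and absolute copy
#' numbers, P-site offset calibration, raw and dwell-weighted footprint
#' coverage, proteome reconstruction and total ribosome flux, translation
#' and transcription profiles, and part measurements.
#'
#' @param reads_ribo,reads_rna read `data.table`s ([load_reads()] or a
#'   `FluxSim`'s read sets).
#' @param transcripts a `TranscriptSet` with sequences.
#' @param parts part `data.table`.
#' @param spikeins a `SpikeInSet` (unfitted; reads are tallied here).
#' @param cells a `CellParams`.
#' @param codon_times codon dwell-time table.
#' @param offsets optional pre-calibrated `OffsetTable`; calibrated from the
#'   data when `NULL`.
#' @param min_rpf coverage gate for part reporting.
#' @return list with `spikeins`, `copies` (data.table), `offsets`, `N`, `W`,
#'   `proteome`, `q`, `profile` (`TranslationProfile`), `Tprof`
#'   (copy-number based), `Tprof_cov` (coverage based), `parts`
#'   (measurements), `genes`.
#' @export
profile_experiment <- function(reads_ribo, reads_rna, transcripts, parts,
                               spikeins, cells,
                               codon_times = default_codon_times(),
                               offsets = NULL, min_rpf = 5) {
  ref_lens <- reference_lengths(transcripts)
  total_rna <- nrow(reads_rna)
  spikeins <- tally_spikein_reads(spikeins, reads_rna)
  spikeins <- detection_limit(spikeins, total_mapped_reads = total_rna)

  rna_cov <- middle_coverage(reads_rna, ref_lens)
  tx_ids <- names(transcripts)
  rna_counts <- vapply(transcripts, function(m)
    sum(rna_cov[[m$reference]][(m$tss + 1L):m$tes]), numeric(1))
  tx_lens <- vapply(transcripts, tx_length, numeric(1))
  cp <- copies_per_cell(rna_counts, tx_lens, spikeins, cells)
  copies <- data.table(transcript_id = tx_ids, reads = rna_counts,
                       length = tx_lens, copies_per_cell = cp$copies_per_cell,
                       below_limit = cp$below_limit)
  m_x <- setNames(cp$copies_per_cell, tx_ids)
  below <- setNames(as.list(cp$below_limit), tx_ids)

  if (is.null(offsets))
    offsets <- calibrate_offsets(reads_ribo, transcripts)
  N <- p_coverage(reads_ribo, offsets, transcripts, ref_lens)
  W <- weight_coverage(N, codon_times, transcripts)

  f <- m_i <- a_i <- numeric(0)
  gene_tx <- character(0)
  for (m in transcripts) {
    for (j in seq_along(m$cds)) {
      gene <- if (j == 1L) m$id else paste0(m$id, ".cds", j)
      x <- m$cds[[j]]
      w_tx <- tx_coverage(W, m)
      f[gene] <- sum(w_tx[(x[1] + 1L):x[2]])
      aa <- .translate_cds(m, j)
      m_i[gene] <- protein_mass(aa)
      a_i[gene] <- nchar(aa)
      gene_tx[gene] <- m$id
    }
  }
  proteome <- protein_copy_numbers(f, m_i, a_i, cells)
  q <- proteome$q
  genes <- copy(proteome$genes)
  genes[, transcript_id := gene_tx[gene]]
  genes[, copies_per_cell := m_x[transcript_id]]

  profile <- translation_profile(W, q, m_x, transcripts,
                                 below_limit = below)
  Tprof <- transcription_profile(m_x, cells, transcripts, ref_lens)
  Tprof_cov <- transcription_profile_from_coverage(reads_rna, spikeins,
                                                   cells, ref_lens)
  parts_tab <- measure_parts(profile, N, transcripts, parts,
                             Tprof = Tprof_cov, min_rpf = min_rpf)
  list(spikeins = spikeins, copies = copies, offsets = offsets, N = N, W = W,
       proteome = proteome, q = q, profile = profile, Tprof = Tprof,
       Tprof_cov = Tprof_cov, parts = parts_tab, genes = genes)
}

#' @rdname profile_experiment
#' @param sim a `FluxSim` from [simulate_experiment()].
#' @param ... passed on to `profile_experiment()`.
#' @export
profile_simulation <- function(sim, ...) {
  profile_experiment(sim$reads_ribo, sim$reads_rna, sim$transcripts,
                     sim$parts, sim$spikeins, sim$cells,
                     codon_times = sim$config$codon_times, ...)
}

#' Export the main pipeline outputs to a directory
#'
#' Writes bedGraph tracks for the translation and transcription profiles
#' (units in the track description), the part-measurement TSV, offsets,
#' calibration summary and copy table.
#'
#' @param res result list from [profile_experiment()].
#' @param transcripts the `TranscriptSet` used.
#' @param dir output directory.
#' @export
export_results <- function(res, transcripts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  # translation profile back onto reference axes for the track
  ref_lens <- reference_lengths(transcripts)
  rvals <- lapply(names(ref_lens), function(r) numeric(ref_lens[[r]]))
  names(rvals) <- names(ref_lens)
  for (m in transcripts) {
    tr <- res$profile$tracks[[m$id]]
    if (is.null(tr)) next
    rvals[[m$reference]][transcript_positions(m) + 1L] <- tr
  }
  write_bedgraph(rvals, p("translation_profile.bedgraph"),
                 name = "translation_profile", units = "ribosomes/s")
  write_bedgraph(res$Tprof_cov$values, p("transcription_profile.bedgraph"),
                 name = "transcription_profile", units = "RNAP/s")
  fwrite(res$parts, p("parts.tsv"), sep = "\t")
  fwrite(res$offsets, p("offsets.tsv"), sep = "\t")
  fwrite(res$copies, p("copies.tsv"), sep = "\t")
  fwrite(data.table(k = res$spikeins$fit$k,
                    detection_limit_rpkm = res$spikeins$fit$detection_limit,
                    linear_ids = paste(res$spikeins$fit$linear_ids,
                                       collapse = ",")),
         p("calibration.tsv"), sep = "\t")
  fwrite(res$genes, p("genes.tsv"), sep = "\t")
  invisible(dir)
}
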