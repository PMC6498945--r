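#' Protein copy numbers and total ribosome flux
#'
#' Under steady-state exponential growth, every weighted footprint is an
#' actively translating ribosome that completes a full-length protein, so
#' gene-level weighted footprint counts apportion the measured total protein
#' mass: `n_i = f_i * m_t / (f_t * m_i)` with `f_t = sum(f_i)`. This makes
#' the mass closure `sum(n_i * m_i) = m_t` an algebraic identity. Replicating
#' the proteome each division takes `r_t = sum(n_i * a_i)` translocations,
#' giving the total ribosome flux `q = 3 * r_t / t_d` in nt/s (one codon
#' step = 3 nt).
#'
#' @param f named numeric: weighted RPF reads summed over each gene's CDS.
#' @param masses named numeric: protein mass per gene, grams
#'   ([protein_mass()]).
#' @param a named integer: protein length per gene, amino acids.
#' @param cells a `CellParams`.
#' @return a `ProteomeEstimate`: list with `genes` (data.table of `f_i`,
#'   `m_i`, `a_i`, `n_i`), `f_t`, `r_t`, `q`.
#' @export
protein_copy_numbers <- function(f, masses, a, cells) {
  genes <- names(f)
  if (is.null(genes)) stop("f must be a named vector")
  missing_mass <- genes[f > 0 & (is.na(masses[genes]) | is.null(masses[genes]))]
  if (length(missing_mass))
    stop("gene(s) with footprints but no protein sequence/mass: ",
         paste(head(missing_mass, 5), collapse = ", "))
  m_i <- masses[genes]; a_i <- a[genes]
  stopifnot(all(m_i > 0), all(a_i > 0))
  f_t <- sum(f)
  if (f_t <= 0) stop("no weighted footprints (f_t = 0)")
  n_i <- f * cells$m_t / (f_t * m_i)
  r_t <- sum(n_i * a_i)
  structure(list(
    genes = data.table(gene = genes, f_i = as.numeric(f), m_i = as.numeric(m_i),
                       a_i = as.numeric(a_i), n_i = as.numeric(n_i)),
    f_t = f_t, r_t = r_t, m_t = cells$m_t, t_d = cells$t_d,
    q = 3 * r_t / cells$t_d), class = "ProteomeEstimate")
}

#' @rdname protein_copy_numbers
#' @param proteome a `ProteomeEstimate`.
#' @param t_d doubling time override, seconds.
#' @export
total_flux <- function(proteome, t_d = proteome$t_d) {
  stopifnot(t_d > 0)
  3 * proteome$r_t / t_d
}

#' @export
print.ProteomeEstimate <- function(x, ...) {
  cat(sprintf("ProteomeEstimate: %d genes, r_t = %.4g aa, q = %.4g nt/s\n",
              nrow(x$genes), x$r_t, x$q))
  invisible(x)
}

#' Translation profiles R(x) in ribosomes/s
#'
#' `R(x) = q * W(x) / (m_x * f_t)`: the total ribosome flux apportioned to
#' position x by its share of the weighted coverage, normalized per
#' transcript copy. `f_t` here is the weighted total over all assigned
#' positions (not only CDSs), so flux carried by readthrough or recoded
#' ribosomes outside annotated CDSs still counts against the total.
#'
#' @param W weighted `CoverageTrack` from [weight_coverage()].
#' @param q total ribosome flux, nt/s ([total_flux()]).
#' @param m_x named numeric: transcript copies per cell.
#' @param transcripts a `TranscriptSet`.
#' @param f_t weighted total (defaults to the track's own `f_t`).
#' @param below_limit named logical: copies below the spike-in detection
#'   limit; carried through as flags.
#' @return a `TranslationProfile`: per-transcript numeric vectors (transcript
#'   axis, ribosomes/s) plus the inputs used.
#' @export
translation_profile <- function(W, q, m_x, transcripts, f_t = W$f_t,
                                below_limit = NULL) {
  stopifnot(!is.null(f_t), f_t > 0)
  tracks <- list()
  for (m in transcripts) {
    w <- tx_coverage(W, m)
    mx <- m_x[[m$id]]
    if (is.null(mx) || is.na(mx)) mx <- 0
    if (mx <= 0) {
      if (any(w > 0))
        stop("transcript '", m$id, "' has coverage but zero copies; ",
             "R(x) undefined")
      tracks[[m$id]] <- w * 0
    } else {
      tracks[[m$id]] <- q * w / (mx * f_t)
    }
  }
  structure(list(tracks = tracks, q = q, f_t = f_t, m_x = m_x,
                 below_limit = below_limit), class = "TranslationProfile")
}

#' @export
print.TranslationProfile <- function(x, ...) {
  cat(sprintf("TranslationProfile: %d transcripts, q = %.4g nt/s\n",
              length(x$tracks), x$q))
  invisible(x)
}

#' Transcription profiles T(x) in RNAP/s
#'
#' At steady state the synthesis flux of each transcript equals its
#' degradation flux, `copies_i * d_i`, and each synthesized RNA corresponds
#' to one RNAP traversal. T(x) sums this flux over every transcript whose
#' span (TSS to TES, UTRs included) covers x, so overlapping transcription
#' units add.
#'
#' @param copies named numeric: transcript copies per cell.
#' @param cells a `CellParams` (degradation rates).
#' @param transcripts a `TranscriptSet`.
#' @param ref_lengths optional named reference lengths.
#' @return a `TranscriptionProfile`: per-reference numeric vectors, RNAP/s.
#' @export
transcription_profile <- function(copies, cells, transcripts,
                                  ref_lengths = NULL) {
  if (is.null(ref_lengths)) ref_lengths <- reference_lengths(transcripts)
  values <- lapply(names(ref_lengths), function(r) numeric(ref_lengths[[r]]))
  names(values) <- names(ref_lengths)
  for (m in transcripts) {
    cp <- copies[[m$id]]
    if (is.null(cp) || is.na(cp)) cp <- 0
    flux <- cp * degradation_rate(cells, m$id)
    idx <- (m$tss + 1L):m$tes
    values[[m$reference]][idx] <- values[[m$reference]][idx] + flux
  }
  structure(list(values = values, units = "RNAP/s"),
            class = "TranscriptionProfile")
}

#' Per-nucleotide coverage of read middle positions
#'
#' Tallies the middle nucleotide of each read (for even lengths, the
#' nucleotide 5' of the mid-position) per reference position; the positional
#' coverage that underlies RNA-seq based profiles.
#'
#' @param reads read `data.table`.
#' @param ref_lengths named reference lengths ([reference_lengths()]).
#' @return named list of numeric vectors, one per reference.
#' @export
middle_coverage <- function(reads, ref_lengths) {
  values <- lapply(names(ref_lengths), function(r) numeric(ref_lengths[[r]]))
  names(values) <- names(ref_lengths)
  keep <- reads$reference %in% names(ref_lengths)
  if (!any(keep)) return(values)
  mid <- as.integer(fifelse(reads$strand == "+",
                            reads$leftmost + ceiling(reads$length / 2) - 1L,
                            reads$leftmost + floor(reads$length / 2)))[keep]
  by_ref <- split(mid, reads$reference[keep])
  for (r in names(by_ref)) {
    m <- by_ref[[r]]
    m <- m[m >= 0L & m < ref_lengths[[r]]]
    values[[r]] <- values[[r]] + tabulate(m + 1L, nbins = ref_lengths[[r]])
  }
  values
}

#' Transcription profile from spike-in calibrated RNA-seq coverage
#'
#' Converts per-nucleotide RNA-seq coverage directly into RNAP/s without
#' needing per-transcript deconvolution: because fragmentation makes the
#' expected middle-nucleotide count at x equal `k x (molecules covering x)`,
#' the local copy number is `cov(x) / (k * n_cells)` and
#' `T(x) = cov(x) * d / (k * n_cells)`. This is the profile used to read
#' promoter and terminator steps at loci where isoforms overlap.
#'
#' @param rna_reads RNA-seq read `data.table`.
#' @param spikeins fitted `SpikeInSet` (slope `k`).
#' @param cells a `CellParams`.
#' @param ref_lengths named reference lengths.
#' @param d degradation rate applied per nucleotide (default the cell-wide
#'   default rate).
#' @return a `TranscriptionProfile`.
#' @export
transcription_profile_from_coverage <- function(rna_reads, spikeins, cells,
                                                ref_lengths,
                                                d = cells$d_default) {
  if (is.null(spikeins$fit)) stop("SpikeInSet is unfitted")
  cov <- middle_coverage(rna_reads, ref_lengths)
  values <- lapply(cov, function(v) v * d / (spikeins$fit$k * cells$n_cells))
  structure(list(values = values, units = "RNAP/s"),
            class = "TranscriptionProfile")
}

#' Translation efficiency (footprint density per mRNA)
#' @param ribo_rpkm,rna_rpkm RPKM values from Ribo-seq and RNA-seq.
#' @return `ribo_rpkm / rna_rpkm`; `NA` with a warning when `rna_rpkm` is 0.
#' @export
translation_efficiency <- function(ribo_rpkm, rna_rpkm) {
  out <- ribo_rpkm / rna_rpkm
  if (any(rna_rpkm == 0)) {
    warning("translation efficiency undefined where rna_rpkm = 0")
    out[rna_rpkm == 0] <- NA_real_
  }
  out
}

#' Protein synthesis rate per cell
#'
#' Transcript copy number times the RBS-mediated initiation rate per
#' transcript: molecules of protein made per second per cell.
#' @param copies transcripts per cell.
#' @param init_rate initiation rate, ribosomes/s per transcript.
#' @export
protein_synthesis_rate <- function(copies, init_rate) {
  stopifnot(all(copies >= 0), all(init_rate >= 0))
  copies * init_rate
}

#' Export per-reference values as bedGraph
#'
#' @param values named list of per-reference numeric vectors (0-based dense).
#' @param path output path.
#' @param name track name.
#' @param units free-text units, stored in the track description.
#' @export
write_bedgraph <- function(values, path, name = "track", units = "") {
  rl <- methods::as(lapply(values, S4Vectors::Rle), "SimpleRleList")
  gr <- methods::as(rl, "GRanges")
  names(S4Vectors::mcols(gr)) <- "score"
  line <- methods::new("GraphTrackLine", name = name, description = units,
                       type = "bedGraph")
  rtracklayer::export(gr, path, format = "bedGraph", trackLine = line)
  invisible(path)
}
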