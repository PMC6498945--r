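#' Codon occupancy (ribosome pausing) analysis
#'
#' Within each gene, per-codon footprint counts are normalized to the gene's
#' own mean so that expression level cancels; the normalized values are then
#' pooled across the transcriptome by P-site codon identity and averaged.
#' Elevated occupancy marks slowly translated (paused) codons. Raw counts
#' N(x) are used, not dwell-weighted coverage, because dwell weighting would
#' cancel exactly the signal being measured. The first and last `trim`
#' codons of each CDS are excluded to keep initiation/termination ramps out
#' of the pool.
#'
#' Genes are pooled only when their mean footprint density reaches
#' `min_density` reads per codon: in a sparsely covered gene the
#' gene-normalized values are dominated by shot noise (single reads become
#' huge normalized spikes), which would drown the codon signal.
#'
#' @param N raw `CoverageTrack` from [p_coverage()].
#' @param transcripts a `TranscriptSet` with sequences.
#' @param trim codons removed from each CDS end (default 5).
#' @param min_density minimum mean footprints per codon for a gene to enter
#'   the pool (default 1; genes with zero footprints are always skipped).
#' @return `data.table` (`codon`, `occupancy`, `n_instances`); mean occupancy
#'   over observed codons is ~1 by construction.
#' @export
codon_occupancy <- function(N, transcripts, trim = 5L, min_density = 1) {
  pool <- list()
  for (m in transcripts) {
    if (!length(m$cds) || is.null(m$sequence)) next
    x <- m$cds[[1]]
    n_cod <- (x[2] - x[1]) %/% 3L
    if (n_cod - 1L - trim < trim + 1L) next
    use <- (trim + 1L):(n_cod - 1L - trim)   # also drops the stop codon
    N_tx <- tx_coverage(N, m)
    starts <- x[1] + 3L * (use - 1L)
    counts <- N_tx[starts + 1L] + N_tx[starts + 2L] + N_tx[starts + 3L]
    if (sum(counts) == 0) next               # genes with no footprints skipped
    if (mean(counts) < min_density) next
    cods <- substring(m$sequence, starts + 1L, starts + 3L)
    pool[[m$id]] <- data.table(codon = cods, value = counts / mean(counts))
  }
  if (!length(pool)) stop("no gene with footprints")
  rbindlist(pool)[, .(occupancy = mean(value), n_instances = .N), by = codon][
    order(codon)]
}

#' Occupancy change between two conditions
#'
#' @param occ_a,occ_b occupancy tables from [codon_occupancy()] for the two
#'   conditions (a = reference, b = perturbed).
#' @return `data.table` with `ratio` (`b / a`) and `log2_ratio` per codon.
#' @export
occupancy_change <- function(occ_a, occ_b) {
  m <- merge(occ_a[, .(codon, occ_a = occupancy)],
             occ_b[, .(codon, occ_b = occupancy)], by = "codon")
  m[, ratio := occ_b / occ_a]
  m[, log2_ratio := log2(ratio)]
  m[]
}

#' Tukey outlier call on per-codon occupancy changes
#'
#' Flags codons whose change statistic lies more than 1.5 interquartile
#' ranges below the first quartile or above the third quartile. When the IQR
#' degenerates to 0, only values strictly outside the collapsed fences are
#' flagged.
#'
#' @param change numeric vector of per-codon change statistics (one per
#'   codon; non-finite entries are ignored but at least 4 finite values are
#'   required).
#' @return logical vector parallel to `change` (`NA` where non-finite).
#' @export
occupancy_outliers <- function(change) {
  ok <- is.finite(change)
  if (sum(ok) < 4L) stop("need at least 4 finite change values")
  q <- quantile(change[ok], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  out <- rep(NA, length(change))
  out[ok] <- change[ok] < q[1] - 1.5 * iqr | change[ok] > q[2] + 1.5 * iqr
  out
}

#' Metagene profile around start or stop codons
#'
#' Mean-normalized footprint coverage aligned at a common anchor and
#' averaged over qualifying genes. Genes need at least `min_rpf` footprints
#' inside the window; genes overlapping another transcript on the same
#' reference are excluded, as are genes whose window would leave the
#' transcript.
#'
#' @param N raw `CoverageTrack`.
#' @param transcripts a `TranscriptSet`.
#' @param anchor `"start"` (first nt of the start codon) or `"stop"` (first
#'   nt of the stop codon).
#' @param window `c(before, after)` nt relative to the anchor.
#' @param min_rpf minimum footprints in the window (default 5).
#' @return `data.table` (`offset`, `mean_cov`, `n_genes`).
#' @export
metagene <- function(N, transcripts, anchor = c("start", "stop"),
                     window = c(-30L, 60L), min_rpf = 5L) {
  anchor <- match.arg(anchor)
  spans <- rbindlist(lapply(transcripts, function(m)
    data.table(id = m$id, reference = m$reference, tss = m$tss, tes = m$tes)))
  gr <- GenomicRanges::GRanges(spans$reference,
                               IRanges::IRanges(spans$tss + 1L, spans$tes))
  n_ovl <- GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE)
  overlapping <- spans$id[n_ovl > 1L]
  rows <- list()
  for (m in transcripts) {
    if (!length(m$cds) || m$id %in% overlapping) next
    a <- if (anchor == "start") m$cds[[1]][1] else m$stop_codon[1]
    lo <- a + window[1]; hi <- a + window[2]
    if (lo < 0L || hi > m$length) next
    cov <- tx_coverage(N, m)[(lo + 1L):hi]
    if (sum(cov) < min_rpf) next
    rows[[m$id]] <- data.table(offset = window[1]:(window[2] - 1L),
                               value = cov / mean(cov))
  }
  if (!length(rows)) stop("no qualifying gene for metagene")
  rbindlist(rows)[, .(mean_cov = mean(value), n_genes = .N), by = offset][
    order(offset)]
}
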