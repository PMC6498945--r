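#' Codon translation-time tables
#'
#' Relative dwell times per codon (dimensionless, mean 1 over sense codons by
#' convention). The default table is uniform: shipping measured dwell times
#' would bake an external data set into every result, so the table is an
#' explicit input (`--codon-times`).
#'
#' @return named numeric of length 64.
#' @export
default_codon_times <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setNames(rep(1, 64), sort(codons))
}

#' @rdname default_codon_times
#' @param path TSV with columns `codon`, `time`.
#' @param normalize rescale so sense codons have mean time 1.
#' @export
load_codon_times <- function(path, normalize = TRUE) {
  dt <- fread(path)
  stopifnot(all(c("codon", "time") %in% names(dt)), all(dt$time > 0))
  times <- default_codon_times()
  times[dt$codon] <- dt$time
  if (normalize) {
    sense <- setdiff(names(times), c("TAA", "TAG", "TGA"))
    times <- times / mean(times[sense])
  }
  times
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Calibrate read-length specific P-site offsets against stop codons
#'
#' Footprints are binned by read length and aligned at annotated stop codons:
#' for each length the histogram of displacements between read 3' ends and
#' the middle nucleotide of the last sense codon (the P-site codon of a
#' terminating ribosome) is built over all transcripts, and the modal
#' displacement is the offset. The 3' end anchors the geometry because the
#' distance from the P site to the point the transcript leaves the ribosome
#' is 3'-defined. Ties in the modal peak break toward the smaller offset (a
#' message records the tie).
#'
#' @param ribo_reads Ribo-seq read `data.table`.
#' @param transcripts a `TranscriptSet` (stop codons from each first CDS).
#' @param lengths read lengths retained (default 23:28 nt).
#' @param min_support minimum reads per length class contributing to the
#'   metagene (default 200); weaker classes are excluded with a warning.
#' @param max_lag largest displacement considered (nt).
#' @return `data.table` (`length`, `offset`, `support`), class `OffsetTable`.
#' @export
calibrate_offsets <- function(ribo_reads, transcripts, lengths = 23:28,
                              min_support = 200L, max_lag = 45L) {
  stops <- rbindlist(lapply(transcripts, function(m) {
    if (!length(m$cds)) return(NULL)
    data.table(reference = m$reference,
               center_ref = tx_to_ref(m, m$stop_codon[1] - 2L),
               tx_strand = m$strand)
  }))
  if (is.null(stops) || nrow(stops) == 0L) stop("no annotated stop codons")
  keep <- ribo_reads$length %in% lengths
  rd <- data.table(
    reference = ribo_reads$reference[keep],
    length = ribo_reads$length[keep],
    p3 = fifelse(ribo_reads$strand[keep] == "+",
                 ribo_reads$leftmost[keep] + ribo_reads$length[keep] - 1L,
                 ribo_reads$leftmost[keep]))
  hits <- rd[stops, on = "reference", allow.cartesian = TRUE, nomatch = NULL]
  hits[, d := fifelse(tx_strand == "+", p3 - center_ref, center_ref - p3)]
  hits <- hits[d >= 0L & d <= max_lag]
  tab <- hits[, .N, by = .(length, d)]
  out <- tab[, {
    support <- sum(N)
    mx <- max(N)
    modal <- sort(d[N == mx])
    if (length(modal) > 1L)
      message("[calibrate_offsets] tie at length ", length[1],
              "; choosing smaller offset ", modal[1])
    .(offset = modal[1], support = support)
  }, by = length]
  weak <- out[support < min_support, length]
  if (length(weak))
    warning("length class(es) below support minimum excluded: ",
            paste(weak, collapse = ", "))
  out <- out[support >= min_support]
  if (nrow(out) == 0L) stop("no read length retained for offset calibration")
  setorder(out, length)
  structure(out[], class = c("OffsetTable", class(out)))
}

#' Reference sequence lengths implied by a transcript set
#' @param transcripts a `TranscriptSet`.
#' @export
reference_lengths <- function(transcripts) {
  dt <- rbindlist(lapply(transcripts, function(m)
    data.table(reference = m$reference, tes = m$tes)))
  v <- dt[, max(tes), by = reference]
  setNames(v$V1, v$reference)
}

#' Frame-aware raw P-site coverage N(x)
#'
#' Each retained footprint contributes +1 at exactly one nucleotide: the
#' middle nucleotide of its P-site codon, found by walking the calibrated
#' offset back from the read's 3' end. Reads with an uncalibrated length, or
#' shorter than their offset, are dropped with a tally; P sites outside every
#' annotated transcript span are counted in an unassigned bin.
#'
#' @param ribo_reads Ribo-seq read `data.table`.
#' @param offsets an `OffsetTable` from [calibrate_offsets()].
#' @param transcripts a `TranscriptSet`.
#' @param ref_lengths optional named reference lengths (nt).
#' @return a `CoverageTrack`: list with `values` (one numeric vector per
#'   reference), `assay`, `weighted`, `n_assigned`, `n_unassigned`,
#'   `n_dropped_length`.
#' @export
p_coverage <- function(ribo_reads, offsets, transcripts, ref_lengths = NULL) {
  if (is.null(ref_lengths)) ref_lengths <- reference_lengths(transcripts)
  off <- setNames(offsets$offset, as.character(offsets$length))
  o <- off[as.character(ribo_reads$length)]
  keep <- !is.na(o) & o < ribo_reads$length
  n_dropped <- sum(!keep)
  p3 <- fifelse(ribo_reads$strand == "+",
                ribo_reads$leftmost + ribo_reads$length - 1L,
                ribo_reads$leftmost)
  center <- as.integer(fifelse(ribo_reads$strand == "+", p3 - o, p3 + o))[keep]
  refs <- ribo_reads$reference[keep]
  spans <- rbindlist(lapply(transcripts, function(m)
    data.table(reference = m$reference, tss = m$tss, tes = m$tes)))
  values <- lapply(names(ref_lengths), function(r) numeric(ref_lengths[[r]]))
  names(values) <- names(ref_lengths)
  n_assigned <- 0L
  n_seen <- length(center)
  by_ref <- split(center, refs)
  for (r in names(by_ref)) {
    if (!r %in% names(values)) next
    centers <- by_ref[[r]]
    inside <- centers >= 0L & centers < ref_lengths[[r]]
    sp <- spans[reference == r]
    if (nrow(sp)) {
      ir <- IRanges::reduce(IRanges::IRanges(start = sp$tss + 1L, end = sp$tes))
      assigned <- inside &
        IRanges::overlapsAny(IRanges::IRanges(centers + 1L, width = 1L), ir)
    } else assigned <- rep(FALSE, length(centers))
    values[[r]] <- values[[r]] +
      tabulate(centers[assigned] + 1L, nbins = ref_lengths[[r]])
    n_assigned <- n_assigned + sum(assigned)
  }
  structure(list(values = values, assay = "riboseq", weighted = FALSE,
                 n_assigned = n_assigned,
                 n_unassigned = n_seen - n_assigned,
                 n_dropped_length = n_dropped),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack (%s%s): %d reference(s), total %.6g%s\n",
              x$assay, if (x$weighted) ", weighted" else "",
              length(x$values), sum(vapply(x$values, sum, numeric(1))),
              if (!is.null(x$f_t)) sprintf(", f_t = %.6g", x$f_t) else ""))
  invisible(x)
}

#' Extract a track over one transcript's 5'-to-3' axis
#' @param track a `CoverageTrack`.
#' @param model a `TranscriptModel`.
#' @return numeric vector of length `tx_length(model)`.
#' @export
tx_coverage <- function(track, model) {
  v <- track$values[[model$reference]]
  if (is.null(v)) stop("reference '", model$reference, "' not in track")
  v[transcript_positions(model) + 1L]
}

#' Codon-time weighted coverage W(x)
#'
#' Divides N(x) by the relative translation time of the codon at x so that
#' the weighted coverage tracks ribosome flux rather than dwell. Positions
#' outside any CDS carry weight 1; codons containing an ambiguous base get
#' weight 1 with a warning. The weighted total `f_t = sum(W)` is stored on
#' the returned track.
#'
#' @param N a raw `CoverageTrack` from [p_coverage()].
#' @param times named codon-time vector (see [default_codon_times()]).
#' @param transcripts a `TranscriptSet` with sequences.
#' @return a weighted `CoverageTrack` with element `f_t`.
#' @export
weight_coverage <- function(N, times, transcripts) {
  wts <- lapply(N$values, function(v) rep(1, length(v)))
  warned <- FALSE
  for (m in transcripts) {
    if (is.null(wts[[m$reference]])) next
    for (x in m$cds) {
      n_cod <- (x[2] - x[1]) %/% 3L
      cods <- if (!is.null(m$sequence))
        substring(m$sequence, x[1] + 3L * (0:(n_cod - 1L)) + 1L,
                  x[1] + 3L * (0:(n_cod - 1L)) + 3L)
      else rep(NA_character_, n_cod)
      t_c <- times[cods]
      if (anyNA(t_c)) {
        if (!warned && !is.null(m$sequence)) {
          warning("codon(s) with ambiguous bases weighted by 1")
          warned <- TRUE
        }
        t_c[is.na(t_c)] <- 1
      }
      tx_pos <- x[1]:(x[2] - 1L)
      ref_pos <- tx_to_ref(m, tx_pos)
      wts[[m$reference]][ref_pos + 1L] <- rep(t_c, each = 3L)
    }
  }
  W <- N
  W$values <- Map(function(v, w) v / w, N$values, wts[names(N$values)])
  W$weighted <- TRUE
  W$f_t <- sum(vapply(W$values, sum, numeric(1)))
  W
}

#' RPKM and RPM by the middle-nucleotide rule
#'
#' A read is counted for a feature when its middle nucleotide (for
#' even-length reads, the nucleotide 5' of the mid-position) falls in the
#' coding sequence.
#'
#' @param reads read `data.table`.
#' @param model a `TranscriptModel` with at least one CDS.
#' @param total_mapped total mapped reads in the library.
#' @param cds_index which CDS to count into (default first).
#' @return list with `count`, `rpkm`, `rpm`.
#' @export
rpkm_rpm <- function(reads, model, total_mapped, cds_index = 1L) {
  if (!length(model$cds)) stop("transcript has no CDS")
  if (total_mapped <= 0) stop("zero total mapped reads")
  cds <- model$cds[[cds_index]]
  cds_len <- cds[2] - cds[1]
  rd <- reads[reference == model$reference]
  if (nrow(rd) == 0L)
    return(list(count = 0L, rpkm = 0, rpm = 0))
  mid_ref <- ifelse(rd$strand == "+",
                    rd$leftmost + ceiling(rd$length / 2) - 1L,
                    rd$leftmost + floor(rd$length / 2))
  mid_tx <- ref_to_tx(model, mid_ref)
  count <- sum(mid_tx >= cds[1] & mid_tx < cds[2] &
                 (rd$strand == model$strand))
  list(count = count,
       rpkm = count / (cds_len / 1e3) / (total_mapped / 1e6),
       rpm = count / (total_mapped / 1e6))
}
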