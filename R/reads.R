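#' Load mapped read positions
#'
#' Ingests alignments either from SAM/BAM or from the package's plain-text
#' position-table dialect: a TSV with header
#' `reference`, `leftmost`, `length`, `strand` (and an optional
#' `mapq_unique` logical column). `leftmost` is the 0-based leftmost aligned
#' reference position. SAM/BAM `POS` (1-based) is converted on load.
#'
#' Unmapped records and records that are not uniquely mapped (secondary or
#' supplementary alignments, or `MAPQ < min_mapq`) are dropped; the numbers
#' kept and dropped are reported via `message()` and attached as attributes
#' `n_dropped_multi` / `n_dropped_unmapped` / `n_dropped_unknown_ref`.
#'
#' @param path SAM (`.sam`), BAM (`.bam`) or position-table path.
#' @param assay `"riboseq"` or `"rnaseq"`.
#' @param transcripts optional `TranscriptSet`; reads on references not used
#'   by any transcript are dropped with a warning.
#' @param min_mapq minimum mapping quality considered unique (default 10).
#' @return `data.table` with columns `reference`, `leftmost`, `length`,
#'   `strand`, `assay`, `mapq_unique`, containing only usable records.
#' @export
load_reads <- function(path, assay = c("riboseq", "rnaseq"),
                       transcripts = NULL, min_mapq = 10L) {
  assay <- match.arg(assay)
  ext <- tolower(tools::file_ext(path))
  n_unmapped <- 0L
  if (ext %in% c("sam", "bam")) {
    bam <- path
    if (ext == "sam") bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
    p <- Rsamtools::ScanBamParam(
      what = c("rname", "pos", "strand", "qwidth", "mapq", "flag"))
    b <- Rsamtools::scanBam(bam, param = p)[[1]]
    flag <- b$flag
    mapped <- !bitwAnd(flag, 4L)
    n_unmapped <- sum(!mapped)
    dt <- data.table(
      reference = as.character(b$rname)[mapped],
      leftmost = b$pos[mapped] - 1L,
      length = b$qwidth[mapped],
      strand = as.character(b$strand)[mapped],
      mapq_unique = (b$mapq[mapped] >= min_mapq) &
        !bitwAnd(flag[mapped], 256L) & !bitwAnd(flag[mapped], 2048L))
  } else {
    dt <- if (file.size(path) > 0) fread(path) else data.table()
    need <- c("reference", "leftmost", "length", "strand")
    if (nrow(dt) == 0L) {
      warning("empty read file: ", path)
      dt <- data.table(reference = character(), leftmost = integer(),
                       length = integer(), strand = character(),
                       mapq_unique = logical())
    }
    if (!all(need %in% names(dt)))
      stop("position table must have columns: ", paste(need, collapse = ", "))
    if (!"mapq_unique" %in% names(dt)) dt[, mapq_unique := TRUE]
  }
  stopifnot(all(dt$length > 0L | nrow(dt) == 0L))
  n_multi <- sum(!dt$mapq_unique)
  dt <- dt[mapq_unique == TRUE]
  n_unknown <- 0L
  if (!is.null(transcripts) && nrow(dt)) {
    refs <- unique(vapply(transcripts, `[[`, character(1), "reference"))
    n_unknown <- sum(!dt$reference %in% refs)
    if (n_unknown > 0L)
      warning(n_unknown, " read(s) on references absent from the annotation dropped")
    dt <- dt[reference %in% refs]
  }
  dt[, assay := assay]
  setattr(dt, "n_dropped_multi", n_multi)
  setattr(dt, "n_dropped_unmapped", n_unmapped)
  setattr(dt, "n_dropped_unknown_ref", n_unknown)
  message(sprintf("[load_reads] %s: kept %d, dropped %d multi-mapped, %d unmapped, %d unknown-ref",
                  assay, nrow(dt), n_multi, n_unmapped, n_unknown))
  dt[]
}

#' Write reads in the position-table dialect
#' @param reads read `data.table`.
#' @param path output TSV path.
#' @export
write_position_table <- function(reads, path) {
  fwrite(reads[, .(reference, leftmost, length, strand)], path, sep = "\t")
  invisible(path)
}

#' Drop reads overlapping masked intervals
#'
#' Reads whose aligned span overlaps any interval in a BED mask (for example
#' genome regions homologous to plasmid-borne copies) are removed.
#'
#' @param reads read `data.table` from [load_reads()].
#' @param mask BED file path or a `GRanges` of masked intervals.
#' @return filtered `data.table` (attribute `n_masked` gives the count removed).
#' @export
apply_mask <- function(reads, mask) {
  if (is.character(mask)) mask <- rtracklayer::import(mask, format = "bed")
  if (nrow(reads) == 0L) return(reads)
  gr <- GenomicRanges::GRanges(
    reads$reference,
    IRanges::IRanges(start = reads$leftmost + 1L, width = reads$length))
  hit <- IRanges::overlapsAny(gr, mask, ignore.strand = TRUE)
  out <- reads[!hit]
  setattr(out, "n_masked", sum(hit))
  out
}

#' Merge replicate read sets
#'
#' Biological replicates are pooled into one metagene read set before any
#' profiling; all downstream estimates operate on the merged set.
#' @param ... read `data.table`s with identical columns and assay labels.
#' @export
merge_replicates <- function(...) {
  sets <- list(...)
  stopifnot(length(unique(vapply(sets, function(x) x$assay[1], character(1)))) <= 1L)
  rbindlist(sets)
}
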