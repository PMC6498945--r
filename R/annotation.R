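#' Transcript models and part annotations
#'
#' A `TranscriptModel` describes one transcription unit: its span on a
#' reference sequence, its coding region(s), and the positions of the genetic
#' parts attached to it (ribosome binding site, stop codon, frameshift
#' regions). All internal coordinates are 0-based, half-open. The transcript
#' span is stored as reference coordinates (`tss`, `tes`, with `tss < tes`
#' regardless of strand), while every feature coordinate is stored on the
#' transcript's own 5'-to-3' axis so that downstream window arithmetic is
#' strand-free.
#'
#' @param id transcript identifier.
#' @param reference name of the reference sequence the transcript lies on.
#' @param strand `"+"` or `"-"`.
#' @param tss,tes reference-axis span of the transcript (0-based half-open;
#'   `tss < tes`). For minus-strand transcripts the biological start site is
#'   at reference position `tes - 1`.
#' @param cds list of integer pairs `c(start, end)` on the transcript axis
#'   (0-based half-open), 5' to 3'. The final 3 nt of each CDS are its stop
#'   codon.
#' @param rbs_start transcript-axis position `x0` where the ribosome binding
#'   site begins (`NA` if not annotated).
#' @param sequence transcript nucleotide sequence (5' to 3'), or `NULL`.
#' @return an object of class `TranscriptModel`.
#' @export
transcript_model <- function(id, reference, strand = "+", tss, tes,
                             cds = list(), rbs_start = NA_integer_,
                             sequence = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            strand %in% c("+", "-"),
            tss >= 0, tes > tss)
  len <- as.integer(tes - tss)
  cds <- lapply(cds, function(x) as.integer(x[1:2]))
  for (x in cds) {
    if (!(x[1] >= 0 && x[1] < x[2] && x[2] <= len))
      stop("CDS [", x[1], ",", x[2], ") outside transcript '", id, "' of length ", len)
    if ((x[2] - x[1]) %% 3L != 0L)
      stop("CDS length not a multiple of 3 in transcript '", id, "'")
  }
  if (!is.null(sequence)) {
    sequence <- as.character(sequence)
    if (nchar(sequence) != len)
      stop("sequence length (", nchar(sequence), ") != transcript length (",
           len, ") for '", id, "'")
  }
  structure(list(
    id = id, reference = reference, strand = strand,
    tss = as.integer(tss), tes = as.integer(tes), length = len,
    cds = cds, rbs_start = as.integer(rbs_start),
    stop_codon = if (length(cds)) c(cds[[1]][2] - 3L, cds[[1]][2]) else NULL,
    sequence = sequence
  ), class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s [%s:%d-%d %s], %d nt, %d CDS\n",
              x$id, x$reference, x$tss, x$tes, x$strand, x$length,
              length(x$cds)))
  invisible(x)
}

#' @rdname transcript_model
#' @param models list of `TranscriptModel` objects.
#' @export
transcript_set <- function(models) {
  stopifnot(all(vapply(models, inherits, logical(1), "TranscriptModel")))
  names(models) <- vapply(models, `[[`, character(1), "id")
  if (anyDuplicated(names(models)))
    stop("duplicate transcript ids")
  structure(models, class = "TranscriptSet")
}

#' @export
print.TranscriptSet <- function(x, ...) {
  cat(sprintf("TranscriptSet of %d transcripts on %d reference(s)\n",
              length(x), length(unique(vapply(x, `[[`, character(1), "reference")))))
  invisible(x)
}

#' Transcript-axis length
#' @param model a `TranscriptModel`.
#' @export
tx_length <- function(model) model$length

#' Map between reference and transcript coordinates
#'
#' `tx_to_ref()` converts a 0-based transcript-axis position to the 0-based
#' reference position of the same nucleotide; `ref_to_tx()` is the inverse.
#' `transcript_positions()` lists the reference positions of all transcript
#' nucleotides in 5'-to-3' order.
#'
#' @param model a `TranscriptModel`.
#' @param pos integer vector of positions.
#' @export
tx_to_ref <- function(model, pos) {
  if (model$strand == "+") model$tss + pos else model$tes - 1L - pos
}

#' @rdname tx_to_ref
#' @export
ref_to_tx <- function(model, pos) {
  if (model$strand == "+") pos - model$tss else model$tes - 1L - pos
}

#' @rdname tx_to_ref
#' @export
transcript_positions <- function(model) tx_to_ref(model, 0:(model$length - 1L))

#' Reading-frame label of a transcript position
#'
#' Frames are defined relative to the middle nucleotide of a CDS's start
#' codon (the P-site center of an initiating ribosome). A P-site center at
#' `pos` is in frame 0 when `(pos - (x_s + 1)) %% 3 == 0`, in frame +1 when
#' the remainder is 1, and in frame -1 when it is 2.
#'
#' @param model a `TranscriptModel`.
#' @param pos transcript-axis position(s).
#' @param cds_index which CDS anchors the frame (default first).
#' @return integer vector with values 0, 1 (frame +1) or 2 (frame -1).
#' @export
frame_offset <- function(model, pos, cds_index = 1L) {
  anchor <- model$cds[[cds_index]][1] + 1L
  (pos - anchor) %% 3L
}

# ---- loading ---------------------------------------------------------------

#' Load transcript annotation plus a part sidecar
#'
#' Reads a GFF3 or BED12 annotation and an optional tab-separated part
#' sidecar with columns `kind`, `transcript_id`, `start`, `end`
#' (transcript-axis, 0-based half-open). GFF3 1-based closed coordinates are
#' converted on load and minus-strand features are flipped onto the
#' transcript's 5'-to-3' axis. Recognized part kinds: `rbs`, `stop`,
#' `promoter`, `terminator`, `frameshift_site` (frameshift rows use
#' `start`/`end` for the middle region `[x_s, x_0)` and two extra columns
#' `start2`/`end2` for the downstream region `[x_1, x_e)`).
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED12 (`.bed`) file.
#' @param parts_path optional part sidecar TSV.
#' @param fasta optional FASTA of the reference sequences; when given,
#'   transcript sequences are extracted (reverse-complemented on minus
#'   strand).
#' @return list with `transcripts` (a `TranscriptSet`) and `parts`
#'   (a `data.table`).
#' @export
load_annotation <- function(path, parts_path = NULL, fasta = NULL) {
  ext <- tolower(tools::file_ext(path))
  refseq <- NULL
  if (!is.null(fasta)) refseq <- Biostrings::readDNAStringSet(fasta)
  models <- if (ext %in% c("gff", "gff3")) {
    .models_from_gff(path)
  } else if (ext == "bed") {
    .models_from_bed12(path)
  } else stop("unsupported annotation format: ", ext)
  if (!is.null(refseq)) {
    models <- lapply(models, function(m) {
      if (!m$reference %in% names(refseq)) return(m)
      s <- Biostrings::subseq(refseq[[m$reference]], m$tss + 1L, m$tes)
      if (m$strand == "-") s <- Biostrings::reverseComplement(s)
      m$sequence <- as.character(s)
      m
    })
  }
  ts <- transcript_set(models)
  parts <- .load_parts(parts_path, ts)
  list(transcripts = ts, parts = parts)
}

.models_from_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(gr)
  is_tx <- meta$type %in% c("mRNA", "transcript")
  if (!any(is_tx)) stop("no mRNA/transcript records in ", path)
  txs <- meta[is_tx, , drop = FALSE]
  if (any(is.na(txs$ID))) stop("transcript record without ID in ", path)
  lapply(seq_len(nrow(txs)), function(i) {
    row <- txs[i, ]
    tss <- row$start - 1L; tes <- row$end
    kids <- meta[meta$type == "CDS" &
                 vapply(meta$Parent, function(p) row$ID %in% p, logical(1)), ,
                 drop = FALSE]
    strand <- as.character(row$strand)
    if (!strand %in% c("+", "-")) strand <- "+"
    cds <- lapply(seq_len(nrow(kids)), function(j) {
      s0 <- kids$start[j] - 1L; e0 <- kids$end[j]
      if (strand == "+") c(s0 - tss, e0 - tss) else c(tes - e0, tes - s0)
    })
    cds <- cds[order(vapply(cds, `[`, numeric(1), 1))]
    transcript_model(row$ID, as.character(row$seqnames), strand, tss, tes, cds)
  })
}

.models_from_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    tss <- row$start - 1L; tes <- row$end
    strand <- as.character(row$strand)
    if (!strand %in% c("+", "-")) strand <- "+"
    cds <- list()
    if (!is.null(row$thick.start) && !is.na(row$thick.start) &&
        row$thick.end >= row$thick.start) {
      s0 <- row$thick.start - 1L; e0 <- row$thick.end
      if (e0 > s0)
        cds <- list(if (strand == "+") c(s0 - tss, e0 - tss)
                    else c(tes - e0, tes - s0))
    }
    transcript_model(as.character(row$name), as.character(row$seqnames),
                     strand, tss, tes, cds)
  })
}

.load_parts <- function(parts_path, ts) {
  empty <- data.table(kind = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      start2 = integer(), end2 = integer())
  if (is.null(parts_path)) {
    warning("no part sidecar supplied; transcripts carry empty part lists")
    return(empty)
  }
  parts <- fread(parts_path)
  need <- c("kind", "transcript_id", "start", "end")
  if (!all(need %in% names(parts)))
    stop("part sidecar must have columns: ", paste(need, collapse = ", "))
  if (!"start2" %in% names(parts)) parts[, `:=`(start2 = NA_integer_, end2 = NA_integer_)]
  bad <- setdiff(parts$transcript_id, names(ts))
  if (length(bad))
    stop("part annotation references unknown transcript(s): ",
         paste(bad, collapse = ", "))
  for (i in seq_len(nrow(parts))) {
    m <- ts[[parts$transcript_id[i]]]
    if (parts$start[i] < 0 || parts$end[i] > m$length)
      stop("part row ", i, " outside transcript '", m$id, "'")
  }
  no_part <- setdiff(names(ts), parts$transcript_id)
  if (length(no_part))
    warning(length(no_part), " transcript(s) without part annotation: ",
            paste(head(no_part, 5), collapse = ", "))
  parts[]
}

#' Attach RBS annotations from a part table to the transcript models
#'
#' Sets `rbs_start` (`x0`) on each transcript that has an `rbs` part row.
#' @param ts a `TranscriptSet`.
#' @param parts part `data.table` from [load_annotation()].
#' @export
apply_rbs_parts <- function(ts, parts) {
  rbs <- parts[kind == "rbs"]
  for (i in seq_len(nrow(rbs))) {
    ts[[rbs$transcript_id[i]]]$rbs_start <- as.integer(rbs$start[i])
  }
  ts
}

#' Write a transcript set back to GFF3
#'
#' Emits one `mRNA` record per transcript plus its `CDS` children, converting
#' internal 0-based half-open coordinates back to 1-based closed GFF3.
#' Reading the file with [load_annotation()] reproduces the coordinates
#' exactly (sequences are not round-tripped).
#'
#' @param ts a `TranscriptSet`.
#' @param path output path.
#' @export
write_annotation <- function(ts, path) {
  rows <- list()
  for (m in ts) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = m$reference, start = m$tss + 1L, end = m$tes,
      strand = m$strand, type = "mRNA", ID = m$id, Parent = NA_character_)
    for (x in m$cds) {
      rs <- sort(tx_to_ref(m, c(x[1], x[2] - 1L)))
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = m$reference, start = rs[1] + 1L, end = rs[2] + 1L,
        strand = m$strand, type = "CDS", ID = NA_character_, Parent = m$id)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$seqnames, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, ID = df$ID,
    phase = ifelse(df$type == "CDS", 0L, NA_integer_),
    Parent = IRanges::CharacterList(lapply(df$Parent, function(p)
      if (is.na(p)) character() else p)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
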