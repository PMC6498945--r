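#' Genetic-part quantification from local profile changes
#'
#' A part is quantified by comparing window means of the per-nucleotide
#' translation (or transcription) profile on either side of it. All windows
#' are 0-based half-open intervals on the transcript axis and are reported
#' verbatim in every measurement for audit; efficiencies falling outside
#' [0, 1] are reported raw with a qc flag, never clamped.
#'
#' @name parts
NULL

.win_mean <- function(v, w) {
  if (is.null(w) || w[2] <= w[1]) return(NA_real_)
  mean(v[(w[1] + 1L):w[2]])
}

.win_sum <- function(v, w) {
  if (is.null(w) || w[2] <= w[1]) return(0)
  sum(v[(w[1] + 1L):w[2]])
}

.fmt_win <- function(w) {
  if (is.null(w)) "NA" else sprintf("[%d,%d)", w[1], w[2])
}

#' Averaging windows for an RBS
#'
#' The upstream window is `[x0 - n, x0)`, clipped at the transcript start
#' site and, inside operons, at 9 nt (3 codons) downstream of an upstream
#' CDS's stop codon falling in the window. The CDS window starts 51 nt (17
#' codons) into the coding region to avoid the 5' footprint ramp and ends
#' before the stop codon, which carries no elongating P sites:
#' `[x_s + 51, x_e - 3)`.
#'
#' @param model a `TranscriptModel`.
#' @param x0 RBS start position (transcript axis); defaults to the model's
#'   annotated `rbs_start`.
#' @param cds_index CDS controlled by this RBS.
#' @param n upstream averaging window, nt (default 30 = 10 codons).
#' @param ramp_skip nt of CDS excluded at the 5' end (default 51).
#' @return list with `upstream`, `cds` (each `c(start, end)`), and `qc`.
#' @export
rbs_windows <- function(model, x0 = model$rbs_start, cds_index = 1L,
                        n = 30L, ramp_skip = 51L) {
  stopifnot(!is.na(x0))
  cds <- model$cds[[cds_index]]
  if (cds[2] - cds[1] <= ramp_skip + 3L)
    stop("CDS shorter than ramp exclusion + one codon")
  qc <- "ok"
  us <- max(0L, x0 - n)                     # TSS clip (transcript axis 0)
  for (other in model$cds[-cds_index]) {    # operon neighbour upstream
    e <- other[2]
    if (e <= x0 && e > x0 - n) us <- max(us, e + 9L)
  }
  if (us >= x0) qc <- "window_truncated"
  list(upstream = c(us, x0), cds = c(cds[1] + ramp_skip, cds[2] - 3L),
       qc = qc)
}

# first out-of-frame stop codon at/after `from`, in the frame whose codon
# starts are congruent to `shift` relative to the CDS grid; returns the
# half-open end of that stop codon, or tx length if none (flagged upstream).
.first_oof_stop <- function(model, from, cds_index, shift) {
  len <- model$length
  if (is.null(model$sequence)) return(NA_integer_)
  anchor <- model$cds[[cds_index]][1] + shift
  c0 <- from + ((anchor - from) %% 3L)
  starts <- seq.int(c0, len - 3L, by = 3L)
  if (!length(starts)) return(len)
  cods <- substring(model$sequence, starts + 1L, starts + 3L)
  hit <- which(cods %in% .STOP_CODONS)
  if (!length(hit)) return(len)
  starts[hit[1]] + 3L
}

#' Out-of-frame flux corrections for RBS measurement
#'
#' Ribosomes translating upstream of an RBS in the -1 or +1 frame relative
#' to the RBS-controlled ORF inflate both windows of the RBS model but stop
#' at the first out-of-frame stop codon downstream. `C-` and `C+` are the
#' mean per-nucleotide flux in the upstream window attributable to P sites
#' in each out-of-frame register; `C(x)` carries their sum downstream,
#' dropping each term once x passes that frame's first stop (`s-`, `s+`).
#'
#' @param R_tx translation profile over the transcript axis (ribosomes/s).
#' @param model a `TranscriptModel` (sequence needed to locate stops).
#' @param windows window list from [rbs_windows()].
#' @param cds_index CDS anchoring the frames.
#' @return list `C_minus`, `C_plus`, `s_minus`, `s_plus`, `C` (vectorized
#'   function of transcript position), `flag` (TRUE when a frame had no stop
#'   before the transcript end).
#' @export
frame_corrections <- function(R_tx, model, windows, cds_index = 1L) {
  w <- windows$upstream
  len_w <- w[2] - w[1]
  if (len_w <= 0) {
    C_minus <- C_plus <- 0
  } else {
    pos <- w[1]:(w[2] - 1L)
    fr <- frame_offset(model, pos, cds_index)
    C_minus <- sum(R_tx[pos[fr == 2L] + 1L]) / len_w
    C_plus <- sum(R_tx[pos[fr == 1L] + 1L]) / len_w
  }
  from <- max(0L, w[1])
  s_minus <- .first_oof_stop(model, from, cds_index, -1L)
  s_plus <- .first_oof_stop(model, from, cds_index, 1L)
  flag <- FALSE
  if (is.na(s_minus)) { s_minus <- model$length; flag <- TRUE }
  if (is.na(s_plus)) { s_plus <- model$length; flag <- TRUE }
  if (s_minus >= model$length || s_plus >= model$length) flag <- TRUE
  Cfun <- function(x) C_minus * (x < s_minus) + C_plus * (x < s_plus)
  list(C_minus = C_minus, C_plus = C_plus,
       s_minus = s_minus, s_plus = s_plus, C = Cfun, flag = flag)
}

#' RBS translation initiation rate (ribosomes/s)
#'
#' The jump in ribosome flux across the RBS: the mean corrected profile over
#' the CDS window minus the mean corrected profile over the upstream window.
#'
#' @inheritParams frame_corrections
#' @param N_tx optional raw footprint counts over the transcript axis; when
#'   given, measurements whose CDS window holds fewer than `min_rpf`
#'   footprints are withheld (`qc = "low_coverage"`) unless `force`.
#' @param min_rpf minimum footprints in the CDS window (default 5).
#' @param force report the estimate despite low coverage or a below-limit
#'   copy-number flag.
#' @param below_limit transcript copy number was below the spike-in
#'   detection limit.
#' @inheritParams rbs_windows
#' @return one-row `data.table`: `part_id`, `kind`, `estimate`, `units`,
#'   `window_upstream`, `window_cds`, `qc`.
#' @export
rbs_initiation_rate <- function(R_tx, model, x0 = model$rbs_start,
                                cds_index = 1L, n = 30L, ramp_skip = 51L,
                                N_tx = NULL, min_rpf = 5, force = FALSE,
                                below_limit = FALSE) {
  w <- rbs_windows(model, x0, cds_index, n, ramp_skip)
  corr <- frame_corrections(R_tx, model, w, cds_index)
  cds_pos <- w$cds[1]:(w$cds[2] - 1L)
  mean_cds <- mean(R_tx[cds_pos + 1L] - corr$C(cds_pos))
  mean_up <- if (w$upstream[2] > w$upstream[1])
    .win_mean(R_tx, w$upstream) - corr$C_minus - corr$C_plus else 0
  est <- mean_cds - mean_up
  qc <- w$qc
  if (below_limit) qc <- "below_detection"
  if (!is.null(N_tx) && .win_sum(N_tx, w$cds) < min_rpf) qc <- "low_coverage"
  if (qc != "ok" && !force) est <- NA_real_
  data.table(part_id = paste0(model$id, ":rbs"), kind = "rbs",
             estimate = est, units = "ribosomes/s",
             window_upstream = .fmt_win(w$upstream),
             window_cds = .fmt_win(w$cds), qc = qc)
}

# half-open end of the downstream T_e window: x1 + n, truncated at the next
# in-frame stop codon (readthrough ribosomes terminate there) or tx end.
.te_downstream_end <- function(model, x1, n, cds_index) {
  lim <- min(model$length, x1 + n)
  if (is.null(model$sequence)) return(lim)
  starts <- seq.int(x1, lim - 3L, by = 3L)
  if (length(starts)) {
    cods <- substring(model$sequence, starts + 1L, starts + 3L)
    hit <- which(cods %in% .STOP_CODONS)
    if (length(hit)) lim <- min(lim, starts[hit[1]])
  }
  lim
}

#' Stop-codon translation termination efficiency
#'
#' `T_e = 1 - mean(R over [x1, x1+n)) / mean(R over [x_s+51, x0))`: the
#' fraction of ribosomes that dissociate at the stop codon rather than read
#' through. The downstream window is truncated at the next in-frame stop
#' codon (where readthrough ribosomes terminate) or the transcript end.
#'
#' @inheritParams rbs_initiation_rate
#' @param cds_index CDS whose stop codon is measured.
#' @return one-row `data.table` as in [rbs_initiation_rate()] (estimate is a
#'   fraction; values outside [0,1] are flagged `qc = "out_of_range"`).
#' @export
termination_efficiency <- function(R_tx, model, cds_index = 1L, n = 30L,
                                   ramp_skip = 51L, N_tx = NULL, min_rpf = 5,
                                   force = FALSE) {
  cds <- model$cds[[cds_index]]
  x0 <- cds[2] - 3L; x1 <- cds[2]
  up <- c(cds[1] + ramp_skip, x0)
  dn <- c(x1, .te_downstream_end(model, x1, n, cds_index))
  qc <- "ok"
  if (dn[2] <= dn[1]) qc <- "window_truncated"
  mean_up <- .win_mean(R_tx, up)
  mean_dn <- if (qc == "window_truncated") NA_real_ else .win_mean(R_tx, dn)
  est <- NA_real_
  if (is.na(mean_up) || mean_up == 0) {
    qc <- "low_coverage"
  } else if (qc != "window_truncated") {
    est <- 1 - mean_dn / mean_up
  }
  if (!is.null(N_tx) && .win_sum(N_tx, up) < min_rpf) {
    qc <- "low_coverage"
    if (!force) est <- NA_real_
  }
  if (!is.na(est) && (est < 0 || est > 1)) qc <- "out_of_range"
  data.table(part_id = paste0(model$id, ":stop", cds_index), kind = "stop",
             estimate = est, units = "fraction",
             window_upstream = .fmt_win(up), window_cds = .fmt_win(dn),
             qc = qc)
}

#' Frameshifting efficiency at a recoding site
#'
#' Compares footprint density upstream (the region directly downstream of
#' the stimulating structure, `[x_s, x0)`) and downstream (`[x1, x_e)`) of
#' the junction. Returns both `F_e = 1 - mean_down / mean_up` (the fraction
#' of ribosomes not continuing) and the continuation ratio
#' `mean_down / mean_up`, which is the quantity comparable to a percent of
#' frameshifting ribosomes. The two are complementary readings of the same
#' comparison; both are reported.
#'
#' @param R_tx translation profile over the transcript axis.
#' @param regions list or vector with `xs`, `x0` (upstream region bounds)
#'   and `x1`, `xe` (downstream region bounds), transcript axis, half-open.
#' @param part_id identifier for the output row.
#' @return two-row `data.table` (kinds `frameshift_Fe` and
#'   `frameshift_ratio`).
#' @export
frameshift_efficiency <- function(R_tx, regions, part_id = "frameshift") {
  xs <- regions[["xs"]]; x0 <- regions[["x0"]]
  x1 <- regions[["x1"]]; xe <- regions[["xe"]]
  mean_up <- .win_mean(R_tx, c(xs, x0))
  mean_dn <- .win_mean(R_tx, c(x1, xe))
  qc <- "ok"
  if (is.na(mean_up) || mean_up == 0) {
    fe <- ratio <- NA_real_
    qc <- "low_coverage"
  } else {
    ratio <- mean_dn / mean_up
    fe <- 1 - ratio
    if (ratio < 0 || ratio > 1) qc <- "out_of_range"
  }
  data.table(part_id = part_id,
             kind = c("frameshift_Fe", "frameshift_ratio"),
             estimate = c(fe, ratio), units = "fraction",
             window_upstream = .fmt_win(c(xs, x0)),
             window_cds = .fmt_win(c(x1, xe)), qc = qc)
}

#' Fraction of footprints in each reading frame
#'
#' Pools raw footprint counts over a region and splits them by the frame
#' label of each P-site position relative to the anchoring CDS.
#'
#' @param N_tx raw footprint counts over the transcript axis.
#' @param model a `TranscriptModel`.
#' @param region `c(start, end)` transcript-axis half-open interval.
#' @param cds_index CDS anchoring frame 0.
#' @return named numeric `c(f0, fp1, fm1)` summing to 1, or all `NA` when the
#'   region holds no reads.
#' @export
frame_fractions <- function(N_tx, model, region, cds_index = 1L) {
  pos <- region[1]:(region[2] - 1L)
  fr <- frame_offset(model, pos, cds_index)
  tot <- sum(N_tx[pos + 1L])
  if (tot == 0) return(c(f0 = NA_real_, fp1 = NA_real_, fm1 = NA_real_))
  c(f0 = sum(N_tx[pos[fr == 0L] + 1L]) / tot,
    fp1 = sum(N_tx[pos[fr == 1L] + 1L]) / tot,
    fm1 = sum(N_tx[pos[fr == 2L] + 1L]) / tot)
}

# window means on the reference axis, oriented along transcription
.ref_flank_means <- function(values, pos, n, strand) {
  len <- length(values)
  if (strand == "+") {
    up <- c(max(0L, pos - n), pos); dn <- c(pos, min(len, pos + n))
  } else {
    dn <- c(max(0L, pos - n), pos); up <- c(pos, min(len, pos + n))
  }
  list(up = .win_mean(values, up), dn = .win_mean(values, dn),
       up_w = up, dn_w = dn)
}

#' Promoter strength and terminator efficiency from transcription profiles
#'
#' Promoter strength is the step in RNAP flux across the transcription start
#' site: mean T(x) over the 30 nt downstream minus the 30 nt upstream.
#' Terminator efficiency is the fractional drop across the terminator:
#' `1 - mean_downstream / mean_upstream`.
#'
#' @param Tprof a `TranscriptionProfile`.
#' @param reference reference sequence name.
#' @param pos reference-axis position of the TSS / terminator (0-based).
#' @param strand transcription direction.
#' @param n flanking window, nt.
#' @param part_id identifier for the output row.
#' @return one-row `data.table` in the common part-measurement layout.
#' @export
promoter_strength <- function(Tprof, reference, pos, strand = "+", n = 30L,
                              part_id = "promoter") {
  fm <- .ref_flank_means(Tprof$values[[reference]], pos, n, strand)
  data.table(part_id = part_id, kind = "promoter",
             estimate = fm$dn - fm$up, units = "RNAP/s",
             window_upstream = .fmt_win(fm$up_w),
             window_cds = .fmt_win(fm$dn_w), qc = "ok")
}

#' @rdname promoter_strength
#' @export
terminator_efficiency <- function(Tprof, reference, pos, strand = "+",
                                  n = 30L, part_id = "terminator") {
  fm <- .ref_flank_means(Tprof$values[[reference]], pos, n, strand)
  qc <- "ok"; est <- NA_real_
  if (is.na(fm$up) || fm$up == 0) {
    qc <- "low_coverage"
  } else {
    est <- 1 - fm$dn / fm$up
    if (est < 0 || est > 1) qc <- "out_of_range"
  }
  data.table(part_id = part_id, kind = "terminator", estimate = est,
             units = "fraction", window_upstream = .fmt_win(fm$up_w),
             window_cds = .fmt_win(fm$dn_w), qc = qc)
}

#' Measure every annotated part of an experiment
#'
#' Driver that walks the part table and emits one measurement row per part:
#' RBS initiation rates (Eq.-2-style step with out-of-frame corrections),
#' stop-codon termination efficiencies for every transcript with a CDS
#' (skipping transcripts bearing an annotated frameshift site, whose flux
#' model is violated), frameshift efficiencies, and promoter/terminator
#' strengths when a transcription profile is supplied.
#'
#' @param profile a `TranslationProfile`.
#' @param N raw `CoverageTrack` (for coverage gates and frame fractions).
#' @param transcripts a `TranscriptSet`.
#' @param parts part `data.table` from [load_annotation()].
#' @param Tprof optional `TranscriptionProfile`.
#' @param min_rpf,force see [rbs_initiation_rate()].
#' @return `data.table` of part measurements.
#' @export
measure_parts <- function(profile, N, transcripts, parts, Tprof = NULL,
                          min_rpf = 5, force = FALSE) {
  out <- list()
  fs_tx <- parts[kind == "frameshift_site", transcript_id]
  for (m in transcripts) {
    if (!length(m$cds)) next
    R_tx <- profile$tracks[[m$id]]
    if (is.null(R_tx)) next
    N_tx <- tx_coverage(N, m)
    bl <- isTRUE(profile$below_limit[[m$id]])
    prow <- parts[kind == "rbs" & transcript_id == m$id]
    x0 <- if (nrow(prow)) prow$start[1] else m$rbs_start
    if (!is.na(x0))
      out[[length(out) + 1L]] <- rbs_initiation_rate(
        R_tx, m, x0 = x0, N_tx = N_tx, min_rpf = min_rpf, force = force,
        below_limit = bl)
    if (!m$id %in% fs_tx)
      out[[length(out) + 1L]] <- termination_efficiency(
        R_tx, m, N_tx = N_tx, min_rpf = min_rpf, force = force)
  }
  for (i in which(parts$kind == "frameshift_site")) {
    m <- transcripts[[parts$transcript_id[i]]]
    R_tx <- profile$tracks[[m$id]]
    out[[length(out) + 1L]] <- frameshift_efficiency(
      R_tx, list(xs = parts$start[i], x0 = parts$end[i],
                 x1 = parts$start2[i], xe = parts$end2[i]),
      part_id = paste0(m$id, ":frameshift"))
  }
  if (!is.null(Tprof)) {
    for (i in which(parts$kind == "promoter")) {
      m <- transcripts[[parts$transcript_id[i]]]
      out[[length(out) + 1L]] <- promoter_strength(
        Tprof, m$reference, tx_to_ref(m, parts$start[i]), m$strand,
        part_id = paste0(m$id, ":promoter"))
    }
    for (i in which(parts$kind == "terminator")) {
      m <- transcripts[[parts$transcript_id[i]]]
      out[[length(out) + 1L]] <- terminator_efficiency(
        Tprof, m$reference, tx_to_ref(m, parts$start[i]), m$strand,
        part_id = paste0(m$id, ":terminator"))
    }
  }
  rbindlist(out)
}
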