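#' Spike-in sets and absolute calibration
#'
#' Quantitative RNA-seq is calibrated with synthetic RNA spike-ins added at
#' known molar amounts before fragmentation. Because alkaline fragmentation
#' makes read yield proportional to RNA mass, expected reads are proportional
#' to `molecules x length`; the fitted slope `k` (reads per nt per molecule)
#' converts any transcript's reads/nt into molecules, and division by the
#' cell count gives copies per cell.
#'
#' @param path TSV with columns `id`, `length_nt`, `molecules_per_sample`.
#' @return a `SpikeInSet` with zeroed read tallies and no fit.
#' @export
load_spikein_sheet <- function(path) {
  sheet <- fread(path)
  need <- c("id", "length_nt", "molecules_per_sample")
  if (!all(need %in% names(sheet)))
    stop("spike-in sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$id)) stop("duplicate spike-in id(s)")
  if (any(sheet$length_nt <= 0)) stop("spike-in lengths must be > 0")
  if (any(sheet$molecules_per_sample < 0)) stop("negative molecules_per_sample")
  spikein_set(sheet)
}

#' @rdname load_spikein_sheet
#' @param sheet a data.frame with the three sheet columns.
#' @export
spikein_set <- function(sheet) {
  sheet <- as.data.table(sheet)[, .(id, length_nt, molecules_per_sample)]
  sheet[, mapped_reads := 0L]
  structure(list(sheet = sheet, fit = NULL), class = "SpikeInSet")
}

#' @export
print.SpikeInSet <- function(x, ...) {
  cat(sprintf("SpikeInSet: %d spike-ins%s\n", nrow(x$sheet),
              if (is.null(x$fit)) " (unfitted)" else
                sprintf(", k = %.3g reads/nt/molecule, detection limit %.3g RPKM (%d linear)",
                        x$fit$k, x$fit$detection_limit, length(x$fit$linear_ids))))
  invisible(x)
}

#' Tally RNA-seq reads on the spike-in references
#' @param spikeins a `SpikeInSet`.
#' @param reads RNA-seq read `data.table` ([load_reads()]).
#' @export
tally_spikein_reads <- function(spikeins, reads) {
  counts <- reads[reference %in% spikeins$sheet$id, .N, by = reference]
  spikeins$sheet[, mapped_reads := 0L]
  spikeins$sheet[counts, mapped_reads := i.N, on = c(id = "reference")]
  spikeins$fit <- NULL
  spikeins
}

#' Detection limit and linear spike-in subset
#'
#' Scans candidate RPKM thresholds (the observed spike-in RPKMs, ascending)
#' and keeps the lowest threshold for which the spike-ins at or above it show
#' a linear dependence between reads and molecules. Linearity is judged on
#' log-log axes against the mass-proportional model `reads/nt = k x
#' molecules` (slope fixed at 1, intercept `log k` fitted): the subset passes
#' when `R^2 >= r2_min` over at least `min_points` spike-ins.
#'
#' The fitted slope `k` is then taken as the pooled ratio
#' `sum(reads) / sum(molecules x length)` over the linear subset, the
#' Poisson maximum-likelihood estimate.
#'
#' @param spikeins a `SpikeInSet` with tallied reads.
#' @param total_mapped_reads total mapped RNA-seq reads (for RPKM); default
#'   is the sum of spike-in reads only, so pass the library total for
#'   meaningful RPKM units.
#' @param r2_min linearity threshold (default 0.9, `--linearity-r2`).
#' @param min_points minimum spike-ins in the linear subset (default 3).
#' @return the `SpikeInSet` with `fit = list(k, detection_limit, linear_ids)`.
#' @export
detection_limit <- function(spikeins, total_mapped_reads = NULL,
                            r2_min = 0.9, min_points = 3L) {
  sh <- copy(spikeins$sheet)
  if (is.null(total_mapped_reads)) total_mapped_reads <- sum(sh$mapped_reads)
  if (sum(sh$mapped_reads > 0) < min_points)
    stop("calibration failed: fewer than ", min_points, " spike-ins with reads")
  sh[, rpkm := mapped_reads / (length_nt / 1e3) / (total_mapped_reads / 1e6)]
  cand <- sort(unique(sh[mapped_reads > 0, rpkm]))
  chosen <- NULL
  for (thr in cand) {
    sub <- sh[rpkm >= thr & mapped_reads > 0 & molecules_per_sample > 0]
    if (nrow(sub) < min_points) break
    y <- log(sub$mapped_reads / sub$length_nt)
    x <- log(sub$molecules_per_sample)
    c0 <- mean(y - x)
    ss_res <- sum((y - x - c0)^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
    if (r2 >= r2_min) { chosen <- list(thr = thr, ids = sub$id); break }
  }
  if (is.null(chosen))
    stop("calibration failed: no linear subset of size >= ", min_points,
         " at R^2 >= ", r2_min)
  lin <- sh[id %in% chosen$ids]
  k <- sum(lin$mapped_reads) /
    sum(lin$molecules_per_sample * lin$length_nt)
  spikeins$fit <- list(k = k, detection_limit = chosen$thr,
                       linear_ids = chosen$ids,
                       total_mapped_reads = total_mapped_reads)
  spikeins
}

#' Absolute transcript copies per cell
#'
#' `copies = (reads / length) / k / n_cells`, with `k` the fitted spike-in
#' slope. Estimates whose RPKM falls below the spike-in detection limit are
#' flagged (`below_limit`), never zeroed: the point estimate is retained so
#' that downstream code can decide whether to trust it.
#'
#' @param read_count mapped reads for the transcript(s).
#' @param length transcript length(s), nt.
#' @param spikeins a fitted `SpikeInSet`.
#' @param cells a `CellParams` object.
#' @return `data.table` with `copies_per_cell` and `below_limit`.
#' @export
copies_per_cell <- function(read_count, length, spikeins, cells) {
  if (is.null(spikeins$fit)) stop("SpikeInSet is unfitted; run detection_limit()")
  stopifnot(all(length > 0))
  copies <- (read_count / length) / spikeins$fit$k / cells$n_cells
  rpkm <- read_count / (length / 1e3) /
    (spikeins$fit$total_mapped_reads / 1e6)
  data.table(copies_per_cell = copies,
             below_limit = rpkm < spikeins$fit$detection_limit)
}

# ---- cell parameters -------------------------------------------------------

#' Cell parameters
#'
#' Bundle of the experimentally measured cellular quantities needed for
#' absolute units: doubling time (s), total protein mass (g/cell), cell
#' count per sample, and per-transcript mRNA degradation rates (1/s). A
#' transcript with no measured rate falls back to the fixed default
#' 0.0067/s.
#'
#' @param t_d doubling time, seconds.
#' @param m_t total protein mass, g/cell.
#' @param n_cells cells per sample.
#' @param d named numeric of transcript-specific degradation rates (1/s).
#' @param d_default fallback degradation rate (1/s).
#' @export
cell_params <- function(t_d, m_t, n_cells, d = numeric(), d_default = 0.0067) {
  stopifnot(t_d > 0, m_t > 0, n_cells > 0, d_default > 0, all(d > 0))
  structure(list(t_d = t_d, m_t = m_t, n_cells = n_cells,
                 d = d, d_default = d_default), class = "CellParams")
}

#' @rdname cell_params
#' @param cells a `CellParams`.
#' @param ids transcript ids to look up.
#' @export
degradation_rate <- function(cells, ids) {
  out <- cells$d[ids]
  out[is.na(out)] <- cells$d_default
  unname(out)
}

#' Read per-transcript degradation rates from TSV (`transcript_id`, `rate`)
#' @rdname cell_params
#' @param path TSV path.
#' @export
load_degradation_rates <- function(path) {
  dt <- fread(path)
  stopifnot(all(c("transcript_id", "rate") %in% names(dt)))
  setNames(dt$rate, dt$transcript_id)
}

# ---- protein mass ----------------------------------------------------------

# Average (not monoisotopic) residue masses, Da. One water is added per chain.
.AA_RESIDUE_DA <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_DA <- 18.01524
.AVOGADRO <- 6.02214076e23

#' Protein mass from an amino acid sequence
#'
#' Sums average residue masses, adds one water, and converts Da to grams via
#' Avogadro's number. Average masses are used because the quantity feeds a
#' bulk protein-mass balance, not mass spectrometry.
#'
#' @param aa_sequence character vector of amino acid sequences (one-letter,
#'   standard 20 residues; a trailing `*` is tolerated and ignored).
#' @return mass in grams, one value per sequence.
#' @export
protein_mass <- function(aa_sequence) {
  vapply(aa_sequence, function(s) {
    s <- sub("\\*$", "", s)
    if (nchar(s) == 0L) stop("empty amino acid sequence")
    aa <- strsplit(s, "")[[1]]
    bad <- which(!aa %in% names(.AA_RESIDUE_DA))
    if (length(bad))
      stop("unknown residue '", aa[bad[1]], "' at position ", bad[1])
    (sum(.AA_RESIDUE_DA[aa]) + .WATER_DA) / .AVOGADRO
  }, numeric(1), USE.NAMES = FALSE)
}
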