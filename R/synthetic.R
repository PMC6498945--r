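#' Simulation configuration
#'
#' Describes a synthetic steady-state exponential culture: a transcriptome
#' with copy numbers spanning ~4 decades, per-RBS initiation rates spanning
#' 0.03-3 ribosomes/s, stop codons drawn from a set of termination
#' efficiencies, an optional high-expression pseudoknot construct carrying a
#' -1 frameshift junction, a two-isoform terminator locus, and an ERCC-like
#' spike-in set (92 species, 250-2,000 nt, 6 decades of concentration).
#' Footprints are 23-28 nt with length-specific 3'-anchored P-site offsets.
#'
#' Position-specific dwell features mirror real bacterial profiles: a 5'
#' ramp decaying over the first 17 codons, a termination pause at the last
#' sense codon (stop codon in the A site), and a stall at the pseudoknot.
#' Setting `ramp_height = 1`, `stop_pause = 1`, `pk_pause = 1` yields the
#' idealized constant-speed world in which the part equations are exact.
#'
#' @param n_transcripts number of regular transcripts.
#' @param cds_codons range of CDS lengths, codons (stop included).
#' @param utr5 5' UTR length, nt (RBS sits in its 3' end).
#' @param utr3_clear_codons in-frame sense codons after the stop before the
#'   readthrough-terminating UTR stop codon.
#' @param utr3_tail extra 3' nt after the UTR stop.
#' @param copies_decades log10 range of transcript copies per cell.
#' @param init_range range of RBS initiation rates, ribosomes/s (log-uniform).
#' @param init_fixed if non-NULL, all transcripts get this initiation rate.
#' @param term_effs termination efficiencies sampled per transcript.
#' @param term_fixed if non-NULL, all transcripts get this efficiency.
#' @param codon_times named codon dwell-time table (default uniform).
#' @param offsets named P-site offsets (3' end to P-site center) per length.
#' @param length_probs named sampling weights for read lengths.
#' @param depth_ribo,depth_rna total reads emitted per assay.
#' @param spike_n,spike_length_range,spike_decades,spike_share spike-in set
#'   geometry and its share of RNA-seq read mass.
#' @param stop_pause dwell multiplier at the last sense codon.
#' @param ramp_height,ramp_codons 5' ramp: dwell multiplier decays linearly
#'   from `ramp_height` to 1 over `ramp_codons` codons.
#' @param include_frameshift add the pseudoknot construct.
#' @param frameshift_fraction fraction of ribosomes shifting to -1 at the
#'   slippery site.
#' @param construct_mrna_share construct share of all mRNA molecules.
#' @param construct_codons,construct_lacz_codons,construct_middle_codons
#'   construct geometry (codons; middle = slippery site + pseudoknot region).
#' @param construct_init,construct_term_eff construct initiation rate and
#'   gene10 stop-codon efficiency.
#' @param pk_dropoff fraction of ribosomes lost at the pseudoknot (0 keeps
#'   the full-length-product assumption intact; ~0.85 emulates a heavily
#'   sequestering stall).
#' @param pk_pause dwell multiplier at the two codons abutting the
#'   pseudoknot.
#' @param include_terminator_locus add a two-isoform locus for
#'   promoter/terminator readout.
#' @param terminator_eff,terminator_copies terminator truth and total copies
#'   at that locus.
#' @param t_d doubling time, s.
#' @param n_cells cells per sample.
#' @param d_rate mRNA degradation rate, 1/s.
#' @param pad reference padding either side of each transcript, nt.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(
    n_transcripts = 50L, cds_codons = c(150L, 400L),
    utr5 = 60L, utr3_clear_codons = 12L, utr3_tail = 21L,
    copies_decades = c(-2, 2),
    init_range = c(0.03, 3), init_fixed = NULL,
    term_effs = c(0.9, 0.97, 0.99), term_fixed = NULL,
    codon_times = NULL,
    offsets = c(`23` = 12L, `24` = 12L, `25` = 13L, `26` = 13L,
                `27` = 14L, `28` = 14L),
    length_probs = c(`23` = 0.05, `24` = 0.10, `25` = 0.15, `26` = 0.20,
                     `27` = 0.25, `28` = 0.25),
    depth_ribo = 8e6, depth_rna = 2e6,
    spike_n = 92L, spike_length_range = c(250L, 2000L), spike_decades = 6,
    spike_share = 0.05,
    stop_pause = 5, ramp_height = 2, ramp_codons = 17L,
    include_frameshift = TRUE, frameshift_fraction = 0.03,
    construct_mrna_share = 0.4, construct_codons = 220L,
    construct_lacz_codons = 200L, construct_middle_codons = 20L,
    construct_init = 0.5, construct_term_eff = 0.97,
    pk_dropoff = 0, pk_pause = 10,
    include_terminator_locus = TRUE, terminator_eff = 0.95,
    terminator_copies = 20,
    t_d = 3000, n_cells = 1e8, d_rate = 0.0067, pad = 40L) {
  if (is.null(codon_times)) codon_times <- default_codon_times()
  cfg <- as.list(environment())
  stopifnot(cfg$frameshift_fraction >= 0, cfg$frameshift_fraction <= 1,
            cfg$pk_dropoff >= 0, cfg$pk_dropoff < 1,
            all(cfg$offsets >= 0),
            all(cfg$offsets < as.integer(names(cfg$offsets))),
            cfg$construct_middle_codons + 20L < cfg$construct_codons)
  structure(cfg, class = "SimulationConfig")
}

#' @rdname simulation_config
#' @param ... overrides passed to [simulation_config()].
#' @details `burden_config()` bundles the ribosome-sequestration scenario: a
#'   heavily stalling pseudoknot that drops 85% of ribosomes, emulating a
#'   construct that captures a large share of the translating pool. It
#'   violates the every-footprint-completes-a-protein assumption on purpose
#'   and is meant for qualitative burden analyses, not rate recovery.
#' @export
burden_config <- function(...) {
  simulation_config(pk_dropoff = 0.85, ...)
}

.SENSE_CODONS <- setdiff(names(default_codon_times()), .STOP_CODONS)

.rand_sense <- function(n) sample(.SENSE_CODONS, n, replace = TRUE)
.rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# linear 5' ramp multipliers for n_sense codons
.ramp_mult <- function(n_sense, cfg) {
  m <- rep(1, n_sense)
  k <- min(cfg$ramp_codons, n_sense)
  if (cfg$ramp_height != 1 && k > 1)
    m[1:k] <- seq(cfg$ramp_height, 1, length.out = k)
  m
}

# Build one regular transcript plus its flux streams.
# A stream is a set of P-site codon centers visited at a common per-copy
# flux; `mult` carries position-specific dwell multipliers.
.build_regular <- function(id, n_cod, dR, te, cfg) {
  n_sense <- n_cod - 1L
  cds_seq <- paste0("ATG", paste(.rand_sense(n_sense - 1L), collapse = ""), "TAA")
  utr3 <- paste0(paste(.rand_sense(cfg$utr3_clear_codons), collapse = ""),
                 "TAA", .rand_nt(cfg$utr3_tail))
  seq <- paste0(.rand_nt(cfg$utr5), cds_seq, utr3)
  len <- nchar(seq)
  xs <- cfg$utr5
  model <- transcript_model(id, id, "+", cfg$pad, cfg$pad + len,
                            cds = list(c(xs, xs + 3L * n_cod)),
                            rbs_start = xs - 15L, sequence = seq)
  x0s <- xs + 3L * n_sense; x1 <- x0s + 3L
  mult <- .ramp_mult(n_sense, cfg)
  mult[n_sense] <- mult[n_sense] * cfg$stop_pause
  main <- data.table(center = xs + 1L + 3L * (0:(n_sense - 1L)),
                     flux = dR, mult = mult)
  rt_n <- cfg$utr3_clear_codons
  rt_mult <- c(1, rep(1, rt_n))
  rt_mult[rt_n + 1L] <- cfg$stop_pause
  rt <- data.table(center = c(x0s + 1L, x1 + 1L + 3L * (0:(rt_n - 1L))),
                   flux = (1 - te) * dR, mult = rt_mult)
  streams <- rbind(main, rt)[flux > 0]
  streams[, id := id]
  list(model = model, streams = streams)
}

# Pseudoknot construct: gene10 (frame 0, ends with a stop) fused to a lacZ
# ORF in the -1 frame; frameshift happens at the start of the middle region.
.build_construct <- function(cfg, dR, te, fs) {
  n_cod <- cfg$construct_codons; n_sense <- n_cod - 1L
  mc <- cfg$construct_middle_codons; L2 <- cfg$construct_lacz_codons
  pc <- 1 - cfg$pk_dropoff
  cds_seq <- paste0("ATG", paste(.rand_sense(n_sense - 1L), collapse = ""), "TAA")
  # -1 ORF: first codon starts on the final A of gene10's TAA stop
  c1 <- sample(grep("^A", .SENSE_CODONS, value = TRUE), 1L)
  lacz_cod <- c(c1, .rand_sense(L2 - 2L), "TAA")
  tail_seq <- .rand_nt(20L)
  seq <- paste0(.rand_nt(cfg$utr5), cds_seq,
                substring(paste(lacz_cod, collapse = ""), 2L), tail_seq)
  len <- nchar(seq)
  xs <- cfg$utr5
  e <- xs + 3L * n_cod                      # end of gene10 CDS
  model <- transcript_model("construct", "construct", "+", cfg$pad,
                            cfg$pad + len,
                            cds = list(c(xs, e), c(e - 1L, e - 1L + 3L * L2)),
                            rbs_start = xs - 15L, sequence = seq)
  m_s <- xs + 3L * (n_sense - mc)           # middle-region start
  x0s <- xs + 3L * n_sense; x1 <- x0s + 3L
  mult <- .ramp_mult(n_sense, cfg)
  pk_at <- (n_sense - mc - 1L):(n_sense - mc)
  mult[pk_at] <- mult[pk_at] * cfg$pk_pause
  mult[n_sense] <- mult[n_sense] * cfg$stop_pause
  flux <- c(rep(dR, n_sense - mc), rep(pc * (1 - fs) * dR, mc))
  main <- data.table(center = xs + 1L + 3L * (0:(n_sense - 1L)),
                     flux = flux, mult = mult)
  # frame-0 readthrough of the gene10 stop, until the next frame-0 stop
  rt_flux <- pc * (1 - fs) * (1 - te) * dR
  rt_end <- .te_downstream_end(model, x1, len - x1, 1L)
  rt_centers <- c(x0s + 1L)
  if (rt_end > x1 + 2L) rt_centers <- c(rt_centers, seq.int(x1 + 1L, rt_end - 2L, 3L))
  rt_mult <- rep(1, length(rt_centers)); rt_mult[length(rt_mult)] <- cfg$stop_pause
  rt <- data.table(center = rt_centers, flux = rt_flux, mult = rt_mult)
  # -1-frame stream: from the slippery site through the lacZ ORF
  m1_centers <- seq.int(m_s, e + 3L * (L2 - 2L), 3L)
  m1_mult <- rep(1, length(m1_centers)); m1_mult[length(m1_mult)] <- cfg$stop_pause
  m1 <- data.table(center = m1_centers, flux = pc * fs * dR, mult = m1_mult)
  streams <- rbind(main, rt, m1)[flux > 0]
  streams[, id := "construct"]
  parts <- data.table(
    kind = c("rbs", "frameshift_site"), transcript_id = "construct",
    start = c(xs - 15L, m_s), end = c(xs, x0s),
    start2 = c(NA_integer_, e), end2 = c(NA_integer_, e + 3L * (L2 - 1L)))
  list(model = model, streams = streams, parts = parts)
}

#' Simulate a combined Ribo-seq / quantitative RNA-seq experiment
#'
#' Draws the world described by a [simulation_config()] and emits mapped
#' reads for both assays (position-table layout, one reference per
#' transcription unit, plus spike-in references), together with annotation,
#' part table, spike-in sheet, cell parameters, and a ground-truth ledger.
#' RNA-seq reads are drawn proportional to molecules x length (random
#' fragmentation); footprints are drawn per P-site codon proportional to
#' copies x flux x dwell, then dressed with a sampled read length and that
#' length's 3' P-site offset. Counting noise is multinomial at fixed total
#' depth (Poisson per position conditioned on depth). The same seed yields
#' byte-identical output.
#'
#' @param config a `SimulationConfig`.
#' @param seed integer seed; fully determines the output.
#' @return a `FluxSim` list: `transcripts`, `parts`, `spikeins`, `cells`,
#'   `reads_ribo`, `reads_rna`, `truth` (ledger), `streams`, `config`,
#'   `seed`.
#' @export
simulate_experiment <- function(config = simulation_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  n <- cfg$n_transcripts
  ids <- sprintf("tx%03d", seq_len(n))
  len_rng <- seq.int(cfg$cds_codons[1], cfg$cds_codons[2])
  n_cods <- len_rng[sample.int(length(len_rng), n, replace = TRUE)]
  copies <- 10^runif(n, cfg$copies_decades[1], cfg$copies_decades[2])
  dRs <- if (!is.null(cfg$init_fixed)) rep(cfg$init_fixed, n)
         else 10^runif(n, log10(cfg$init_range[1]), log10(cfg$init_range[2]))
  tes <- if (!is.null(cfg$term_fixed)) rep(cfg$term_fixed, n)
         else sample(cfg$term_effs, n, replace = TRUE)

  models <- list(); streams <- list(); parts <- list()
  tx_truth <- list()
  for (i in seq_len(n)) {
    b <- .build_regular(ids[i], n_cods[i], dRs[i], tes[i], cfg)
    models[[ids[i]]] <- b$model
    streams[[ids[i]]] <- b$streams
    parts[[ids[i]]] <- data.table(
      kind = "rbs", transcript_id = ids[i],
      start = b$model$rbs_start, end = b$model$rbs_start + 15L,
      start2 = NA_integer_, end2 = NA_integer_)
    tx_truth[[ids[i]]] <- data.table(
      id = ids[i], type = "regular", copies = copies[i],
      init_rate = dRs[i], term_eff = tes[i])
  }
  if (cfg$include_frameshift) {
    copies_c <- cfg$construct_mrna_share / (1 - cfg$construct_mrna_share) *
      sum(copies)
    bc <- .build_construct(cfg, cfg$construct_init, cfg$construct_term_eff,
                           cfg$frameshift_fraction)
    models[["construct"]] <- bc$model
    streams[["construct"]] <- bc$streams
    parts[["construct"]] <- bc$parts
    tx_truth[["construct"]] <- data.table(
      id = "construct", type = "frameshift", copies = copies_c,
      init_rate = cfg$construct_init, term_eff = cfg$construct_term_eff)
  }
  if (cfg$include_terminator_locus) {
    c_long <- cfg$terminator_copies * (1 - cfg$terminator_eff)
    c_short <- cfg$terminator_copies - c_long
    seq_b <- .rand_nt(700L)
    models[["term_b"]] <- transcript_model("term_b", "term_locus", "+",
                                           cfg$pad, cfg$pad + 700L,
                                           sequence = seq_b)
    models[["term_a"]] <- transcript_model("term_a", "term_locus", "+",
                                           cfg$pad, cfg$pad + 400L,
                                           sequence = substring(seq_b, 1L, 400L))
    parts[["term"]] <- data.table(
      kind = c("promoter", "terminator"), transcript_id = "term_b",
      start = c(0L, 400L), end = c(1L, 401L),
      start2 = NA_integer_, end2 = NA_integer_)
    tx_truth[["term_a"]] <- data.table(id = "term_a", type = "isoform",
                                       copies = c_short, init_rate = 0,
                                       term_eff = NA_real_)
    tx_truth[["term_b"]] <- data.table(id = "term_b", type = "isoform",
                                       copies = c_long, init_rate = 0,
                                       term_eff = NA_real_)
  }
  ts <- transcript_set(models)
  parts <- rbindlist(parts)
  tx_truth <- rbindlist(tx_truth)

  # ---- ledger: genes, protein masses, proteome totals ----------------------
  cmap <- setNames(tx_truth$copies, tx_truth$id)
  pc <- 1 - cfg$pk_dropoff; fs <- cfg$frameshift_fraction
  genes <- list()
  for (m in ts) {
    for (j in seq_along(m$cds)) {
      x <- m$cds[[j]]
      gene <- if (j == 1L) m$id else paste0(m$id, ".cds", j)
      aa <- .translate_cds(m, j)
      flux <- if (m$id == "construct") {
        if (j == 1L) pc * (1 - fs) * cfg$construct_init
        else pc * fs * cfg$construct_init
      } else tx_truth[id == m$id, init_rate]
      genes[[gene]] <- data.table(
        gene = gene, transcript_id = m$id, a_i = nchar(aa),
        m_i = protein_mass(aa), completing_flux = flux,
        n_i = cmap[[m$id]] * flux * cfg$t_d,
        synth_rate = cmap[[m$id]] * flux)
    }
  }
  genes <- rbindlist(genes)
  m_t <- sum(genes$n_i * genes$m_i)
  q <- 3 * sum(genes$n_i * genes$a_i) / cfg$t_d
  cells <- cell_params(t_d = cfg$t_d, m_t = m_t, n_cells = cfg$n_cells,
                       d_default = cfg$d_rate)

  part_truth <- rbindlist(list(
    tx_truth[type == "regular",
             .(part_id = paste0(id, ":rbs"), kind = "rbs", truth = init_rate)],
    tx_truth[type == "regular",
             .(part_id = paste0(id, ":stop1"), kind = "stop", truth = term_eff)],
    if (cfg$include_frameshift) data.table(
      part_id = c("construct:rbs", "construct:frameshift"),
      kind = c("rbs", "frameshift_ratio"),
      truth = c(cfg$construct_init, fs)),
    if (cfg$include_terminator_locus) data.table(
      part_id = c("term_b:promoter", "term_b:terminator"),
      kind = c("promoter", "terminator"),
      truth = c(cfg$terminator_copies * cfg$d_rate, cfg$terminator_eff))))

  # ---- emission ------------------------------------------------------------
  st <- rbindlist(streams)
  st[, t_c := .psite_codon_time(st$center, st$id, ts, cfg$codon_times)]
  st[, weight := cmap[id] * flux * mult * t_c]
  reads_ribo <- .emit_ribo(st, cfg, ts)
  spike <- .make_spikes(cfg, sum(tx_truth$copies * cfg$n_cells *
                                   vapply(ts, tx_length, numeric(1))[tx_truth$id]))
  reads_rna <- .emit_rna(ts, tx_truth, spike, cfg)

  structure(list(
    transcripts = ts, parts = parts, spikeins = spikein_set(spike),
    cells = cells, reads_ribo = reads_ribo, reads_rna = reads_rna,
    truth = list(transcripts = tx_truth, genes = genes, parts = part_truth,
                 q = q, m_t = m_t),
    streams = st, total_stream_weight = sum(st$weight),
    config = cfg, seed = seed), class = "FluxSim")
}

.translate_cds <- function(m, j) {
  x <- m$cds[[j]]
  s <- substring(m$sequence, x[1] + 1L, x[2])
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
  sub("\\*$", "", aa)
}

# dwell time of the codon occupying the P site (codon spans [center-1,
# center+2) on the transcript axis, whatever the reading frame)
.psite_codon_time <- function(centers, ids, ts, times) {
  seqs <- vapply(ts, function(m) if (is.null(m$sequence)) "" else m$sequence,
                 character(1))
  cod <- substring(seqs[ids], centers, centers + 2L)
  t_c <- times[cod]
  t_c[is.na(t_c)] <- 1
  unname(t_c)
}

.emit_ribo <- function(st, cfg, ts) {
  ref_of <- vapply(ts, `[[`, character(1), "reference")
  tss_of <- vapply(ts, `[[`, integer(1), "tss")
  ref_row <- unname(ref_of[st$id])
  tss_row <- unname(tss_of[st$id])
  counts <- as.vector(rmultinom(1L, cfg$depth_ribo, st$weight))
  idx <- rep.int(seq_len(nrow(st)), counts)
  n <- length(idx)
  len_set <- as.integer(names(cfg$length_probs))
  li <- sample.int(length(len_set), n, replace = TRUE,
                   prob = cfg$length_probs)
  lens <- len_set[li]
  off <- unname(cfg$offsets[as.character(len_set)])[li]
  center_ref <- st$center[idx] + tss_row[idx]
  data.table(reference = ref_row[idx],
             leftmost = as.integer(center_ref + off - lens + 1L),
             length = lens, strand = rep("+", n),
             assay = rep("riboseq", n), mapq_unique = rep(TRUE, n))
}

.make_spikes <- function(cfg, tx_mass) {
  lens <- round(seq(cfg$spike_length_range[1], cfg$spike_length_range[2],
                    length.out = cfg$spike_n))
  mols <- 10^seq(0, cfg$spike_decades, length.out = cfg$spike_n)
  mols <- sample(mols)
  base <- cfg$spike_share / (1 - cfg$spike_share) * tx_mass / sum(mols * lens)
  data.table(id = sprintf("spike_%03d", seq_len(cfg$spike_n)),
             length_nt = as.integer(lens),
             molecules_per_sample = mols * base)
}

.emit_rna <- function(ts, tx_truth, spike, cfg) {
  units <- rbind(
    data.table(reference = vapply(ts, `[[`, character(1), "reference")[tx_truth$id],
               len = vapply(ts, tx_length, numeric(1))[tx_truth$id],
               mol = tx_truth$copies * cfg$n_cells,
               pad = vapply(ts, `[[`, integer(1), "tss")[tx_truth$id]),
    data.table(reference = spike$id, len = as.numeric(spike$length_nt),
               mol = spike$molecules_per_sample, pad = 0L))
  counts <- as.vector(rmultinom(1L, cfg$depth_rna, units$mol * units$len))
  idx <- rep.int(seq_len(nrow(units)), counts)
  n <- length(idx)
  lens <- sample(25:35, n, replace = TRUE)
  mids <- floor(runif(n) * units$len[idx])
  leftmost <- units$pad[idx] + mids - (ceiling(lens / 2) - 1L)
  leftmost <- pmax(leftmost, 0L)
  data.table(reference = units$reference[idx],
             leftmost = as.integer(leftmost), length = lens,
             strand = rep("+", n), assay = rep("rnaseq", n),
             mapq_unique = rep(TRUE, n))
}

#' Analytic expectation tracks for one simulated transcript
#'
#' Closed-form expectations against which the estimators are checked:
#' `N` is the expected raw footprint count per transcript-axis nucleotide at
#' the configured depth, `W` its dwell-weighted version (the same division
#' applied by [weight_coverage()]), and `R` the true translation profile in
#' ribosomes/s: three times the per-copy ribosome flux at each P-site codon
#' center (a ribosome stream of flux r contributes R = 3r at every third
#' nucleotide, so per-nucleotide window means recover r).
#'
#' @param sim a `FluxSim` from [simulate_experiment()].
#' @param id transcript id.
#' @return list of numeric vectors `N`, `W`, `R` over the transcript axis.
#' @export
noiseless_profile <- function(sim, id) {
  m <- sim$transcripts[[id]]
  keep_rows <- which(sim$streams$id == id)
  st <- sim$streams[keep_rows]
  len <- m$length
  N <- W <- R <- numeric(len)
  scale <- sim$config$depth_ribo / sim$total_stream_weight
  N[st$center + 1L] <- N[st$center + 1L] + st$weight * scale
  R[st$center + 1L] <- R[st$center + 1L] + 3 * st$flux
  w <- rep(1, len)
  for (x in m$cds) {
    n_cod <- (x[2] - x[1]) %/% 3L
    cods <- substring(m$sequence, x[1] + 3L * (0:(n_cod - 1L)) + 1L,
                      x[1] + 3L * (0:(n_cod - 1L)) + 3L)
    t_c <- sim$config$codon_times[cods]; t_c[is.na(t_c)] <- 1
    w[(x[1] + 1L):x[2]] <- rep(t_c, each = 3L)
  }
  W <- N / w
  list(N = N, W = W, R = R)
}

#' Write a simulation to disk
#'
#' Emits `annotation.gff3`, `parts.tsv`, `spikeins.tsv`, `ribo_reads.tsv`,
#' `rna_reads.tsv` (position-table dialect), `sequences.fa`,
#' `cell_params.tsv` and the ground-truth ledger tables. Identical seeds
#' give byte-identical files.
#'
#' @param sim a `FluxSim`.
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_annotation(sim$transcripts, p("annotation.gff3"))
  fwrite(sim$parts, p("parts.tsv"), sep = "\t")
  fwrite(sim$spikeins$sheet[, .(id, length_nt, molecules_per_sample)],
         p("spikeins.tsv"), sep = "\t")
  write_position_table(sim$reads_ribo, p("ribo_reads.tsv"))
  write_position_table(sim$reads_rna, p("rna_reads.tsv"))
  by_ref <- split(unclass(sim$transcripts),
                  vapply(sim$transcripts, `[[`, character(1), "reference"))
  seqs <- Biostrings::DNAStringSet(vapply(by_ref, function(ms) {
    m <- ms[[which.max(vapply(ms, `[[`, integer(1), "tes"))]]
    paste0(strrep("N", m$tss), m$sequence)
  }, character(1)))
  Biostrings::writeXStringSet(seqs, p("sequences.fa"))
  fwrite(data.table(t_d = sim$cells$t_d, m_t = sim$cells$m_t,
                    n_cells = sim$cells$n_cells,
                    d_default = sim$cells$d_default),
         p("cell_params.tsv"), sep = "\t")
  fwrite(sim$truth$transcripts, p("ledger_transcripts.tsv"), sep = "\t")
  fwrite(sim$truth$genes, p("ledger_genes.tsv"), sep = "\t")
  fwrite(sim$truth$parts, p("ledger_parts.tsv"), sep = "\t")
  invisible(dir)
}
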