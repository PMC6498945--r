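test_that("simulated P-site offsets are recovered exactly", {
  sim <- simulate_experiment(light_config(include_frameshift = FALSE),
                             seed = 11)
  off <- quiet(calibrate_offsets(sim$reads_ribo, sim$transcripts))
  cfg_off <- sim$config$offsets
  expect_equal(setNames(off$offset, off$length),
               setNames(as.integer(cfg_off), names(cfg_off)))
  expect_true(all(off$support >= 200))
})

test_that("read lengths outside the retention window are excluded", {
  sim <- simulate_experiment(light_config(include_frameshift = FALSE),
                             seed = 12)
  rd <- data.table::copy(sim$reads_ribo)
  extra <- rd[1:500]; extra[, length := 31L]
  off <- quiet(calibrate_offsets(rbind(rd, extra), sim$transcripts))
  expect_false(31L %in% off$length)
})

test_that("modal ties break toward the smaller offset", {
  m <- toy_model(paste0(strrep("A", 30),
                        paste0("ATG", strrep("AAA", 20), "TAA"),
                        strrep("C", 30)), 30L, 30L + 66L)
  ts <- transcript_set(list(m))
  center <- m$stop_codon[1] - 2L            # last sense codon center
  rd <- data.table::data.table(
    reference = "toy",
    leftmost = c(rep(center + 10L - 24L, 5), rep(center + 13L - 24L, 5)),
    length = 25L, strand = "+", assay = "riboseq", mapq_unique = TRUE)
  expect_message(
    off <- quiet2 <- suppressWarnings(
      calibrate_offsets(rd, ts, min_support = 1L)),
    "tie")
  expect_equal(off$offset, 10L)
})

test_that("p_coverage places each read at exactly one nucleotide", {
  m <- toy_model(paste0(strrep("A", 30), "ATG", strrep("AAA", 30), "TAA",
                        strrep("C", 30)), 30L, 30L + 96L)
  ts <- transcript_set(list(m))
  off <- data.table::data.table(length = 25L, offset = 12L, support = 1000L)
  rd <- data.table::data.table(reference = "toy",
                               leftmost = 100L - 12L - 25L + 1L + 12L,
                               length = 25L, strand = "+",
                               assay = "riboseq", mapq_unique = TRUE)
  # p3 = leftmost + 24, center = p3 - 12 = leftmost + 12
  N <- p_coverage(rd, off, ts)
  expect_equal(which(N$values$toy > 0) - 1L, rd$leftmost + 12L)
  expect_equal(sum(N$values$toy), 1)
  # conservation on a simulated set
  sim <- simulate_experiment(light_config(include_frameshift = FALSE),
                             seed = 13)
  offs <- quiet(calibrate_offsets(sim$reads_ribo, sim$transcripts))
  N2 <- p_coverage(sim$reads_ribo, offs, sim$transcripts)
  expect_equal(sum(vapply(N2$values, sum, numeric(1))), N2$n_assigned)
  expect_equal(N2$n_assigned + N2$n_unassigned + N2$n_dropped_length,
               nrow(sim$reads_ribo))
})

test_that("weight_coverage divides by codon dwell times", {
  seqs <- paste0(strrep("G", 6), "ATG", "CCC", "AAA", "TAA", strrep("G", 6))
  m <- toy_model(seqs, 6L, 18L)
  ts <- transcript_set(list(m))
  N <- toy_track(list(toy = c(rep(0, 6), rep(4, 12), rep(0, 6))))
  times <- default_codon_times()
  W <- weight_coverage(N, times, ts)
  expect_equal(W$values$toy, N$values$toy)          # uniform times: W == N
  expect_equal(W$f_t, sum(N$values$toy))
  times["CCC"] <- 2
  W2 <- weight_coverage(N, times, ts)
  expect_equal(W2$values$toy[10:12], rep(2, 3))     # N=4 over t=2
  expect_equal(W2$values$toy[7:9], rep(4, 3))
  N0 <- toy_track(list(toy = rep(0, 24)))
  expect_equal(weight_coverage(N0, times, ts)$values$toy, rep(0, 24))
})

test_that("RPKM/RPM follow the middle-nucleotide rule", {
  m <- toy_model(paste0(strrep("A", 30), "ATG", strrep("AAA", 331), "TAA",
                        strrep("C", 30)), 30L, 30L + 999L)
  # CDS is 999 nt; use length such that formula gives round numbers
  rd <- data.table::data.table(
    reference = "toy", leftmost = rep(200L, 10), length = 25L, strand = "+",
    assay = "riboseq", mapq_unique = TRUE)
  r <- rpkm_rpm(rd, m, total_mapped = 1e6)
  expect_equal(r$count, 10L)
  expect_equal(r$rpkm, 10 / 0.999, tolerance = 1e-12)
  expect_equal(r$rpm, 10)
  # even-length read: the nucleotide 5' of the mid-position decides
  rd_edge <- data.table::data.table(
    reference = "toy", leftmost = 30L - 11L, length = 24L, strand = "+",
    assay = "riboseq", mapq_unique = TRUE)   # 5'-of-mid = 30 = first CDS nt
  expect_equal(rpkm_rpm(rd_edge, m, 1e6)$count, 1L)
  rd_out <- data.table::copy(rd_edge); rd_out$leftmost <- 30L - 12L
  expect_equal(rpkm_rpm(rd_out, m, 1e6)$count, 0L)
  expect_equal(rpkm_rpm(rd[0], m, 1e6)$count, 0L)
  expect_error(rpkm_rpm(rd, m, 0), "zero total")
})

test_that("codon time tables load and normalize", {
  f <- tempfile()
  writeLines(c("codon\ttime", "AAA\t2", "CCC\t0.5"), f)
  t1 <- load_codon_times(f, normalize = FALSE)
  expect_equal(unname(t1["AAA"]), 2)
  expect_equal(unname(t1["GGG"]), 1)
  t2 <- load_codon_times(f, normalize = TRUE)
  sense <- setdiff(names(t2), c("TAA", "TAG", "TGA"))
  expect_equal(mean(t2[sense]), 1)
})
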