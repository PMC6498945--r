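# toy transcript used across the window tests: all-A sequence, CDS [30,120)
# ending in TAA, no out-of-frame stops anywhere
.toy_flat <- function(len = 160L) {
  seq <- paste0(strrep("A", 117), "TAA", strrep("A", len - 120L))
  toy_model(seq, 30L, 120L, rbs_start = 30L)
}

test_that("rbs_windows clips to TSS and to upstream operon stops", {
  m <- .toy_flat()
  # TSS 10 nt upstream of the RBS
  w <- rbs_windows(m, x0 = 10L)
  expect_equal(w$upstream, c(0L, 10L))
  expect_equal(w$qc, "ok")
  # isolated gene, far TSS: full 30-nt window, CDS window drops ramp + stop
  w2 <- rbs_windows(m, x0 = 30L)
  expect_equal(w2$upstream, c(0L, 30L))
  expect_equal(w2$cds, c(81L, 117L))
  # operon: upstream CDS stop inside the window moves the start to stop+9
  op <- transcript_model("op", "op", "+", 0L, 400L,
                         cds = list(c(60L, 162L), c(210L, 330L)))
  w3 <- rbs_windows(op, x0 = 190L, cds_index = 2L)
  expect_equal(w3$upstream, c(171L, 190L))
  # clipping past the RBS start truncates the window
  w4 <- rbs_windows(op, x0 = 165L, cds_index = 2L)
  expect_equal(w4$qc, "window_truncated")
})

test_that("frame corrections match hand evaluation on a toy transcript", {
  # -1-frame stop codon at [53,56); no +1-frame stop at all
  seq <- paste0(strrep("A", 53), "TAA", strrep("A", 61), "TAA")
  m <- toy_model(seq, 30L, 120L, rbs_start = 30L)
  R <- numeric(120)
  R[seq(3L, 27L, 3L) + 1L] <- 1.8        # -1-frame flux 0.6 upstream (R = 3r)
  R[seq(30L, 54L, 3L) + 1L] <- 1.8       # ... continuing to its stop at 56
  R[seq(31L, 115L, 3L) + 1L] <- 3        # in-frame CDS flux 1.0
  w <- rbs_windows(m, x0 = 30L)
  corr <- frame_corrections(R, m, w)
  expect_equal(corr$C_minus, 9 * 1.8 / 30)    # = 0.54, hand sum over window
  expect_equal(corr$C_plus, 0)
  expect_equal(corr$s_minus, 56L)
  expect_equal(corr$s_plus, 120L)             # none found: persists, flagged
  expect_true(corr$flag)
  expect_equal(corr$C(c(40L, 55L)), c(0.54, 0.54))
  expect_equal(corr$C(c(56L, 100L)), c(0, 0))

  # Eq. 2 with corrections is exact here; the naive difference of window
  # means is off by the out-of-frame upstream flux
  est <- rbs_initiation_rate(R, m)
  expect_equal(est$estimate, 1.0, tolerance = 1e-12)
  naive <- mean(R[82:117]) - mean(R[1:30])
  expect_gt(abs(naive - 1.0), abs(est$estimate - 1.0) + 0.5)
})

test_that("rbs initiation rate on flat and step profiles", {
  m <- .toy_flat()
  R <- numeric(160)
  R[82:117] <- 0.7                            # constant CDS flux, empty UTR
  expect_equal(rbs_initiation_rate(R, m)$estimate, 0.7)
  expect_equal(rbs_initiation_rate(rep(0.4, 160), m)$estimate, 0)
  # coverage gate withholds the estimate unless forced
  low <- rbs_initiation_rate(R, m, N_tx = numeric(160), min_rpf = 5)
  expect_equal(low$qc, "low_coverage")
  expect_true(is.na(low$estimate))
  forced <- rbs_initiation_rate(R, m, N_tx = numeric(160), force = TRUE)
  expect_equal(forced$estimate, 0.7)
})

test_that("termination efficiency from window means", {
  m <- .toy_flat()
  R <- numeric(160); R[82:117] <- 1
  expect_equal(termination_efficiency(R, m)$estimate, 1)   # zero downstream
  R2 <- R; R2[121:150] <- 1
  expect_equal(termination_efficiency(R2, m)$estimate, 0)  # no drop
  R3 <- R; R3[121:150] <- 0.026
  expect_equal(termination_efficiency(R3, m)$estimate, 0.974)
  zero <- termination_efficiency(numeric(160), m)
  expect_equal(zero$qc, "low_coverage")
  # downstream window truncates at the next in-frame stop codon
  seq2 <- paste0(strrep("A", 117), "TAA", strrep("A", 12), "TAA",
                 strrep("A", 25))
  m2 <- toy_model(seq2, 30L, 120L)
  r <- termination_efficiency(R3, m2)
  expect_equal(r$window_cds, "[120,132)")
})

test_that("frameshift efficiency returns both readings", {
  R <- numeric(300)
  R[101:160] <- 1; R[171:290] <- 0.03
  regions <- list(xs = 100L, x0 = 160L, x1 = 170L, xe = 290L)
  fe <- frameshift_efficiency(R, regions)
  expect_equal(fe[kind == "frameshift_ratio", estimate], 0.03)
  expect_equal(fe[kind == "frameshift_Fe", estimate], 0.97)
  R2 <- R; R2[171:290] <- 1
  fe2 <- frameshift_efficiency(R2, regions)
  expect_equal(fe2[kind == "frameshift_ratio", estimate], 1)
  expect_equal(fe2[kind == "frameshift_Fe", estimate], 0)
  R3 <- R; R3[171:290] <- 0
  expect_equal(frameshift_efficiency(R3, regions)[kind == "frameshift_ratio",
                                                  estimate], 0)
  und <- frameshift_efficiency(numeric(300), regions)
  expect_equal(unique(und$qc), "low_coverage")
})

test_that("frame fractions sum to one and label correctly", {
  m <- .toy_flat()
  N <- numeric(160)
  N[seq(31L, 115L, 3L) + 1L] <- 5        # all P-sites in frame 0
  ff <- frame_fractions(N, m, region = c(30L, 117L))
  expect_equal(unname(ff), c(1, 0, 0))
  set.seed(1)
  N2 <- rpois(160, 2)
  ff2 <- frame_fractions(N2, m, region = c(30L, 117L))
  expect_equal(sum(ff2), 1)
  expect_true(all(is.na(frame_fractions(numeric(160), m, c(30L, 117L)))))
})

test_that("promoter strength and terminator efficiency read profile steps", {
  Tp <- structure(list(values = list(chr = c(rep(0, 100), rep(0.3, 100))),
                       units = "RNAP/s"), class = "TranscriptionProfile")
  expect_equal(promoter_strength(Tp, "chr", 100L)$estimate, 0.3)
  flat <- structure(list(values = list(chr = rep(0.2, 200)),
                         units = "RNAP/s"), class = "TranscriptionProfile")
  expect_equal(promoter_strength(flat, "chr", 100L)$estimate, 0)
  Tt <- structure(list(values = list(chr = c(rep(1, 100), rep(0.05, 100))),
                       units = "RNAP/s"), class = "TranscriptionProfile")
  expect_equal(terminator_efficiency(Tt, "chr", 100L)$estimate, 0.95)
  # minus strand flips the windows
  expect_equal(terminator_efficiency(Tt, "chr", 100L, strand = "-")$estimate,
               1 - 1 / 0.05)
  expect_equal(terminator_efficiency(Tt, "chr", 100L,
                                     strand = "-")$qc, "out_of_range")
})

test_that("efficiencies outside [0,1] are flagged, never clamped", {
  m <- .toy_flat()
  R <- numeric(160); R[82:117] <- 1; R[121:150] <- 2
  r <- termination_efficiency(R, m)
  expect_lt(r$estimate, 0)
  expect_equal(r$qc, "out_of_range")
})
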