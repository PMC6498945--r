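# shared fixtures: everything is generated in code at test time

# small, fast simulation world for unit-level closed-loop checks
light_config <- function(...) {
  args <- list(n_transcripts = 6L, cds_codons = c(100L, 180L),
               depth_ribo = 2e5, depth_rna = 1e5, copies_decades = c(0, 2))
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# toy transcript on its own reference, plus strand, no padding
toy_model <- function(seq, cds_start, cds_end, id = "toy",
                      rbs_start = NA_integer_) {
  transcript_model(id, id, "+", 0L, nchar(seq),
                   cds = if (is.na(cds_start)) list()
                         else list(c(cds_start, cds_end)),
                   rbs_start = rbs_start, sequence = seq)
}

# coverage track holding one explicit per-reference vector
toy_track <- function(values, assay = "riboseq", weighted = FALSE) {
  structure(list(values = values, assay = assay, weighted = weighted,
                 n_assigned = sum(unlist(values)), n_unassigned = 0L,
                 n_dropped_length = 0L,
                 f_t = if (weighted) sum(unlist(values)) else NULL),
            class = "CoverageTrack")
}

expect_rel <- function(x, y, tol) expect_lt(abs(x / y - 1), tol)
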