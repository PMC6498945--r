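---
title: "Absolute transcription and translation profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute transcription and translation profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Ribosome profiling (Ribo-seq) counts ribosome-protected mRNA footprints at
nucleotide resolution; quantitative RNA-seq with spike-in standards counts
mRNA molecules. Separately, each yields only relative abundances. Combined
with a small set of directly measured cellular parameters — doubling time
`t_d`, total protein mass per cell `m_t`, and cell counts — they can be
converted into two flux tracks in physical units:

* a **translation profile** `R(x)`, the number of ribosomes passing
  nucleotide `x` of a transcript per second (ribosomes/s, per transcript
  copy), and
* a **transcription profile** `T(x)`, the number of RNA polymerases passing
  nucleotide `x` per second (RNAP/s).

Because both are in absolute units, local *changes* in the tracks are
directly interpretable as the strengths of the genetic parts that cause
them: a ribosome binding site (RBS) is a step up in `R`, a stop codon a step
down, a promoter a step up in `T`, a terminator a step down, and a
frameshift element redistributes flux between reading frames.

# From footprints to R(x)

1. **P-site assignment.** Footprints of 23–28 nt are calibrated per read
   length against annotated stop codons: the modal displacement between read
   3' ends and the middle nucleotide of the last sense codon (the P-site
   codon of a terminating ribosome) is that length's offset. The 3' end
   anchors the geometry because the distance from the P site to where the
   mRNA leaves the ribosome is fixed at the 3' side. Each retained read then
   contributes one count at its P-site codon center, giving the raw coverage
   `N(x)` with a reading-frame label.
2. **Dwell-time weighting.** Slow codons accumulate footprints without
   carrying more flux, so `W(x) = N(x) / t_codon(x)` divides out relative
   codon translation times. The shipped default table is uniform; a measured
   table can be supplied (`load_codon_times()`), and weighting with the
   uniform table is the identity.
3. **Absolute scale.** Treating every weighted footprint as one translating
   ribosome that completes its protein, gene-level weighted counts `f_i`
   apportion the measured proteome: `n_i = f_i m_t / (f_t m_i)` protein
   copies per cell, with `m_i` computed from the amino acid sequence using
   average residue masses. Replicating the proteome takes
   `r_t = sum(n_i a_i)` translocations per division, so the cell-wide
   ribosome flux is `q = 3 r_t / t_d` nt/s (1 codon = 3 nt). Finally
   `R(x) = q W(x) / (m_x f_t)`, normalizing by the transcript's copy number
   `m_x` from calibrated RNA-seq.

Two different totals appear here, deliberately. Inside the copy-number
formula `f_t` is the sum over CDSs (`sum(f_i)`), which makes the mass
closure `sum(n_i m_i) = m_t` an exact identity. In `R(x)` the denominator is
the weighted total over *all* assigned positions, so flux carried outside
annotated CDSs (readthrough, recoded frames) still counts against the total.

A useful consequence of P-site counting: a single ribosome stream of flux
`r` puts its P-site centers on every third nucleotide, so the expectation of
`R` is `3r` at those positions and `0` between them, and any window mean
over whole codons recovers `r`. All part models below are window means.

# From calibrated RNA-seq to T(x)

Spike-ins of known molar amounts (92 species, 250–2,000 nt, ~10^6-fold
concentration range) are fragmented and sequenced with the sample, making
expected reads proportional to `molecules x length`. The detection limit is
the lowest RPKM above which spike-in reads/nt are log-log linear in
molecules (slope fixed at 1, `R^2 >= 0.9` over at least 3 spike-ins;
configurable). The slope `k` (reads per nt per molecule) is the pooled
count ratio over the linear subset — the Poisson maximum-likelihood
estimate — and `copies = (reads/length) / k / n_cells`. Estimates below the
detection limit are flagged, never zeroed.

At steady state each transcript's synthesis flux equals its degradation
flux, so `T(x) = sum over covering transcripts of copies_i x d_i`, with
transcript-specific degradation rates where measured and 0.0067/s
otherwise. Where isoforms overlap (a terminator locus), per-transcript copy
counting cannot deconvolve the isoforms, so part readout uses the
per-nucleotide form `T(x) = cov(x) d / (k n_cells)` computed directly from
middle-nucleotide coverage; the two agree wherever transcripts don't
overlap.

# Part models and their windows

All windows are half-open intervals on the transcript's 5'→3' axis and are
reported verbatim with every measurement.

* **RBS initiation rate** `dR`: mean of `R − C` over the CDS window minus
  mean of `R − C⁻ − C⁺` over the 30-nt upstream window. The upstream window
  is clipped at the transcript start site, and inside operons at 9 nt past
  an upstream CDS's stop. The CDS window is `[x_s+51, x_e−3)`: the first 17
  codons are excluded because of the 5' footprint ramp, and the stop triplet
  because it carries no elongating P sites — as printed, the window would
  run to `x_e`, which deflates the mean by one codon and breaks exactness on
  the noiseless expectation track, so the stop is excluded here.
* **Out-of-frame corrections** `C⁻, C⁺`: mean upstream per-nucleotide flux
  sampled at the −1/+1 frame offsets (sums over the frame's P-site positions
  divided by the full window length — the normalization under which
  subtracting the constant from every nucleotide removes that stream's
  contribution to any whole-codon window mean exactly). `C(x)` carries each
  term downstream until that frame's first stop codon; a frame with no stop
  before the transcript end keeps its term and flags the measurement.
* **Termination efficiency** `T_e = 1 − mean R[x1, x1+30) / mean R[x_s+51,
  x0)`. The downstream window is truncated at the next *in-frame* stop
  codon, where readthrough ribosomes terminate. Efficiencies outside [0,1]
  are reported raw with a `qc` flag, never clamped.
* **Frameshift efficiency**: the upstream region is placed directly
  downstream of the stimulating pseudoknot (where pausing no longer distorts
  density); both `F_e = 1 − ratio` and the continuation ratio
  `mean_down/mean_up` are returned — the ratio is the number comparable to a
  "percent of ribosomes frameshifting".
* **Promoter / terminator**: step in `T(x)` across the feature using 30-nt
  flanks (difference for promoters, fractional drop for terminators).

Reporting gates: a measurement needs at least 5 footprints in its averaged
window (`--min-rpf`, mirroring the metagene precedent) and an
above-detection-limit copy number; gated estimates are withheld unless
forced, with `qc` recording why.

# The synthetic world

`simulate_experiment()` draws a steady-state exponential culture and emits
mapped reads for both assays plus a ground-truth ledger, so every estimator
can be tested closed-loop. Stated defaults: 50 transcripts with CDS lengths
of 150–400 codons, copy numbers log-uniform over 4 decades, initiation rates
log-uniform over 0.03–3 ribosomes/s, termination efficiencies drawn from
{0.9, 0.97, 0.99}, footprint lengths 23–28 nt with 3'-anchored offsets of
12–14 nt, an ERCC-like spike-in sheet (92 species, 250–2,000 nt, 6 decades,
~5% of RNA read mass), `t_d = 3000` s (MOPS-glycerol-like growth),
`n_cells = 1e8`, and `m_t` set to the protein mass the stated expression
state implies (which keeps the ledger self-consistent with the mass-closure
identity). Read depths default to 8e6 footprints and 2e6 RNA reads — scaled
down from the tens of millions of reads of a real experiment, but deep
enough that the stated recovery precision (for example T_e to ±0.01 through
a 30-nt window) is achievable for the median gene; this choice was fixed
before the acceptance suite was written.

Realistic dwell features are on by default: a 5' ramp decaying from 2x over
the first 17 codons, a 5x termination pause at the last sense codon (this is
also what makes the stop-codon metagene's modal peak well defined — under
perfectly uniform dwell all upstream codons tie), and a 10x stall at the
pseudoknot. A burden variant (`burden_config()`) additionally drops 85% of
ribosomes at the pseudoknot to emulate a heavily sequestering stall; that
scenario deliberately violates the every-footprint-completes
assumption (partially translated chains carry footprints but no protein
mass), globally deflating rate estimates — the burden phenomenology — and is
therefore excluded from quantitative recovery checks.

Counting noise is multinomial at fixed total depth (Poisson per position
conditioned on the total), which keeps the analytic expectation tracks
(`noiseless_profile()`) exact. The generator does not simulate ribosome
collisions/traffic (initiation is assumed rate-limiting), sequence-level
errors or adapters, library-prep sequence bias, or RNase footprint-boundary
heterogeneity beyond the length mixture. A green closed-loop test therefore
establishes estimator correctness under the stated noise model, not
robustness to those artefacts.

What the dwell features imply for accuracy: ramp and pause positions inflate
`f_t` relative to flux-proportional coverage, deflating all initiation-rate
estimates by a few percent (window ratios such as `T_e` and the frameshift
ratio are immune because the bias cancels). This is a limitation inherent to
the method, and is why the recovery tolerance for initiation rates (±10%
median) is wider than for the ratios.

# Numerical and policy choices

* Coordinates are 0-based half-open everywhere internally; GFF3 is converted
  on load and minus-strand features are flipped to the transcript axis.
* Offset ties break toward the smaller offset, with a logged message.
* Codons containing ambiguous bases weight as 1 with a warning.
* Division-by-zero situations (zero upstream mean, zero mRNA RPKM, zero
  copies under nonzero coverage) yield `NA`/flags or errors rather than
  infinities; empty-after-truncation windows abort the part with a flag.
* `codon_occupancy()` uses raw `N` (dwell weighting would cancel the
  signal), trims 5 codons at each CDS end, and pools only genes with at
  least one footprint per codon on average — in a 4-decade expression world,
  sparsely covered genes contribute gene-normalized shot noise (one read
  becomes a ~20x spike) that drowns the codon signal. The occupancy change
  statistic is a log2 ratio (a declared choice; a difference would conflate
  change with baseline occupancy).
* The Tukey outlier rule (1.5xIQR beyond the quartiles) is applied exactly
  as stated. Note that for ~60 near-continuous change values it flags about
  0.5–1% spurious codons regardless of sequencing depth, so "the perturbed
  codon is the *sole* outlier" is not a reliably achievable event; the
  perturbed codon being the *top-ranked* gainer is.

# Known limitations

* Steady-state exponential growth is assumed throughout; growth transitions
  or induced degradation machinery violate both profiles' interpretations.
* Protein degradation is neglected (a per-gene hook exists but defaults
  off); strongly degraded proteins will have underestimated synthesis flux.
* The P-site model assigns one nucleotide per footprint; A-site effects and
  disomes are out of scope.
* Overlapping genes are excluded from termination and metagene analyses
  rather than deconvolved.
* RNAP elongation speed is not modeled; `T(x)` is a steady-state flux
  balance, not a positional polymerase density.
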