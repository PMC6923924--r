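---
title: "Isoform-level footprint allocation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform-level footprint allocation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ribosome profiling (Ribo-seq) sequences ~30-nt ribosome-protected fragments.
On a transcriptome with alternative isoforms, most footprints fall in exons
shared verbatim between isoforms of a gene and therefore map to several
transcripts equally well. Gene-level analyses side-step this; isoform-level
ribosome abundance and codon-resolution occupancy require deciding, read by
read, which isoform (and which codon) a footprint came from — without using
RNA-seq abundances, whose relationship to ribosome loading is exactly what
one wants to measure (translation efficiency varies by orders of magnitude).

`riboem` estimates both quantities from Ribo-seq alone by iterative
proportional allocation, optionally augmented by a codon-context neural
"shape model", and ships a fully ground-truthed synthetic data generator to
validate the machinery end to end.

## The allocation model

Every read is reduced to a set of candidate `(transcript, P-site codon)`
pairs (the P-site is the 5' end plus a configurable offset, 12 nt by
default; candidates outside the CDS are discarded so that abundance and
profile denominators agree). Reads with identical candidate sets are
compressed into equivalence classes with a multiplicity; allocation on
classes is mathematically identical to per-read allocation.

* **Abundance-only mode** (`method = "abundance"`). Starting from uniform
  CDS-length-normalized abundances `r_i = 1e6 / n`, each iteration assigns a
  read to candidate transcript `i` with weight `r_i / sum(r_k over the
  candidate set)`, then re-estimates
  `r_i = (c_i / l_i) / sum_k (c_k / l_k) * 1e6` from the allocated masses
  `c_i` and CDS lengths `l_i`. If a candidate set has zero total abundance
  the read is split uniformly, so mass is always conserved. This is the
  multinomial-mixture EM familiar from RNA-seq quantification, with CDS
  length entering only through the abundance normalization.
* **Shape-aware mode** (`method = "shape"`). The candidate weight becomes
  `r_i * s_i(codon)`, where `s_i` is the *instructive shape* predicted for
  every CDS codon by a model of local codon context. Each iteration (1)
  allocates under the current abundances and shapes, (2) every
  `retrain_every` iterations rebuilds the shape training set from the
  current allocation, retrains the model from scratch and refreshes all
  shapes, and (3) updates abundances. Retraining from scratch avoids drift
  coupling between refits. The product rule is the minimal combination that
  reduces exactly to the abundance-only mode when `s == 1`; shapes are
  renormalized to mean 1 per transcript so they carry no abundance
  information.
* **Uniform baseline** (`method = "uniform"`). One pass, `1/|candidates|`
  each — the comparator an aligner's "spread multi-mappers evenly" policy
  would produce.

Convergence is declared when the largest abundance change per iteration
falls below `tol` (default 1e-8 of the per-million scale) or at the
iteration cap (default 200). In shape mode the loop never stops on
tolerance while a refit is still scheduled, because a refit changes the
weights even at converged abundances.

## The shape model

The model predicts the normalized occupancy
`x_ij = c_ij / sum_j(c_ij) * l_i` (mean 1 across a CDS of `l_i` codons) at a
codon from the surrounding codon sequence: a window of 121 codons (60 each
side), each codon one of 64 tokens plus a 65th padding token outside the
CDS. Architecture: an embedding-style one-hot convolution, two further 1-D
convolutions (kernel 7, 32 filters, ReLU), a head concatenating the
center-position features with the window-mean features, one fully connected
layer (width 64), and a scalar output that is exponentiated so predictions
are strictly positive. The loss is the squared difference of natural logs,
clipped at 1e-8; any log base only rescales the loss, and the worked
example `loss(e, 1) = 1` fixes the natural-log convention.

Two design points deserve explanation:

* **Center + mean pooling, not global pooling alone.** A single global pool
  over the window discards *which* codon sits at the ribosome position, and
  the dominant biological signal — codon-specific dwell time — lives
  exactly there. The head therefore sees both the center features and the
  window average (the sequence context).
* **Valid convolutions over an extended context.** Each training window
  carries `window + 3*(kernel-1)` tokens so that three valid convolutions
  yield exactly `window` feature positions. Whole-transcript prediction
  pads the token sequence once and slides the same stack, making batched
  training windows and sliding prediction bit-identical — there is no
  train/predict boundary mismatch to reason about.

Training set construction: zero values are discarded; the mean and
population SD of the log targets define a `[mu - 3 sigma, mu + 3 sigma]`
retention range; the range is split into 10 equal bins and each non-empty
bin is resampled to `samples_per_bin` points (with replacement when short),
balancing the log-normal-shaped target distribution. A fraction of *source
positions* is held out before resampling as the validation set: splitting
after resampling would leak duplicated points into validation and defeat
early stopping (we observed exactly this failure, with validation loss an
order of magnitude below the noise floor of the targets). Training uses
Adam (lr 1e-3, batch 128) and stops at the first epoch whose validation
loss exceeds the previous epoch's, keeping the previous weights, or at the
epoch cap. All randomness (initialization, shuffling, split) is seeded.

When the per-bin target count is degenerate (`sigma == 0`), the filter and
binning are skipped and points are drawn uniformly.

## The synthetic data generator

The generator emulates the conditions the method is meant for:

* **Transcriptome**: 300 genes, 1–3 isoforms each, built from 3–5 exon
  blocks of 150–400 nt. At least two exons per gene are constitutive
  (shared verbatim by all isoforms; the `shared_exon_probability`
  parameter, default 0.5, makes further exons constitutive), the rest are
  included per isoform with probability 0.5. Exon lengths are drawn with no
  frame constraint, so roughly two thirds of skipped exons shift the
  reading frame of everything downstream — the scenario in which isoform
  profiles genuinely differ on shared sequence. The CDS spans the
  transcript, trimmed to a codon multiple; every isoform has at least 100
  codons under the defaults. About half of all default-config reads are
  multi-mappable.
* **Abundances**: TPM log-normal (sdlog 1.5, a typical expression
  dispersion), TE log-normal (sdlog 1). Ribosome abundance is proportional
  to TPM × TE, renormalized to parts per million; expected read counts
  follow from CDS length. The stored TE is `r_i / t_i`, i.e. the sampled TE
  rescaled by the constant the renormalization introduces (the family and
  spread are preserved).
* **Occupancy**: one elongation rate per codon identity, log-normal with
  sdlog 0.5, shared transcriptome-wide, so codon identity has a recoverable
  global effect (this is what the Codon Residence Index and the shape model
  should find). Each transcript's profile is the steady state of the
  ribosome flow model (RFM) under those rates with initiation rate 0.02.
  The low initiation rate keeps translation initiation-limited — the
  physiological regime, in which occupancy tracks local dwell time
  (`x_j ≈ flux / lambda_j`) with occasional partial queues upstream of the
  slowest codons, which are natural stalling events. At high initiation the
  RFM instead produces system-wide traffic jams with step-function
  profiles, unlike ribosome-profiling data.
* **Reads**: per transcript, `ribo_count` P-site codons are drawn from the
  profile; each read is the exact 30-nt substring starting 12 nt upstream
  of the P-site. Windows that would leave the transcript are skipped and
  counted (they slightly deplete the first and last few codons). Qualities
  are constant; there is no sequencing-error model, no UTR simulation and
  no paired-end support. RNA-seq is represented by exporting the true TPM
  table rather than simulating reads, since the estimator never consumes
  RNA-seq reads.

What passing tests on this generator do **not** show about real data:
alignment ambiguity from sequencing errors and near-identical paralogs,
length-dependent P-site offsets, UTR and start/stop peaks, library biases,
and rRNA/tRNA contamination (filtering those is an upstream step).

### RFM steady state, numerically

The steady state solves the tridiagonal system
`lambda_{j-1} x_{j-1} (1 - x_j) = lambda_j x_j (1 - x_{j+1})` with
initiation term `lambda_0 (1 - x_1)` and free exit `lambda_n x_n`.
Single-direction shooting on the flux is exponentially ill-conditioned on
long chains (low-density stretches are unstable backward, jammed stretches
forward), and plain Newton stalls on the soft mode of a queue front. The
solver uses pseudo-transient continuation: linearized implicit-Euler steps
`(I/tau - dF/dx) delta = F` via the Thomas algorithm, with the
pseudo-timestep adapted inversely to the residual (switched evolution
relaxation) and pushed up aggressively when the residual stagnates — safe
because the RFM fixed point is globally asymptotically stable. The initial
guess takes the mean-field two-phase profile around the tightest link.
Residual tolerance 1e-10; validated against closed forms
(`x = lambda_0 / (lambda_0 + lambda_1)` for one site) and long-horizon
`deSolve` integration.

## Downstream statistics

* **Translation efficiency**: `TE = r_i / t_i` on matched per-million
  scales; transcripts with zero mRNA abundance are flagged undefined.
* **Stalling**: per transcript, positions strictly above `mu + 2 sigma` of
  the profile, with the population (n-denominator) SD; per-transcript
  statistics because the rule operates on each transcript's normalized
  distribution, strict inequality so a uniform profile yields no calls, and
  scale invariance so raw mass and normalized values agree.
* **Codon Residence Index**: for codon `j` on transcript `i`, the mean
  occupancy over its occurrences divided by the average of those means over
  the synonymous family present on the transcript (including `j`), minus 1.
  Families follow the standard genetic code with the three stop codons
  pooled. Aggregation averages per-transcript CRIs (unweighted; an
  abundance filter `> 10` on both ribosome and mRNA abundance excludes
  transcripts whose per-codon occupancy is unreliable). Condition
  comparison uses a paired two-sided Wilcoxon signed-rank test per codon
  over shared transcripts, with Benjamini–Hochberg adjustment across the 64
  codons (raw p-values are kept; the test is reported `NA` when all paired
  differences are zero or fewer than 5 pairs exist).
* **Evaluation**: against the simulator's *realized* ground truth — the
  per-read true origins — rather than the theoretical RFM profile. This
  isolates allocation error, the quantity the allocator controls; at desk
  scale the multinomial sampling gap between the theoretical profile and
  any read-level reconstruction would otherwise dominate every comparison.

## Problem sizes and runtime choices

Desk-scale defaults keep the full pipeline on one CPU core in minutes: 300
genes (~480 isoforms, median CDS ~290 codons), 2e5 reads, shape-model
training at `samples_per_bin = 2000` (10 bins, so ~18k training windows per
refit after the validation holdout), 32 filters, epoch cap 5 inside the
loop, and a shape loop of 10 iterations with a refit every 2, warm-started
from the 200-iteration abundance-only fit. The abundance-only fit takes
seconds; each shape refit is tens of seconds, dominated by the
convolutions. Larger filter counts, windows, deeper training or a refit
every iteration are straightforward configuration changes
(`shape_control()`) when more hardware or patience is available.

## Known limitations

* The shape model's benefit depends on how much of the transcriptome is
  multi-mapped and how strong codon-dwell heterogeneity is. With ~50%
  unique-mapping reads (the default generator) the abundance-only and
  shape-aware fits reconstruct profiles almost equally well; under heavy
  multi-mapping (~10% unique, as in a real human transcriptome) the
  shape-aware fit is distinctly better — the regime the method was designed
  for.
* On a *single* gene the shape model can memorize the current (mixed)
  allocation and reinforce it; its disambiguation power comes from
  transferring codon-dwell patterns learned transcriptome-wide. Users
  should not expect it to unmix isolated two-isoform toys.
* The exact mapper is exact-match only; real data should be aligned
  externally (transcriptome-space SAM/BAM with secondary records retained)
  and imported with `load_alignments()`.
* CRI values are per-transcript statistics of *normalized* occupancy; they
  are comparable across conditions only after the same abundance filtering.
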