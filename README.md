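# riboem

Isoform-level ribosome abundance and codon-resolution ribosome occupancy
from Ribo-seq alone.

## The problem

Ribosome profiling reads are ~30-nt fragments, and on transcriptomes with
alternative splicing most of them fall in exons shared verbatim between
isoforms of a gene — they map to several transcripts equally well. Deciding
where each footprint came from is the whole game for isoform-level
translation analysis, and borrowing RNA-seq abundances to decide is
circular when translation efficiency itself is the quantity of interest.

`riboem` resolves multi-mapped footprints by iterative proportional
allocation. With `c_i` the (fractional) read mass allocated to transcript
`i` and `l_i` its CDS length, the CDS-length-normalized ribosome abundance
is

    r_i = (c_i / l_i) / sum_k (c_k / l_k) * 1e6

(the Ribo-seq analogue of TPM). Each iteration splits a read over its
candidate `(transcript, P-site codon)` set with weight proportional to
`r_i` — optionally times an *instructive shape* `s_i(codon)`, a positive
per-codon factor predicted by a small convolutional network from the 121
codons around the position — and then re-estimates `r_i` from the allocated
masses. The shape model is retrained during the iteration from the data
being processed, so frame shifts between isoforms (a shared exon read in
different frames) can pull the allocation apart where a pure abundance
split cannot. Downstream statistics include translation efficiency
(`TE = r_i / t_i` against mRNA TPM `t_i`), ribosomal stalling calls
(profile values strictly above `mu + 2 sigma` per transcript), and the
Codon Residence Index

    CRI_ij = mean occupancy of codon j on transcript i
             / mean over j's synonymous family (present on i)  -  1

with paired Wilcoxon comparison of CRI between conditions.

A self-contained simulator generates ground-truthed data reproducing the
intended conditions: multi-isoform genes with shared exons (some
frame-shifting), log-normal TPM and TE, ribosome-flow-model occupancy
profiles driven by per-codon elongation rates, and error-free 30-nt
footprints with known P-sites.

## Worked example

Simulate a small dataset, map the reads, fit abundances, and evaluate
against the simulator's ground truth:

```r
library(riboem)
cfg <- sim_config(n_genes = 30, n_ribo_reads = 2e4, seed = 7)
sim <- simulate_riboseq(cfg)
aln <- map_reads_exact(sim$reads, sim$transcriptome, psite_offset = 12)
aln
#> read_alignments: 19,407 reads mapped (0 dropped), 4180 equivalence classes
#>   unique-mapping fraction: 51.5%

fit <- ribofit(aln, sim$transcriptome, method = "abundance", iters = 200)
fit
#> ribofit (method = "abundance"): 53 transcripts, 19,407 reads allocated
#>   iterations: 200; final max |delta r|/1e6 = 3.41e-06

evaluate_allocation(fit, sim$truth_table, sim$transcriptome)
#> evaluation vs ground truth (method = "abundance")
#>   count PCC: 0.9998   count MSE: 490.6
#>   length-normalized abundance PCC: 0.9997
#>   profile PCC: mean 0.7798; 50.9% of 53 isoforms > 0.9
#>   stalling: sensitivity 66.5%, precision 75.9% (723 true, 634 called)
```

Per-transcript counts are recovered almost perfectly (count PCC is the
correlation between estimated and true reads per transcript); per-codon
profile fidelity is read-depth-limited at this scale. Adding the shape
model (`method = "shape"`, typically warm-started with `init = fit`)
refines within-transcript allocation; `method = "uniform"` gives the naive
equal-split baseline.

Translation efficiency and codon dwell statistics:

```r
tpm <- setNames(sim$truth$table$tpm, sim$truth$table$transcript_id)
head(translation_efficiency(coef(fit), tpm), 3)
#>   transcript_id      ribo       rna        te undefined
#> 1       G0001.1  3813.682  6769.401 0.5633706     FALSE
#> 2       G0002.1 39863.676 27109.709 1.4704575     FALSE
#> 3       G0002.2  5751.753  3834.609 1.4999580     FALSE

aggregate_cri(fit, sim$transcriptome, coef(fit), tpm)
#> cri_table: 52 transcripts
#>   fastest codons (lowest mean CRI):
#>  codon family  n   mean_cri
#>    GTA      V 50 -0.5790525
#>    CGC      R 46 -0.5477047
#>    TAG      * 45 -0.5361043
#>   slowest codons (highest mean CRI):
#>  codon family  n  mean_cri
#>    CGA      R 48 0.6265963
#>    GCC      A 42 0.7188774
#>    ACC      T 48 0.7759486
```

A positive CRI means the ribosome dwells longer on that codon than on its
synonyms; in this simulation the recovered slow/fast codons track the
planted per-codon elongation rates.

Real data enter through `load_transcriptome()` (FASTA + CDS annotation as
TSV or GTF) and `load_alignments()` (transcriptome-space SAM/BAM with
secondary records retained; leading soft clips shift the 5' end before the
P-site offset). A command-line wrapper with `simulate`, `fit` and `analyze`
subcommands is installed at `inst/cli/riboem`.

The TSV annotation dialect is a header line plus one row per transcript:
`transcript_id  gene_id  cds_start  cds_end`, with 0-based half-open CDS
coordinates in transcript space.

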