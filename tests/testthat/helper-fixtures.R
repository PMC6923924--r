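# Small fixtures built in code; used across test files.

# two-gene toy transcriptome with a shared exon between isoforms of gene A
toy_txome <- function() {
  exon1 <- "ATGGCTGCCGCTAAAGGT"            # 18 nt
  exon2 <- "TTTCCCGGGAAACGCGTGTAC"         # 21 nt
  exon3 <- "GATTACAGATTACAGATTACA"         # 21 nt
  seqs <- c(
    A.1 = paste0(exon1, exon2, exon3),     # 60 nt, 20 codons
    A.2 = paste0(exon1, exon3),            # 39 nt, 13 codons
    B.1 = "ATGAAACCCGGGTTTACGTGGTGCTAA"    # 27 nt, 9 codons
  )
  tx <- data.frame(transcript_id = names(seqs), gene_id = c("A", "A", "B"),
                   cds_start = 0L, cds_end = nchar(seqs),
                   stringsAsFactors = FALSE)
  transcriptome(tx, seqs)
}

# minimal transcriptome from explicit sequences (whole-sequence CDS)
txome_from_seqs <- function(seqs, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- names(seqs)
  tx <- data.frame(transcript_id = names(seqs), gene_id = gene_ids,
                   cds_start = 0L,
                   cds_end = nchar(seqs) - nchar(seqs) %% 3L,
                   stringsAsFactors = FALSE)
  transcriptome(tx, seqs)
}

random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
        collapse = "")
}

# small simulation shared by several tests (cheap but non-trivial)
small_sim <- function(seed = 7, n_genes = 30, n_reads = 2e4) {
  simulate_riboseq(sim_config(n_genes = n_genes, n_ribo_reads = n_reads,
                              seed = seed))
}

# brute-force substring scan: all exact occurrences of `read` in transcripts
brute_force_hits <- function(read, txome) {
  out <- NULL
  for (i in seq_len(nrow(txome$tx))) {
    s <- txome$seq[i]
    L <- nchar(read)
    if (nchar(s) < L) next
    starts <- which(vapply(seq_len(nchar(s) - L + 1L),
                           function(p) substr(s, p, p + L - 1L) == read,
                           logical(1))) - 1L
    if (length(starts))
      out <- rbind(out, data.frame(tx = i, pos = starts))
  }
  out
}
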