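#' Simulation configuration
#'
#' Bundles the parameters of the synthetic Ribo-seq generator: a multi-isoform
#' transcriptome with verbatim-shared exons (so that multi-mapping reads
#' exist, and some shared exons are read in different frames by different
#' isoforms), log-normal transcript abundances and translation efficiencies,
#' ribosome-flow-model (RFM) codon occupancy profiles driven by a
#' transcriptome-wide codon-identity rate table, and error-free 30-nt
#' footprint reads with known P-sites.
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene integer range `c(min, max)` of isoforms drawn per
#'   gene.
#' @param exons_per_gene integer range of exon counts per gene.
#' @param exon_length_range exon length range in nt; lengths are drawn
#'   uniformly with no frame constraint, so roughly two thirds of
#'   skipped-exon junctions shift the reading frame between isoforms.
#' @param shared_exon_probability probability that an exon is constitutive
#'   (present in every isoform); at least one exon per gene is always
#'   constitutive so isoforms share sequence verbatim.
#' @param tpm_meanlog,tpm_sdlog log-scale parameters of the transcript
#'   abundance (TPM) distribution.
#' @param te_meanlog,te_sdlog log-scale parameters of the translation
#'   efficiency distribution.
#' @param n_ribo_reads total number of Ribo-seq footprints to emit.
#' @param read_length footprint length in nt.
#' @param rfm_initiation_rate RFM initiation rate, relative to the geometric
#'   mean elongation rate of 1. The default keeps translation
#'   initiation-limited (the physiological regime), so occupancy is locally
#'   proportional to codon dwell time rather than dominated by traffic jams.
#' @param rfm_codon_rate_sigma log-scale spread of the per-codon-identity
#'   elongation rates; 0 makes all codons equally fast.
#' @param psite_offset nt from footprint 5' end to the P-site nucleotide.
#' @param seed integer seed; stage `k` of the generator uses `seed + k` so
#'   each stage is reproducible in isolation.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 300,
                       isoforms_per_gene = c(1L, 3L),
                       exons_per_gene = c(3L, 5L),
                       exon_length_range = c(150L, 400L),
                       shared_exon_probability = 0.5,
                       tpm_meanlog = 0, tpm_sdlog = 1.5,
                       te_meanlog = 0, te_sdlog = 1,
                       n_ribo_reads = 2e5,
                       read_length = 30L,
                       rfm_initiation_rate = 0.02,
                       rfm_codon_rate_sigma = 0.5,
                       psite_offset = 12L,
                       seed = 42L) {
  cfg <- list(n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length_range = as.integer(exon_length_range),
              shared_exon_probability = shared_exon_probability,
              tpm_meanlog = tpm_meanlog, tpm_sdlog = tpm_sdlog,
              te_meanlog = te_meanlog, te_sdlog = te_sdlog,
              n_ribo_reads = as.integer(n_ribo_reads),
              read_length = as.integer(read_length),
              rfm_initiation_rate = rfm_initiation_rate,
              rfm_codon_rate_sigma = rfm_codon_rate_sigma,
              psite_offset = as.integer(psite_offset),
              seed = as.integer(seed))
  stopifnot(cfg$n_genes > 0, cfg$n_ribo_reads > 0, cfg$read_length >= 3L,
            cfg$shared_exon_probability >= 0, cfg$shared_exon_probability <= 1,
            cfg$rfm_initiation_rate > 0, cfg$rfm_codon_rate_sigma >= 0,
            cfg$psite_offset >= 0, cfg$tpm_sdlog >= 0, cfg$te_sdlog >= 0,
            length(cfg$isoforms_per_gene) == 2L, length(cfg$exons_per_gene) == 2L,
            all(cfg$isoforms_per_gene >= 1L), all(cfg$exons_per_gene >= 1L),
            all(cfg$exon_length_range >= 9L))
  structure(cfg, class = "sim_config")
}

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Generate a synthetic multi-isoform transcriptome
#'
#' Genes are built from exon blocks; each isoform concatenates the gene's
#' constitutive exons plus a random subset of the optional ones, so isoforms
#' of a gene share at least one exon verbatim. The CDS spans the transcript,
#' trimmed at the 3' end to a whole number of codons. Duplicate isoform
#' structures within a gene are dropped.
#'
#' @param config a [sim_config].
#' @return a [transcriptome]; the attribute `"isoform_exons"` records, per
#'   gene, the exon lengths and the exon-inclusion matrix of its isoforms.
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rows <- vector("list", config$n_genes)
  seqs <- character(0)
  meta <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("G%04d", g)
    n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
    ex_len <- sample(config$exon_length_range[1]:config$exon_length_range[2],
                     n_ex, replace = TRUE)
    exons <- vapply(ex_len, rand_seq, character(1))
    constitutive <- stats::runif(n_ex) < config$shared_exon_probability
    # at least two constitutive exons: guarantees verbatim-shared sequence
    # between isoforms and keeps every isoform's CDS in the intended
    # 100-600-codon range under the default exon lengths
    need <- min(n_ex, 2L)
    while (sum(constitutive) < need)
      constitutive[sample(which(!constitutive), 1L)] <- TRUE
    n_iso <- sample(config$isoforms_per_gene[1]:config$isoforms_per_gene[2], 1L)
    inc <- matrix(FALSE, n_iso, n_ex)
    for (i in seq_len(n_iso)) {
      inc[i, ] <- constitutive | (stats::runif(n_ex) < 0.5)
    }
    inc <- unique(inc)
    for (i in seq_len(nrow(inc))) {
      tid <- sprintf("%s.%d", gene_id, i)
      s <- paste(exons[inc[i, ]], collapse = "")
      cds_end <- nchar(s) - nchar(s) %% 3L
      rows[[length(seqs) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = gene_id,
        cds_start = 0L, cds_end = cds_end, stringsAsFactors = FALSE)
      seqs[tid] <- s
    }
    meta[[g]] <- list(gene_id = gene_id, exon_lengths = ex_len,
                      constitutive = constitutive, inclusion = inc)
  }
  out <- transcriptome(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
                       seqs)
  attr(out, "isoform_exons") <- meta
  out
}

#' Sample per-transcript ground-truth abundances
#'
#' Transcript abundances (TPM) and translation efficiencies are drawn
#' log-normally; ribosome abundance is proportional to their product and
#' renormalized to parts-per-million. Expected footprint counts follow from
#' CDS length: `c_ri = round(n_ribo_reads * r_i l_ri / sum(r_k l_rk))`.
#' The stored `te` column is `ribo_abundance / tpm`, i.e. the sampled TE
#' rescaled by the constant that the per-million renormalization of ribosome
#' abundance introduces (still log-normal with the configured spread).
#'
#' @param txome a [transcriptome].
#' @param config a [sim_config].
#' @return `ground_truth` object: data.frame with columns `transcript_id`,
#'   `tpm`, `te`, `ribo_abundance`, `ribo_count`; occupancy profiles are
#'   filled in by [simulate_profiles()].
#' @export
sample_ground_truth <- function(txome, config = sim_config()) {
  stopifnot(inherits(txome, "transcriptome"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(txome$tx)
  tpm <- stats::rlnorm(n, config$tpm_meanlog, config$tpm_sdlog)
  tpm <- tpm / sum(tpm) * 1e6
  te_raw <- sample_te(n, config)
  r <- tpm * te_raw
  r <- r / sum(r) * 1e6
  l_r <- txome$tx$cds_length
  cnt <- round(config$n_ribo_reads * (r * l_r) / sum(r * l_r))
  gt <- data.frame(transcript_id = txome$tx$transcript_id,
                   tpm = tpm, te = r / tpm, ribo_abundance = r,
                   ribo_count = as.integer(cnt), stringsAsFactors = FALSE)
  structure(list(table = gt, profiles = NULL, codon_rates = NULL),
            class = "ground_truth")
}

#' @rdname sample_ground_truth
#' @param n number of draws.
#' @return for `sample_te`: raw log-normal TE draws (before the per-million
#'   renormalization that couples TE to the transcriptome-wide mean).
#' @export
sample_te <- function(n, config = sim_config()) {
  stats::rlnorm(n, config$te_meanlog, config$te_sdlog)
}

#' Ribosome flow model steady state
#'
#' Site densities of the ribosome flow model with dynamics
#' `dx_j/dt = lambda_{j-1} x_{j-1} (1 - x_j) - lambda_j x_j (1 - x_{j+1})`,
#' initiation term `lambda_0 (1 - x_1)` and free exit `lambda_n x_n`. The
#' steady state (the globally stable fixed point of the relaxation dynamics)
#' is found by integrating the dynamics for a burn-in and polishing with
#' damped Newton iterations on the tridiagonal steady-state system.
#'
#' @param rates positive rates `lambda_0..lambda_n` (initiation first, then
#'   one elongation rate per codon site).
#' @param tol residual tolerance: `max_j |dx_j/dt|` at the solution.
#' @param max_iter maximum relaxation/Newton rounds before failing.
#' @return numeric vector of site densities in (0,1), with the steady-state
#'   flux in attribute `"flux"`.
#' @examples
#' rfm_steady_state(c(1, 1))     # x = 0.5
#' rfm_steady_state(c(1, 3))     # x = lambda_0/(lambda_0+lambda_1) = 0.25
#' @export
rfm_steady_state <- function(rates, tol = 1e-10, max_iter = 20L) {
  stopifnot(is.numeric(rates), length(rates) >= 2L)
  if (any(rates <= 0)) stop("all rates must be positive")
  cpp_rfm_solve(as.numeric(rates), tol, as.integer(max_iter))
}

#' Fill in ground-truth codon occupancy profiles
#'
#' One elongation rate per codon identity is drawn log-normally (so codon
#' identity has a transcriptome-wide effect on dwell time); each transcript's
#' occupancy profile is the RFM steady state under those rates, normalized to
#' sum to 1 over its CDS codons.
#'
#' @param txome a [transcriptome].
#' @param truth a `ground_truth` from [sample_ground_truth()] (or `NULL` to
#'   return profiles alone).
#' @param config a [sim_config].
#' @return the `ground_truth` with `profiles` (list of per-codon probability
#'   vectors, named by transcript) and `codon_rates` (named length-64 vector)
#'   filled in.
#' @export
simulate_profiles <- function(txome, truth = NULL, config = sim_config()) {
  stopifnot(inherits(txome, "transcriptome"))
  set.seed(config$seed + 2L)
  rates <- stats::rlnorm(64L, 0, config$rfm_codon_rate_sigma)
  names(rates) <- CODONS
  profs <- vector("list", nrow(txome$tx))
  names(profs) <- txome$tx$transcript_id
  # identical CDS -> identical profile; cache by codon-index key
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(txome$tx))) {
    cod <- txome$codons[[i]]
    key <- paste(cod, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) { profs[[i]] <- hit; next }
    lam <- rates[cod + 1L]
    lam[is.na(lam)] <- 1.0  # N-containing codons elongate at the mean rate
    x <- rfm_steady_state(c(config$rfm_initiation_rate, lam))
    p <- as.numeric(x) / sum(x)
    profs[[i]] <- p
    cache[[key]] <- p
  }
  if (is.null(truth)) {
    truth <- structure(list(table = NULL, profiles = NULL, codon_rates = NULL),
                       class = "ground_truth")
  }
  truth$profiles <- profs
  truth$codon_rates <- rates
  truth
}

#' Generate synthetic footprint reads
#'
#' For each transcript, `ribo_count` P-site codons are drawn from its
#' occupancy profile; each read is the exact `read_length`-nt substring whose
#' 5' end lies `psite_offset` nt upstream of the P-site nucleotide. Reads
#' whose window would leave the transcript are skipped and counted.
#'
#' @param txome a [transcriptome].
#' @param truth a `ground_truth` with profiles filled in.
#' @param config a [sim_config].
#' @param fastq optional path; when given, reads are written as FASTQ
#'   (gzipped if the path ends in `.gz`) with constant quality strings.
#' @return list with `reads` (character vector), `truth_table` (data.frame
#'   `read_id`, `transcript_id`, `codon`, the true origin of every emitted
#'   read), `n_skipped` (reads lost to transcript-edge clipping), and
#'   `n_skipped_tx` (transcripts shorter than the read length, skipped
#'   entirely).
#' @export
simulate_footprints <- function(txome, truth, config = sim_config(), fastq = NULL) {
  stopifnot(inherits(txome, "transcriptome"), inherits(truth, "ground_truth"),
            !is.null(truth$profiles), !is.null(truth$table))
  set.seed(config$seed + 3L)
  tx <- txome$tx
  gt <- truth$table
  stopifnot(identical(gt$transcript_id, tx$transcript_id))
  rl <- config$read_length
  off <- config$psite_offset
  too_short <- tx$length < rl
  if (any(too_short & gt$ribo_count > 0L))
    warning(sum(too_short & gt$ribo_count > 0L),
            " transcript(s) shorter than the read length skipped")
  reads_l <- vector("list", nrow(tx))
  tx_l <- vector("list", nrow(tx))
  cod_l <- vector("list", nrow(tx))
  n_skipped <- 0L
  for (i in seq_len(nrow(tx))) {
    ci <- gt$ribo_count[i]
    if (ci <= 0L || too_short[i]) next
    prof <- truth$profiles[[i]]
    cnt <- as.integer(stats::rmultinom(1L, ci, prof))
    codons <- rep.int(seq_along(cnt) - 1L, cnt)  # 0-based codon index
    start <- tx$cds_start[i] + 3L * codons - off  # 0-based 5' end
    keep <- start >= 0L & (start + rl) <= tx$length[i]
    n_skipped <- n_skipped + sum(!keep)
    if (!any(keep)) next
    start <- start[keep]
    reads_l[[i]] <- substring(txome$seq[i], start + 1L, start + rl)
    cod_l[[i]] <- codons[keep]
    tx_l[[i]] <- rep.int(tx$transcript_id[i], sum(keep))
  }
  reads <- unlist(reads_l, use.names = FALSE)
  if (is.null(reads)) reads <- character(0)
  ids <- sprintf("r%07d", seq_along(reads))
  truth_table <- data.frame(read_id = ids,
                            transcript_id = unlist(tx_l, use.names = FALSE),
                            codon = unlist(cod_l, use.names = FALSE),
                            stringsAsFactors = FALSE)
  if (!is.null(fastq)) {
    con <- if (grepl("\\.gz$", fastq)) gzfile(fastq, "w") else file(fastq, "w")
    on.exit(close(con))
    qual <- strrep("I", rl)
    writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  }
  list(reads = reads, truth_table = truth_table, n_skipped = n_skipped,
       n_skipped_tx = sum(too_short & gt$ribo_count > 0L))
}

#' Export ground-truth transcript abundances as an RNA-seq style TPM table
#'
#' The generator is Ribo-seq only; for translation-efficiency analysis the
#' true transcript abundances are exported directly in the `(transcript_id,
#' tpm)` format an RNA-seq quantifier would produce.
#'
#' @param truth a `ground_truth`.
#' @param path optional TSV path to write.
#' @return data.frame with columns `transcript_id`, `tpm` (invisibly when
#'   written to file).
#' @export
rnaseq_abundance <- function(truth, path = NULL) {
  stopifnot(inherits(truth, "ground_truth"), !is.null(truth$table))
  out <- truth$table[, c("transcript_id", "tpm")]
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Run the full synthetic pipeline
#'
#' Convenience wrapper: transcriptome, ground truth, profiles, footprints.
#'
#' @param config a [sim_config].
#' @param fastq optional FASTQ output path passed to [simulate_footprints()].
#' @return list with `transcriptome`, `truth` (profiles filled), `reads`,
#'   `truth_table`, `n_skipped`.
#' @export
simulate_riboseq <- function(config = sim_config(), fastq = NULL) {
  txome <- simulate_transcriptome(config)
  truth <- sample_ground_truth(txome, config)
  truth <- simulate_profiles(txome, truth, config)
  fp <- simulate_footprints(txome, truth, config, fastq = fastq)
  list(transcriptome = txome, truth = truth, reads = fp$reads,
       truth_table = fp$truth_table, n_skipped = fp$n_skipped)
}

#' Per-codon pileup of true read origins
#'
#' Turns a truth table (true transcript and P-site codon per read) into the
#' flat per-codon count vector used as the realized ground-truth profile.
#'
#' @param truth_table data.frame with `transcript_id` and `codon` columns.
#' @param txome a [transcriptome].
#' @return numeric vector of length `sum(n_codons)` in flat codon order (all
#'   codons of transcript 1, then transcript 2, ...).
#' @export
codon_pileup <- function(truth_table, txome) {
  stopifnot(inherits(txome, "transcriptome"))
  co <- codon_offsets(txome)
  ti <- match(truth_table$transcript_id, txome$tx$transcript_id)
  if (anyNA(ti)) stop("truth table contains unknown transcripts")
  flat <- co$offset[ti] + truth_table$codon + 1L
  as.numeric(tabulate(flat, nbins = co$total))
}
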