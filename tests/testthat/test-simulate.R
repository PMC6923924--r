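test_that("RFM closed forms hold for a single site", {
  x <- rfm_steady_state(c(1, 1))
  expect_equal(as.numeric(x), 0.5, tolerance = 1e-9)
  x <- rfm_steady_state(c(1, 3))
  expect_equal(as.numeric(x), 0.25, tolerance = 1e-9)  # lambda0/(lambda0+lambda1)
  expect_error(rfm_steady_state(c(1, -1)), "positive")
})

test_that("RFM steady state matches long-horizon ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  for (rates in list(c(0.5, 2, 1, 0.3, 1.5, 0.8),
                     c(0.02, exp(rnorm(5, 0, 0.5))),
                     c(2, exp(rnorm(5, 0, 1))))) {
    n <- length(rates) - 1
    deriv <- function(t, x, parms) {
      xm <- c(1, x[-n]); xp <- c(x[-1], 0)
      list(rates[1:n] * xm * (1 - x) - rates[2:(n + 1)] * x * (1 - xp))
    }
    ode <- deSolve::ode(y = rep(0.5, n), times = c(0, 5000), func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    x_ode <- as.numeric(ode[2, -1])
    x <- as.numeric(rfm_steady_state(rates))
    expect_equal(x, x_ode, tolerance = 1e-6)
    expect_true(all(x > 0 & x < 1))
    # flux balance across every link
    flux <- c(rates[1] * (1 - x[1]),
              if (n > 1) rates[2:n] * x[1:(n - 1)] * (1 - x[2:n]),
              rates[n + 1] * x[n])
    expect_lt(max(abs(flux - mean(flux))), 1e-8)
  }
})

test_that("transcriptome generator builds shared-exon isoform families", {
  cfg <- sim_config(n_genes = 20, isoforms_per_gene = c(2L, 2L),
                    shared_exon_probability = 1, seed = 3)
  txo <- simulate_transcriptome(cfg)
  # shared_exon_probability 1 makes all exons constitutive; duplicate isoform
  # structures collapse, so genes may keep a single isoform
  meta <- attr(txo, "isoform_exons")
  expect_true(all(vapply(meta, function(m) all(m$constitutive), logical(1))))

  cfg2 <- sim_config(n_genes = 40, seed = 5)
  txo2 <- simulate_transcriptome(cfg2)
  expect_true(all(txo2$tx$cds_length %% 3 == 0))
  expect_true(all(txo2$tx$n_codons >= 100))
  n_iso <- lengths(txo2$genes)
  expect_true(all(n_iso >= 1 & n_iso <= 3))
  # determinism
  txo3 <- simulate_transcriptome(cfg2)
  expect_identical(txo2$seq, txo3$seq)
  # multi-isoform genes share at least one exon verbatim: a read-length
  # window from a constitutive exon occurs in every isoform
  meta2 <- attr(txo2, "isoform_exons")
  for (m in meta2[1:10]) {
    ids <- txo2$genes[[m$gene_id]]
    if (length(ids) < 2) next
    con <- which(m$constitutive)[1]
    # constitutive exon sequence is a substring of every isoform
    first <- txo2$seq[match(ids[1], txo2$tx$transcript_id)]
    offs <- cumsum(c(0, m$exon_lengths))[con] + 1
    probe <- substr(first, offs, offs + min(30, m$exon_lengths[con]) - 1)
    # locate the constitutive exon within isoform 1 via its inclusion row
    inc1 <- m$inclusion[1, ]
    start1 <- sum(m$exon_lengths[seq_len(con - 1)][inc1[seq_len(con - 1)]]) + 1
    probe <- substr(first, start1, start1 + min(30, m$exon_lengths[con]) - 1)
    for (id in ids)
      expect_true(grepl(probe, txo2$seq[match(id, txo2$tx$transcript_id)],
                        fixed = TRUE))
  }
})

test_that("ground truth obeys the stated normalizations", {
  sim <- small_sim()
  gt <- sim$truth$table
  expect_equal(sum(gt$tpm), 1e6, tolerance = 1e-6)
  expect_equal(sum(gt$ribo_abundance), 1e6, tolerance = 1e-6)
  expect_equal(gt$te, gt$ribo_abundance / gt$tpm, tolerance = 1e-12)
  # counts conserve the read budget up to rounding
  expect_lt(abs(sum(gt$ribo_count) - 2e4), nrow(gt) / 2 + 1)
  # recomputing r from counts via the length-normalized formula agrees to
  # rounding error
  txo <- sim$transcriptome
  r2 <- length_normalized_abundance(gt$ribo_count, txo$tx$cds_length)
  expect_gt(cor(r2, gt$ribo_abundance), 0.999)
})

test_that("equal TE makes ribosome abundance equal transcript abundance", {
  cfg <- sim_config(n_genes = 15, te_sdlog = 0, seed = 9)
  txo <- simulate_transcriptome(cfg)
  gt <- sample_ground_truth(txo, cfg)$table
  expect_equal(gt$ribo_abundance, gt$tpm, tolerance = 1e-9)
})

test_that("log TE draws follow the configured normal distribution", {
  cfg <- sim_config(te_meanlog = 0.5, te_sdlog = 1.2, seed = 2)
  set.seed(123)
  te <- sample_te(10000, cfg)
  ks <- ks.test(log(te), "pnorm", 0.5, 1.2)
  expect_gt(ks$p.value, 0.01)
})

test_that("profiles are normalized, deterministic and near-uniform when rates are flat", {
  cfg <- sim_config(n_genes = 5, rfm_codon_rate_sigma = 0, seed = 21)
  txo <- simulate_transcriptome(cfg)
  pr <- simulate_profiles(txo, config = cfg)
  for (p in pr$profiles) expect_equal(sum(p), 1, tolerance = 1e-9)
  # all codon rates equal: total variation from uniform is small
  p <- pr$profiles[[which.max(txo$tx$n_codons)]]
  tv <- 0.5 * sum(abs(p - 1 / length(p)))
  expect_lt(tv, 0.05)
  # identical CDS -> identical profiles
  seqs <- c(a = random_cds(120, seed = 4), b = random_cds(120, seed = 4))
  txo2 <- txome_from_seqs(seqs)
  cfg2 <- sim_config(seed = 21)
  pr2 <- simulate_profiles(txo2, config = cfg2)
  expect_identical(pr2$profiles[["a"]], pr2$profiles[["b"]])
})

test_that("footprints are exact substrings with P-sites drawn from the profile", {
  sim <- small_sim()
  txo <- sim$transcriptome
  # spot-check substring identity
  idx <- sample(nrow(sim$truth_table), 200)
  for (k in idx) {
    row <- sim$truth_table[k, ]
    i <- match(row$transcript_id, txo$tx$transcript_id)
    start <- txo$tx$cds_start[i] + 3 * row$codon - 12
    expect_identical(sim$reads[k],
                     substr(txo$seq[i], start + 1, start + 30))
  }
  # read-mass conservation: truth rows == reads == sum(counts) - skipped
  expect_identical(nrow(sim$truth_table), length(sim$reads))
  expect_identical(length(sim$reads) + sim$n_skipped,
                   as.integer(sum(sim$truth$table$ribo_count)))

  # empirical P-site frequencies track the profile (single-transcript
  # fixture; enough flanking sequence that no read window is clipped)
  seqs <- c(t1 = random_cds(24, seed = 11))  # 72 nt
  tx <- data.frame(transcript_id = "t1", gene_id = "g", cds_start = 24L,
                   cds_end = 24L + 30L, stringsAsFactors = FALSE)
  txo1 <- transcriptome(tx, seqs)
  cfg <- sim_config(n_genes = 1, seed = 13)
  truth <- structure(list(
    table = data.frame(transcript_id = "t1", tpm = 1e6, te = 1,
                       ribo_abundance = 1e6, ribo_count = 100000L),
    profiles = list(t1 = rep(c(0.05, 0.15), 5)), codon_rates = NULL),
    class = "ground_truth")
  fp <- simulate_footprints(txo1, truth, cfg)
  emp <- tabulate(fp$truth_table$codon + 1L, nbins = 10) / nrow(fp$truth_table)
  expect_lt(0.5 * sum(abs(emp - truth$profiles$t1)), 0.01)
})

test_that("FASTQ output is byte-stable under a fixed seed", {
  cfg <- sim_config(n_genes = 5, n_ribo_reads = 500, seed = 31)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  simulate_riboseq(cfg, fastq = f1)
  simulate_riboseq(cfg, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  # RNA-seq abundance export: conserved and identical to truth
  sim <- simulate_riboseq(cfg)
  tab <- rnaseq_abundance(sim$truth)
  expect_equal(sum(tab$tpm), 1e6, tolerance = 1e-6)
  expect_identical(tab$tpm, sim$truth$table$tpm)
})

test_that("a sizeable fraction of default-config reads is multi-mappable", {
  sim <- small_sim()
  aln <- map_reads_exact(sim$reads, sim$transcriptome, 12)
  expect_gt(1 - aln$unique_fraction, 0.30)
})
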