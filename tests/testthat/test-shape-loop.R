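test_that("shape-weighted allocation reduces to plain allocation when s is 1", {
  sim <- small_sim(seed = 53, n_genes = 12, n_reads = 4000)
  txo <- sim$transcriptome
  aln <- map_reads_exact(sim$reads, txo, 12)
  r <- initialize_uniform(txo)
  co <- riboem:::codon_offsets(txo)
  s1 <- rep(1, co$total)
  a <- allocate_reads(aln, txo, r)
  b <- allocate_reads(aln, txo, r, shapes = s1)
  expect_identical(a$codon_mass, b$codon_mass)
})

test_that("shape values tilt candidate weights proportionally", {
  txo <- txome_from_seqs(c(a = random_cds(100, seed = 1),
                           b = random_cds(100, seed = 2)),
                         gene_ids = c("g", "g"))
  aln <- structure(list(cls = c(1L, 1L), tx = c(1L, 2L), codon = c(4L, 9L),
                        count = 1, size = 2L, n_reads = 1, n_mapped = 1,
                        n_unmapped = 0L, unique_fraction = 0,
                        transcript_ids = txo$tx$transcript_id),
                   class = "read_alignments")
  r <- c(a = 5e5, b = 5e5)
  co <- riboem:::codon_offsets(txo)
  s <- rep(1, co$total)
  s[co$offset[1] + 5] <- 2   # codon 4 of a
  s[co$offset[2] + 10] <- 1  # codon 9 of b
  al <- allocate_reads(aln, txo, r, shapes = s)
  expect_equal(unname(al$tx_mass), c(2 / 3, 1 / 3))
  expect_equal(sum(al$tx_mass), 1)
})

test_that("the shape loop without retraining equals the abundance-only loop bit for bit", {
  sim <- small_sim(seed = 59, n_genes = 10, n_reads = 3000)
  aln <- map_reads_exact(sim$reads, sim$transcriptome, 12)
  fa <- ribofit(aln, sim$transcriptome, method = "abundance", iters = 15)
  # retrain interval beyond the iteration count: shapes stay uniform (NULL)
  fs <- ribofit(aln, sim$transcriptome, method = "shape", iters = 15,
                shape = shape_control(retrain_every = 100L), seed = 1)
  expect_identical(fa$codon_mass, fs$codon_mass)
  expect_identical(fa$abundance$mass, fs$abundance$mass)
  expect_identical(fa$abundance$abundance, fs$abundance$abundance)
})

test_that("mass is conserved through shape-aware iterations", {
  sim <- small_sim(seed = 61, n_genes = 10, n_reads = 3000)
  aln <- map_reads_exact(sim$reads, sim$transcriptome, 12)
  ctl <- shape_control(window = 21, n_filters = 8, hidden = 16,
                       samples_per_bin = 200, epochs = 2, retrain_every = 2)
  fit <- ribofit(aln, sim$transcriptome, method = "shape", iters = 4,
                 shape = ctl, seed = 3)
  expect_equal(sum(fit$codon_mass), aln$n_mapped, tolerance = 1e-8)
  expect_equal(sum(fit$abundance$mass), aln$n_mapped, tolerance = 1e-8)
  expect_equal(sum(fit$abundance$abundance), 1e6, tolerance = 1e-6)
  # shapes exist, are positive, and average one per transcript
  expect_true(all(fit$shapes > 0))
  co <- riboem:::codon_offsets(sim$transcriptome)
  tx_of <- rep.int(seq_along(co$n), co$n)
  means <- tapply(fit$shapes, tx_of, mean)
  expect_equal(unname(as.numeric(means)), rep(1, length(co$n)),
               tolerance = 1e-9)
})

test_that("predicted shapes correlate positively with true occupancy", {
  sim <- small_sim(seed = 67)
  txo <- sim$transcriptome
  aln <- map_reads_exact(sim$reads, txo, 12)
  fit <- ribofit(aln, txo, method = "abundance", iters = 100)
  ts <- build_training_set(fit, txo, samples_per_bin = 1000, seed = 5)
  m <- train_shape_model(ts, shape_control(epochs = 4), seed = 5)
  s <- predict(m, txome = txo)
  xtrue <- lapply(sim$truth$profiles, function(p) p * length(p))
  rho <- cor(unlist(s), unlist(xtrue), method = "spearman")
  expect_gt(rho, 0)
})

test_that("frame-shifted shared exons are disambiguated better with shapes", {
  # Many genes whose two isoforms share a long tail exon read in shifted
  # frames (the skipped middle exon is 100 nt, not a multiple of 3). The
  # codon-dwell signal is learned from the whole transcriptome and
  # transferred to the shared exons, where the abundance-only allocator can
  # only split reads at a constant per-gene ratio.
  set.seed(83)
  mk <- function() {
    exA <- paste(sample(c("A", "C", "G", "T"), 240, replace = TRUE),
                 collapse = "")
    exB <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                 collapse = "")
    exS <- paste(sample(c("A", "C", "G", "T"), 450, replace = TRUE),
                 collapse = "")
    c(paste0(exA, exS), paste0(exA, exB, exS))
  }
  n_genes <- 25
  seqs <- character(0); gids <- character(0)
  for (g in seq_len(n_genes)) {
    p <- mk()
    seqs[paste0("g", g, ".1")] <- p[1]
    seqs[paste0("g", g, ".2")] <- p[2]
    gids <- c(gids, rep(paste0("g", g), 2))
  }
  txo <- txome_from_seqs(seqs, gene_ids = gids)
  cfg <- sim_config(n_genes = n_genes, n_ribo_reads = 60000, seed = 85,
                    rfm_codon_rate_sigma = 1.2)
  n <- nrow(txo$tx)
  set.seed(86)
  tpm <- rlnorm(n, 0, 1); tpm <- tpm / sum(tpm) * 1e6
  r <- tpm * rlnorm(n, 0, 1); r <- r / sum(r) * 1e6
  cnt <- as.integer(round(60000 * r * txo$tx$cds_length /
                            sum(r * txo$tx$cds_length)))
  truth <- structure(list(
    table = data.frame(transcript_id = txo$tx$transcript_id, tpm = tpm,
                       te = r / tpm, ribo_abundance = r, ribo_count = cnt),
    profiles = NULL, codon_rates = NULL), class = "ground_truth")
  truth <- simulate_profiles(txo, truth, cfg)
  fp <- simulate_footprints(txo, truth, cfg)
  aln <- map_reads_exact(fp$reads, txo, 12)
  prime <- ribofit(aln, txo, method = "abundance", iters = 100)
  shape <- ribofit(aln, txo, method = "shape", iters = 6, init = prime,
                   shape = shape_control(samples_per_bin = 1000, epochs = 5,
                                         retrain_every = 2),
                   seed = 7)
  evp <- evaluate_allocation(prime, fp$truth_table, txo)
  evs <- evaluate_allocation(shape, fp$truth_table, txo)
  expect_gt(mean(evs$profile_pcc), mean(evp$profile_pcc))

  # non-proportionality: where the true within-gene split of shared-exon
  # positions departs from the gene's overall ratio, the shape-aware fit
  # must track the true split better than the constant-ratio allocation
  co <- riboem:::codon_offsets(txo)
  true_flat <- codon_pileup(fp$truth_table, txo)
  pairs <- which(aln$size == 2L)
  rows <- aln$cls %in% pairs
  d <- data.frame(cls = aln$cls[rows], tx = aln$tx[rows],
                  codon = aln$codon[rows])
  byc <- split(d, d$cls)
  byc <- Filter(function(z) nrow(z) == 2 && z$tx[1] %% 2 == 1 &&
                  z$tx[2] == z$tx[1] + 1, byc)  # isoform pair of one gene
  lr <- function(mass) {
    vapply(byc, function(z) {
      f <- co$offset[z$tx] + z$codon + 1L
      log((mass[f[1]] + 0.5) / (mass[f[2]] + 0.5))
    }, numeric(1))
  }
  truth_lr <- lr(true_flat)
  keep <- is.finite(truth_lr)
  cor_prime <- cor(lr(prime$codon_mass)[keep], truth_lr[keep])
  cor_shape <- cor(lr(shape$codon_mass)[keep], truth_lr[keep])
  expect_gt(cor_shape, cor_prime)
})
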