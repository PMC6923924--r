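#' Length-normalized per-million abundance
#'
#' `v_i = (c_i / l_i) / sum_k (c_k / l_k) * 1e6` — TPM when applied to
#' RNA-seq counts and transcript lengths, CDS-length-normalized ribosome
#' abundance when applied to footprint counts and CDS lengths.
#'
#' @param counts non-negative counts.
#' @param lengths positive lengths (nt).
#' @return per-million values summing to 1e6.
#' @export
length_normalized_abundance <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths > 0))
  if (all(counts <= 0)) stop("all-zero counts")
  dens <- counts / lengths
  dens / sum(dens) * 1e6
}

#' Translation efficiency
#'
#' `TE = r_i / t_i`: per-million ribosome abundance over per-million
#' transcript abundance, matched by transcript id. Transcripts with zero (or
#' missing) mRNA abundance are flagged undefined and excluded from summaries.
#'
#' @param ribo named vector or data.frame (`transcript_id`, value) of
#'   CDS-length-normalized ribosome abundances.
#' @param rna named vector or data.frame (`transcript_id`, value) of TPM.
#' @return data.frame of class `te_result` with columns `transcript_id`,
#'   `ribo`, `rna`, `te`, `undefined`.
#' @export
translation_efficiency <- function(ribo, rna) {
  r <- as_named(ribo); t <- as_named(rna)
  ids <- intersect(names(r), names(t))
  if (length(ids) == 0L) stop("no shared transcript ids")
  r <- r[ids]; t <- t[ids]
  undef <- !is.finite(t) | t <= 0
  te <- ifelse(undef, NA_real_, r / t)
  structure(data.frame(transcript_id = ids, ribo = unname(r), rna = unname(t),
                       te = unname(te), undefined = unname(undef),
                       stringsAsFactors = FALSE),
            class = c("te_result", "data.frame"))
}

as_named <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2L)
    structure(as.numeric(x[[2L]]), names = as.character(x[[1L]]))
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
}

#' Detect ribosomal stalling positions in one profile
#'
#' Positions whose value strictly exceeds `mu + 2 sigma`, with `mu` and
#' `sigma` the mean and population (n-denominator) standard deviation of the
#' transcript's profile. Scale-invariant, so raw allocated mass and
#' normalized values give the same calls; a uniform (or all-zero) profile
#' yields none.
#'
#' @param x per-codon profile of one transcript (length >= 2).
#' @return list with `positions` (0-based codon indices), `mu`, `sigma`.
#' @export
detect_stalling <- function(x) {
  stopifnot(length(x) >= 2L)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  list(positions = which(x > mu + 2 * sigma) - 1L, mu = mu, sigma = sigma)
}

#' Stalling calls for a whole fit or profile set
#'
#' @param profiles a `ribofit`, or a named list of per-codon profiles.
#' @return data.frame (`transcript_id`, `codon_index`) of called positions,
#'   0-based codon indices.
#' @export
stalling_sites <- function(profiles) {
  if (inherits(profiles, "ribofit")) profiles <- ribo_profile(profiles)
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  out <- lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    if (length(p) < 2L || sum(p) <= 0) return(NULL)
    pos <- detect_stalling(p)$positions
    if (length(pos) == 0L) return(NULL)
    data.frame(transcript_id = id, codon_index = pos, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(transcript_id = character(0), codon_index = integer(0))
  out
}

# synonymous family (amino acid, stops pooled) per codon index 0..63
codon_family <- function() {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[CODONS])
}

#' Codon Residence Index of one transcript
#'
#' For each codon identity present on the transcript, the mean normalized
#' occupancy over its occurrences is divided by the average of those means
#' across the codon's synonymous family (restricted to codons present on the
#' transcript, the codon itself included), minus 1. Positive values mean the
#' ribosome dwells longer on that codon than on its synonyms;
#' single-member families give exactly 0. Invariant to rescaling the whole
#' profile.
#'
#' @param x per-codon profile values of one transcript.
#' @param codons 0-based codon indices of the CDS (same length as `x`).
#' @return data.frame with `codon_index`, `codon`, `family` (amino acid, `*`
#'   for stops), `n` (occurrences), `mean_x`, `cri` (`NA` when the family's
#'   occupancy is all zero).
#' @export
compute_cri <- function(x, codons) {
  stopifnot(length(x) == length(codons))
  ok <- !is.na(codons)
  x <- x[ok]; codons <- codons[ok]
  if (length(x) == 0L) stop("no valid codons")
  fam <- codon_family()
  m <- tapply(x, codons, mean)
  idx <- as.integer(names(m))
  n <- as.integer(table(codons))
  f <- fam[idx + 1L]
  fam_mean <- tapply(m, f, mean)[f]
  cri <- ifelse(fam_mean > 0, m / fam_mean - 1, NA_real_)
  data.frame(codon_index = idx, codon = CODONS[idx + 1L], family = f,
             n = n, mean_x = as.numeric(m), cri = as.numeric(cri),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate CRI across transcripts
#'
#' Computes per-transcript CRIs ([compute_cri()]) on normalized profiles for
#' transcripts whose length-normalized ribosome and mRNA abundances both
#' strictly exceed `min_abundance` (low-coverage transcripts have unreliable
#' per-codon occupancy), then averages per codon across transcripts.
#'
#' @param profiles a `ribofit`, or a named list of per-codon mass vectors.
#' @param txome the [transcriptome] (codon sequences).
#' @param ribo,rna named per-million abundance vectors (or 2-column
#'   data.frames); `rna = NULL` filters on ribosome abundance alone.
#' @param min_abundance abundance filter (default 10).
#' @param condition optional label carried through to comparisons.
#' @return object of class `cri_table`: list with `per_transcript` (64 x n
#'   matrix of CRIs, `NA` where undefined), `summary` (data.frame
#'   `codon_index`, `codon`, `family`, `n`, `mean_cri`), `condition`.
#' @export
aggregate_cri <- function(profiles, txome, ribo, rna = NULL,
                          min_abundance = 10, condition = NA_character_) {
  if (inherits(profiles, "ribofit")) profiles <- ribo_profile(profiles)
  stopifnot(inherits(txome, "transcriptome"))
  r <- as_named(ribo)
  ids <- names(profiles)
  pass <- ids[ids %in% names(r)[r > min_abundance]]
  if (!is.null(rna)) {
    t <- as_named(rna)
    pass <- pass[pass %in% names(t)[t > min_abundance]]
  }
  pass <- pass[vapply(profiles[pass], sum, numeric(1)) > 0]
  mat <- matrix(NA_real_, 64L, length(pass),
                dimnames = list(CODONS, pass))
  for (id in pass) {
    p <- normalize_profile(profiles[[id]])
    cri <- compute_cri(p, cds_codons(txome, id))
    mat[cri$codon_index + 1L, id] <- cri$cri
  }
  if (length(pass) == 0L)
    warning("no transcript passes the abundance filter")
  n <- rowSums(!is.na(mat))
  mean_cri <- ifelse(n > 0, rowMeans(mat, na.rm = TRUE), NA_real_)
  fam <- codon_family()
  structure(list(per_transcript = mat,
                 summary = data.frame(codon_index = 0:63, codon = CODONS,
                                      family = fam, n = as.integer(n),
                                      mean_cri = as.numeric(mean_cri),
                                      stringsAsFactors = FALSE),
                 condition = condition),
            class = "cri_table")
}

#' @export
print.cri_table <- function(x, ...) {
  cat("cri_table", if (!is.na(x$condition)) paste0(" (", x$condition, ")"),
      ": ", ncol(x$per_transcript), " transcripts\n", sep = "")
  s <- x$summary[!is.na(x$summary$mean_cri), ]
  s <- s[order(s$mean_cri), ]
  if (nrow(s)) {
    cat("  fastest codons (lowest mean CRI):\n")
    print(utils::head(s[, c("codon", "family", "n", "mean_cri")], 3),
          row.names = FALSE)
    cat("  slowest codons (highest mean CRI):\n")
    print(utils::tail(s[, c("codon", "family", "n", "mean_cri")], 3),
          row.names = FALSE)
  }
  invisible(x)
}

#' Compare CRI between two conditions
#'
#' Per codon, a paired two-sided Wilcoxon signed-rank test over the
#' transcripts present in both conditions' CRI tables; p-values are
#' Benjamini-Hochberg adjusted across codons (raw p-values are also
#' returned). Codons with fewer than `min_pairs` complete pairs, or with all
#' differences zero (the degenerate identical-conditions case), are reported
#' as `NA` and flagged.
#'
#' @param a,b `cri_table` objects from [aggregate_cri()].
#' @param min_pairs minimum complete pairs per codon (default 5).
#' @return data.frame with `codon_index`, `codon`, `n_pairs`,
#'   `median_delta` (b minus a), `p`, `q`, `skipped`.
#' @export
compare_cri_conditions <- function(a, b, min_pairs = 5L) {
  stopifnot(inherits(a, "cri_table"), inherits(b, "cri_table"))
  shared <- intersect(colnames(a$per_transcript), colnames(b$per_transcript))
  p <- rep(NA_real_, 64L)
  npairs <- integer(64L)
  meddelta <- rep(NA_real_, 64L)
  for (j in seq_len(64L)) {
    va <- a$per_transcript[j, shared]
    vb <- b$per_transcript[j, shared]
    ok <- !is.na(va) & !is.na(vb)
    npairs[j] <- sum(ok)
    if (npairs[j] < min_pairs) next
    d <- vb[ok] - va[ok]
    meddelta[j] <- stats::median(d)
    if (all(d == 0)) next  # degenerate: no nonzero differences
    p[j] <- suppressWarnings(
      stats::wilcox.test(vb[ok], va[ok], paired = TRUE,
                         alternative = "two.sided")$p.value)
  }
  q <- rep(NA_real_, 64L)
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  data.frame(codon_index = 0:63, codon = CODONS, n_pairs = npairs,
             median_delta = meddelta, p = p, q = q,
             skipped = npairs < min_pairs, stringsAsFactors = FALSE)
}

pearson_or_na <- function(x, y) {
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  stats::cor(x, y)
}

#' Evaluate a fit against simulation ground truth
#'
#' Compares estimated per-transcript read counts and abundances, per-codon
#' profiles, and stalling calls with the realized ground truth (the true
#' read origins recorded by the simulator).
#'
#' @param fit a `ribofit`.
#' @param truth_table the simulator's truth table (`read_id`,
#'   `transcript_id`, `codon`).
#' @param txome the [transcriptome].
#' @return object of class `ribo_eval`: list with `count_pcc`, `count_mse`,
#'   `abundance_pcc` (CDS-length-normalized scale), `profile_pcc` (named
#'   per-transcript vector, transcripts with true reads), `mean_profile_pcc`,
#'   `frac_pcc_gt_0.9`, `stalling` (list `sensitivity`, `precision`,
#'   `n_true`, `n_called`).
#' @export
evaluate_allocation <- function(fit, truth_table, txome) {
  stopifnot(inherits(fit, "ribofit"), inherits(txome, "transcriptome"))
  co <- codon_offsets(txome)
  true_flat <- codon_pileup(truth_table, txome)
  tx_of <- rep.int(seq_along(co$n), co$n)
  true_counts <- flat_rowsum(true_flat, tx_of, length(co$n))
  est_counts <- fit$abundance$mass

  count_pcc <- pearson_or_na(est_counts, true_counts)
  count_mse <- mean((est_counts - true_counts)^2)
  r_true <- length_normalized_abundance(true_counts, txome$tx$cds_length)
  abundance_pcc <- pearson_or_na(fit$abundance$abundance, r_true)

  has_reads <- which(true_counts > 0)
  ppcc <- vapply(has_reads, function(i) {
    rng <- (co$offset[i] + 1L):(co$offset[i] + co$n[i])
    pearson_or_na(fit$codon_mass[rng], true_flat[rng])
  }, numeric(1))
  names(ppcc) <- txome$tx$transcript_id[has_reads]

  true_prof <- split(true_flat, tx_of)
  names(true_prof) <- txome$tx$transcript_id
  true_calls <- stalling_sites(true_prof[has_reads])
  est_calls <- stalling_sites(fit)
  key <- function(d) paste(d$transcript_id, d$codon_index)
  overlap <- sum(key(est_calls) %in% key(true_calls))
  stalling <- list(
    sensitivity = if (nrow(true_calls)) overlap / nrow(true_calls) else NA_real_,
    precision = if (nrow(est_calls)) overlap / nrow(est_calls) else NA_real_,
    n_true = nrow(true_calls), n_called = nrow(est_calls))

  structure(list(count_pcc = count_pcc, count_mse = count_mse,
                 abundance_pcc = abundance_pcc,
                 profile_pcc = ppcc,
                 mean_profile_pcc = mean(ppcc, na.rm = TRUE),
                 frac_pcc_gt_0.9 = mean(ppcc > 0.9, na.rm = TRUE),
                 stalling = stalling, method = fit$method),
            class = "ribo_eval")
}

#' @export
print.ribo_eval <- function(x, ...) {
  cat("evaluation vs ground truth (method = \"", x$method, "\")\n", sep = "")
  cat(sprintf("  count PCC: %.4f   count MSE: %.1f\n", x$count_pcc, x$count_mse))
  cat(sprintf("  length-normalized abundance PCC: %.4f\n", x$abundance_pcc))
  cat(sprintf("  profile PCC: mean %.4f; %.1f%% of %d isoforms > 0.9\n",
              x$mean_profile_pcc, 100 * x$frac_pcc_gt_0.9,
              length(x$profile_pcc)))
  cat(sprintf("  stalling: sensitivity %.1f%%, precision %.1f%% (%d true, %d called)\n",
              100 * x$stalling$sensitivity, 100 * x$stalling$precision,
              x$stalling$n_true, x$stalling$n_called))
  invisible(x)
}
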