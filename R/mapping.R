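#' P-site codon index for a footprint 5' end
#'
#' Applies the P-site offset rule: the P-site nucleotide is
#' `five_prime_pos + offset` (0-based transcript coordinates); if it falls
#' inside the half-open CDS interval the 0-based codon index
#' `(n - cds_start) %/% 3` is returned, otherwise `NA` (out-of-CDS sentinel).
#'
#' @param txome a [transcriptome].
#' @param transcript_id transcript identifier(s), recycled against
#'   `five_prime_pos`.
#' @param five_prime_pos 0-based position of the read's 5' end.
#' @param offset P-site offset in nt (default 12, standard 30-nt footprint
#'   geometry); may be a per-read vector for length-dependent offset rules.
#' @return integer codon indices, `NA` where the P-site lies outside the CDS.
#' @export
psite_codon <- function(txome, transcript_id, five_prime_pos, offset = 12L) {
  stopifnot(inherits(txome, "transcriptome"))
  i <- match(transcript_id, txome$tx$transcript_id)
  if (anyNA(i)) stop("unknown transcript id")
  n <- five_prime_pos + offset
  ok <- n >= txome$tx$cds_start[i] & n < txome$tx$cds_end[i]
  out <- rep(NA_integer_, length(n))
  out[ok] <- as.integer((n[ok] - txome$tx$cds_start[i][ok]) %/% 3L)
  out
}

# Compress per-candidate rows (read index, transcript index, 0-based codon)
# into equivalence classes: reads with identical candidate sets share a class
# and a multiplicity. Allocation on classes is mathematically identical to
# per-read allocation and much cheaper.
build_alignment_classes <- function(read, tx, codon, read_mult, n_reads_total,
                                    n_unmapped, txome) {
  o <- order(read, tx, codon)
  read <- read[o]; tx <- tx[o]; codon <- codon[o]
  dup <- duplicated(data.frame(read, tx, codon))
  read <- read[!dup]; tx <- tx[!dup]; codon <- codon[!dup]
  key <- vapply(split(paste(tx, codon, sep = ":"), read),
                paste, character(1), collapse = ";")
  ureads <- as.integer(names(key))
  cls_of_read <- match(key, unique(key))
  n_cls <- max(cls_of_read)
  count <- as.numeric(tapply(read_mult[ureads], cls_of_read, sum))
  rep_read <- ureads[match(seq_len(n_cls), cls_of_read)]
  keep <- read %in% rep_read
  r2 <- read[keep]
  cls_row <- cls_of_read[match(r2, ureads)]
  o2 <- order(cls_row)
  cls_row <- cls_row[o2]
  tx_row <- tx[keep][o2]
  codon_row <- codon[keep][o2]
  size <- as.integer(tabulate(cls_row, nbins = n_cls))
  mapped <- sum(count)
  structure(list(cls = cls_row, tx = tx_row, codon = codon_row,
                 count = count, size = size,
                 n_reads = n_reads_total, n_mapped = mapped,
                 n_unmapped = n_unmapped,
                 unique_fraction = sum(count[size == 1L]) / mapped,
                 transcript_ids = txome$tx$transcript_id),
            class = "read_alignments")
}

#' @export
print.read_alignments <- function(x, ...) {
  cat("read_alignments: ", format(x$n_mapped, big.mark = ","), " reads mapped (",
      x$n_unmapped, " dropped), ", length(x$count), " equivalence classes\n",
      sep = "")
  cat(sprintf("  unique-mapping fraction: %.1f%%\n", 100 * x$unique_fraction))
  invisible(x)
}

#' Exact multi-mapping of footprint reads to a transcriptome
#'
#' Finds every exact occurrence of each read in any transcript sequence (a
#' desk-scale stand-in for an external transcriptome aligner; synthetic reads
#' are error-free substrings). Occurrences are converted to P-site codon
#' candidates with [psite_codon()]; candidates whose P-site falls outside the
#' CDS are discarded, and reads with no remaining candidate are dropped and
#' counted. Reads containing N never match.
#'
#' @param reads character vector of read sequences, or a FASTQ(.gz) path.
#' @param txome a [transcriptome].
#' @param psite_offset P-site offset in nt.
#' @return a `read_alignments` object: per-read candidate sets compressed
#'   into equivalence classes, plus mapping statistics.
#' @export
map_reads_exact <- function(reads, txome, psite_offset = 12L) {
  stopifnot(inherits(txome, "transcriptome"))
  if (length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  reads <- toupper(as.character(reads))
  n_total <- length(reads)
  if (n_total == 0L) stop("no reads")
  u <- unique(reads)
  mult <- tabulate(match(reads, u), nbins = length(u))

  cand_read <- integer(0); cand_tx <- integer(0); cand_pos <- integer(0)
  for (L in sort(unique(nchar(u)))) {
    sel <- which(nchar(u) == L)
    usel <- u[sel]
    kl <- vector("list", nrow(txome$tx))
    for (i in seq_len(nrow(txome$tx))) {
      len <- txome$tx$length[i]
      if (len >= L) kl[[i]] <- substring(txome$seq[i], 1:(len - L + 1L), L:len)
    }
    nk <- lengths(kl)
    m <- match(unlist(kl, use.names = FALSE), usel)
    hit <- which(!is.na(m))
    if (length(hit)) {
      all_tx <- rep.int(seq_along(nk), nk)
      off0 <- rep.int(c(0L, cumsum(nk))[seq_along(nk)], nk)
      cand_read <- c(cand_read, sel[m[hit]])
      cand_tx <- c(cand_tx, all_tx[hit])
      cand_pos <- c(cand_pos, hit - off0[hit] - 1L)  # 0-based 5' position
    }
  }
  # P-site conversion and CDS restriction
  n <- cand_pos + psite_offset
  cs <- txome$tx$cds_start[cand_tx]; ce <- txome$tx$cds_end[cand_tx]
  ok <- n >= cs & n < ce
  cand_read <- cand_read[ok]; cand_tx <- cand_tx[ok]
  cand_codon <- as.integer((n[ok] - cs[ok]) %/% 3L)
  mapped_reads <- unique(cand_read)
  n_unmapped <- as.integer(sum(mult) - sum(mult[mapped_reads]))
  if (length(cand_read) == 0L) stop("no read mapped inside any CDS")
  build_alignment_classes(cand_read, cand_tx, cand_codon, mult,
                          n_total, n_unmapped, txome)
}

#' Import transcriptome-space alignments from SAM/BAM
#'
#' Every mapped sense-strand record (primary and secondary) becomes one
#' candidate. Leading soft clips shift the 5' end before the P-site offset is
#' applied; reverse-strand records are discarded (Ribo-seq transcriptome
#' alignments are sense); records on references absent from the transcriptome
#' are skipped with a warning. Candidates with out-of-CDS P-sites are
#' dropped, and reads left with no candidate are counted as unmapped.
#'
#' @param path a SAM or BAM file with alignments to transcript references.
#' @param txome a [transcriptome].
#' @param psite_offset P-site offset in nt, or a named vector mapping read
#'   length (as character) to offset for length-dependent rules.
#' @return a `read_alignments` object.
#' @export
load_alignments <- function(path, txome, psite_offset = 12L) {
  stopifnot(inherits(txome, "transcriptome"), file.exists(path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq")))[[1]]
  flag <- b$flag
  keep <- !bitwAnd(flag, 4L) & !bitwAnd(flag, 16L)  # mapped, forward strand
  qname <- b$qname[keep]
  rname <- as.character(b$rname[keep])
  pos <- b$pos[keep]
  cigar <- b$cigar[keep]
  rlen <- nchar(as.character(b$seq[keep]))

  ti <- match(rname, txome$tx$transcript_id)
  if (anyNA(ti)) {
    warning(sum(is.na(ti)), " record(s) on references absent from the ",
            "transcriptome skipped")
    ok <- !is.na(ti)
    qname <- qname[ok]; pos <- pos[ok]; cigar <- cigar[ok]
    ti <- ti[ok]; rlen <- rlen[ok]
  }
  lead_clip <- integer(length(cigar))
  has_clip <- grepl("^[0-9]+S", cigar)
  lead_clip[has_clip] <- as.integer(sub("^([0-9]+)S.*$", "\\1",
                                        cigar[has_clip]))
  five_prime <- pos - 1L - lead_clip  # 0-based original 5' end
  off <- if (length(psite_offset) > 1L || !is.null(names(psite_offset))) {
    o <- unname(psite_offset[as.character(rlen)])
    if (anyNA(o)) stop("no P-site offset for read length(s): ",
                       paste(unique(rlen[is.na(o)]), collapse = ", "))
    o
  } else rep.int(psite_offset, length(five_prime))
  n <- five_prime + off
  cs <- txome$tx$cds_start[ti]; ce <- txome$tx$cds_end[ti]
  ok <- n >= cs & n < ce & five_prime >= 0L
  all_reads <- unique(b$qname)
  qname <- qname[ok]; ti <- ti[ok]
  codon <- as.integer((n[ok] - cs[ok]) %/% 3L)
  if (length(qname) == 0L) stop("no alignment record inside any CDS")
  ridx <- match(qname, unique(qname))
  mult <- rep.int(1L, length(unique(qname)))
  n_unmapped <- length(all_reads) - length(unique(qname))
  build_alignment_classes(ridx, ti, codon, mult,
                          length(all_reads), n_unmapped, txome)
}
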