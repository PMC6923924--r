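#' @useDynLib riboem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rmultinom sd cor wilcox.test p.adjust ks.test
#' @importFrom graphics plot
#' @importFrom utils head read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")

# 64 codons in lexicographic order over A < C < G < T; index i corresponds to
# CODONS[i + 1] (codon indices are 0-based throughout).
CODONS <- as.vector(t(outer(
  as.vector(t(outer(BASES, BASES, paste0))), BASES, paste0)))

#' Encode a codon string as lexicographic indices
#'
#' Codons over the alphabet A < C < G < T are mapped bijectively to the
#' integers 0..63 (`AAA` = 0, `AAC` = 1, ..., `TTT` = 63). Codons containing
#' any other character (typically `N`) map to `NA` and are flagged by callers.
#'
#' @param cds a CDS nucleotide string whose length is a multiple of 3, or a
#'   character vector of individual codons.
#' @return integer vector of 0-based codon indices, `NA` where a codon
#'   contains a non-ACGT character.
#' @examples
#' encode_codons("ATGTGGTAA")
#' decode_codons(encode_codons("ATGTGGTAA"))
#' @export
encode_codons <- function(cds) {
  if (length(cds) == 1L && nchar(cds) > 3L) {
    n <- nchar(cds)
    if (n %% 3L != 0L) stop("CDS length is not a multiple of 3")
    cds <- substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  }
  idx <- match(cds, CODONS) - 1L
  idx
}

#' @rdname encode_codons
#' @param idx integer vector of codon indices in 0..63.
#' @export
decode_codons <- function(idx) {
  stopifnot(all(is.na(idx) | (idx >= 0L & idx <= 63L)))
  out <- CODONS[idx + 1L]
  out[is.na(idx)] <- NA_character_
  out
}

#' Construct a transcriptome object
#'
#' Low-level constructor. Validates each transcript against the coordinate
#' invariants (0-based half-open CDS inside the transcript, CDS length a
#' positive multiple of 3, at least 3 codons, sequence over A/C/G/T/N) and
#' drops offending transcripts with a warning. Codon index vectors for every
#' CDS are precomputed.
#'
#' @param tx data.frame with columns `transcript_id`, `gene_id`, `cds_start`
#'   (0-based inclusive), `cds_end` (0-based exclusive).
#' @param sequences named character vector (or `Biostrings::DNAStringSet`) of
#'   transcript sequences, names matching `transcript_id`.
#' @return an object of class `transcriptome`: list with `tx` (annotation
#'   data.frame augmented with `length`, `cds_length`, `n_codons`), `seq`
#'   (character vector), `codons` (list of 0-based codon-index vectors, `NA`
#'   for codons containing N), and `genes` (list mapping gene_id to
#'   transcript_ids).
#' @export
transcriptome <- function(tx, sequences) {
  if (inherits(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  stopifnot(is.data.frame(tx),
            all(c("transcript_id", "gene_id", "cds_start", "cds_end") %in% names(tx)))
  if (anyDuplicated(tx$transcript_id))
    stop("duplicate transcript_id in annotation")
  missing_seq <- !(tx$transcript_id %in% names(sequences))
  if (any(missing_seq)) {
    warning(sum(missing_seq), " annotated transcript(s) absent from FASTA; skipped")
    tx <- tx[!missing_seq, , drop = FALSE]
  }
  if (nrow(tx) == 0L) stop("no transcripts left after matching annotation to sequences")
  seqs <- toupper(sequences[tx$transcript_id])
  tx$length <- nchar(seqs)
  tx$cds_start <- as.integer(tx$cds_start)
  tx$cds_end <- as.integer(tx$cds_end)
  tx$cds_length <- tx$cds_end - tx$cds_start

  bad_alpha <- grepl("[^ACGTN]", seqs)
  bad_coord <- !(tx$cds_start >= 0L & tx$cds_start < tx$cds_end &
                   tx$cds_end <= tx$length)
  bad_frame <- (tx$cds_length %% 3L) != 0L
  bad_short <- tx$cds_length < 9L  # fewer than 3 codons
  bad <- bad_alpha | bad_coord | ifelse(is.na(bad_frame), TRUE, bad_frame) | bad_short
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warning(sum(bad), " transcript(s) failed validation (alphabet/CDS frame/",
            "coordinates) and were dropped: ",
            paste(head(tx$transcript_id[bad], 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "")
    tx <- tx[!bad, , drop = FALSE]
    seqs <- seqs[!bad]
  }
  if (nrow(tx) == 0L) stop("no valid transcripts")
  tx$n_codons <- tx$cds_length %/% 3L
  rownames(tx) <- NULL

  codons <- lapply(seq_len(nrow(tx)), function(i) {
    encode_codons(substr(seqs[i], tx$cds_start[i] + 1L, tx$cds_end[i]))
  })
  names(codons) <- tx$transcript_id
  genes <- split(tx$transcript_id, tx$gene_id)

  structure(list(tx = tx, seq = unname(seqs), codons = codons, genes = genes),
            class = "transcriptome")
}

#' Load a transcriptome from FASTA plus CDS annotation
#'
#' The annotation is either a tab-separated table with columns
#' `transcript_id`, `gene_id`, `cds_start`, `cds_end` (0-based half-open,
#' transcript coordinates) or a GTF whose `CDS` features carry transcript-space
#' coordinates (1-based inclusive, converted internally).
#'
#' @param fasta_path path to a (optionally gzipped) FASTA of transcript
#'   sequences.
#' @param annotation_path path to the TSV or GTF annotation.
#' @param format `"auto"` (by extension), `"tsv"` or `"gtf"`.
#' @return a [transcriptome] object.
#' @export
load_transcriptome <- function(fasta_path, annotation_path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  if (!file.exists(annotation_path)) stop("annotation not found: ", annotation_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  # FASTA descriptions may carry extra tokens after the id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", annotation_path, ignore.case = TRUE)) "gtf" else "tsv"
  tx <- if (format == "gtf") read_cds_gtf(annotation_path) else {
    ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
    need <- c("transcript_id", "gene_id", "cds_start", "cds_end")
    if (!all(need %in% names(ann)))
      stop("TSV annotation must have columns: ", paste(need, collapse = ", "))
    ann[need]
  }
  transcriptome(tx, seqs)
}

# GTF restricted to CDS features in transcript coordinates; multiple CDS lines
# per transcript are merged to their [min, max) span.
read_cds_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9L && x[3] == "CDS", logical(1))
  f <- f[keep]
  if (length(f) == 0L) stop("no CDS features in GTF")
  getattr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0(key, ' "([^"]+)"'), attr))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
  }
  attrs <- vapply(f, `[`, character(1), 9L)
  d <- data.frame(
    transcript_id = getattr(attrs, "transcript_id"),
    gene_id = getattr(attrs, "gene_id"),
    start = as.integer(vapply(f, `[`, character(1), 4L)),
    end = as.integer(vapply(f, `[`, character(1), 5L)),
    stringsAsFactors = FALSE)
  sp <- split(d, d$transcript_id)
  out <- do.call(rbind, lapply(sp, function(x) data.frame(
    transcript_id = x$transcript_id[1], gene_id = x$gene_id[1],
    cds_start = min(x$start) - 1L,  # GTF 1-based inclusive -> 0-based half-open
    cds_end = max(x$end), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Codon-index view of a transcript's CDS
#'
#' @param txome a [transcriptome].
#' @param transcript_id transcript identifier.
#' @return integer vector of 0-based codon indices (length `cds_length/3`),
#'   `NA` at codons containing N.
#' @export
cds_codons <- function(txome, transcript_id) {
  stopifnot(inherits(txome, "transcriptome"))
  cd <- txome$codons[[transcript_id]]
  if (is.null(cd)) stop("unknown transcript: ", transcript_id)
  cd
}

#' @export
print.transcriptome <- function(x, ...) {
  cat("transcriptome: ", nrow(x$tx), " transcripts, ", length(x$genes),
      " genes\n", sep = "")
  cat("  CDS codons: ", min(x$tx$n_codons), "-", max(x$tx$n_codons),
      " (median ", stats::median(x$tx$n_codons), ")\n", sep = "")
  invisible(x)
}

# flat per-codon offsets: codon j of transcript i lives at flat index
# offset[i] + j + 1 (1-based) in a vector of length sum(n_codons)
codon_offsets <- function(txome) {
  n <- txome$tx$n_codons
  off <- c(0L, cumsum(n))
  list(offset = off[-length(off)], total = off[length(off)], n = n)
}
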