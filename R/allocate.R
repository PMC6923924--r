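#' Uniform initial abundance state
#'
#' Every transcript starts at the same CDS-length-normalized abundance,
#' `1e6 / n` parts per million, independent of CDS length.
#'
#' @param txome a [transcriptome].
#' @return named numeric vector of per-million abundances summing to 1e6.
#' @export
initialize_uniform <- function(txome) {
  stopifnot(inherits(txome, "transcriptome"))
  n <- nrow(txome$tx)
  if (n == 0L) stop("empty transcriptome")
  structure(rep(1e6 / n, n), names = txome$tx$transcript_id)
}

#' One allocation pass of multi-mapped reads
#'
#' Each read (equivalence class) is split over its candidate
#' `(transcript, codon)` set with weight proportional to the candidate
#' transcript's normalized abundance times, optionally, the instructive shape
#' value at the candidate codon. When the weights of a candidate set sum to
#' zero the read is split uniformly, keeping mass conserved.
#'
#' @param alignments a `read_alignments` object.
#' @param txome a [transcriptome].
#' @param abundance named per-transcript abundance vector (e.g. from
#'   [initialize_uniform()] or a previous [update_abundance()]).
#' @param shapes optional flat per-codon shape vector (see
#'   [codon_pileup()] for the flat layout); `NULL` means uniform shape.
#' @return list with `codon_mass` (flat per-codon allocated mass),
#'   `tx_mass` (per-transcript mass, named), `total` (== number of allocated
#'   reads).
#' @export
allocate_reads <- function(alignments, txome, abundance, shapes = NULL) {
  check_alignments(alignments, txome)
  co <- codon_offsets(txome)
  r <- abundance[txome$tx$transcript_id]
  fidx <- co$offset[alignments$tx] + alignments$codon + 1L
  w <- alloc_weights(alignments, r, shapes, fidx)
  codon_mass <- flat_rowsum(w, fidx, co$total)
  tx_mass <- flat_rowsum(w, alignments$tx, nrow(txome$tx))
  names(tx_mass) <- txome$tx$transcript_id
  list(codon_mass = codon_mass, tx_mass = tx_mass, total = sum(w))
}

# per-row normalized allocation weights (multiplicity included)
alloc_weights <- function(aln, r, shapes, fidx) {
  w <- r[aln$tx]
  if (!is.null(shapes)) w <- w * shapes[fidx]
  d <- flat_rowsum(w, aln$cls, length(aln$count))
  drow <- d[aln$cls]
  zero <- drow <= 0
  if (any(zero)) {  # zero-abundance candidate sets: uniform fallback
    w[zero] <- 1
    drow[zero] <- aln$size[aln$cls][zero]
  }
  w / drow * aln$count[aln$cls]
}

flat_rowsum <- function(x, group, n) {
  out <- numeric(n)
  rs <- rowsum(x, group, reorder = FALSE)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

check_alignments <- function(alignments, txome) {
  stopifnot(inherits(alignments, "read_alignments"),
            inherits(txome, "transcriptome"))
  if (!identical(alignments$transcript_ids, txome$tx$transcript_id))
    stop("alignments were built against a different transcriptome")
}

#' Re-estimate CDS-length-normalized abundance from allocated mass
#'
#' `r_i = (c_ri / l_ri) / sum_k (c_rk / l_rk) * 1e6` with `c_ri` the allocated
#' read mass on transcript `i` and `l_ri` its CDS length in nt. Invariant to
#' rescaling all masses by a positive constant.
#'
#' @param tx_mass per-transcript allocated mass (named vector, or the list
#'   returned by [allocate_reads()]).
#' @param txome a [transcriptome].
#' @return named per-million abundance vector summing to 1e6.
#' @export
update_abundance <- function(tx_mass, txome) {
  stopifnot(inherits(txome, "transcriptome"))
  if (is.list(tx_mass)) tx_mass <- tx_mass$tx_mass
  m <- tx_mass[txome$tx$transcript_id]
  if (all(m <= 0)) stop("all-zero allocated mass; cannot normalize abundance")
  dens <- m / txome$tx$cds_length
  structure(dens / sum(dens) * 1e6, names = txome$tx$transcript_id)
}

#' Control parameters of the codon-context shape model
#'
#' @param window codon-window length fed to the model (odd; default 121, i.e.
#'   60 codons of context on each side of the ribosome position).
#' @param kernel convolution kernel width (odd).
#' @param n_filters filters per convolutional layer.
#' @param hidden width of the fully connected layer.
#' @param n_bins number of equal log-scale bins for training-set resampling.
#' @param samples_per_bin data points resampled per bin (desk-scale default
#'   2000; increase for deep data).
#' @param epochs epoch cap; training also stops at the first epoch whose
#'   validation loss exceeds the previous epoch's.
#' @param lr,batch,val_frac optimizer learning rate, minibatch size, and
#'   validation fraction for early stopping.
#' @param retrain_every shape-model refit interval in allocation iterations.
#' @return list of class `shape_control`.
#' @export
shape_control <- function(window = 121L, kernel = 7L, n_filters = 32L,
                          hidden = 64L, n_bins = 10L, samples_per_bin = 2000L,
                          epochs = 10L, lr = 1e-3, batch = 128L,
                          val_frac = 0.1, retrain_every = 1L) {
  ctl <- list(window = as.integer(window), kernel = as.integer(kernel),
              n_filters = as.integer(n_filters), hidden = as.integer(hidden),
              n_bins = as.integer(n_bins),
              samples_per_bin = as.integer(samples_per_bin),
              epochs = as.integer(epochs), lr = lr, batch = as.integer(batch),
              val_frac = val_frac, retrain_every = as.integer(retrain_every))
  stopifnot(ctl$window >= 1L, ctl$window %% 2L == 1L, ctl$kernel %% 2L == 1L,
            ctl$n_filters >= 1L, ctl$n_bins >= 1L, ctl$samples_per_bin >= 1L,
            ctl$epochs >= 1L, ctl$retrain_every >= 1L,
            ctl$val_frac >= 0, ctl$val_frac < 1)
  structure(ctl, class = "shape_control")
}

#' Fit isoform-level ribosome abundance and codon-resolution profiles
#'
#' The front door of the package. Iteratively allocates (multi-mapped)
#' footprint reads and re-estimates CDS-length-normalized ribosome abundance:
#'
#' * `method = "abundance"`: reads are split in proportion to current
#'   abundance only — the fast variant.
#' * `method = "shape"`: reads are split in proportion to abundance times an
#'   instructive per-codon shape predicted by a codon-context convolutional
#'   network, itself retrained from the current allocation every
#'   `shape$retrain_every` iterations (shapes start uniform).
#' * `method = "uniform"`: a single pass splitting every read equally over
#'   its candidates — the naive baseline.
#'
#' Iteration stops after `iters` rounds or when the largest abundance change
#' falls below `tol` (in parts-per-million relative to 1e6).
#'
#' @param alignments a `read_alignments` from [map_reads_exact()] or
#'   [load_alignments()].
#' @param txome the [transcriptome] the alignments refer to.
#' @param method allocation rule, see above.
#' @param iters maximum allocation/update iterations.
#' @param tol convergence tolerance on `max |delta r_i| / 1e6`.
#' @param init optional warm start: a named abundance vector or a previous
#'   `ribofit` (e.g. warm-start the shape method from an abundance-only fit).
#' @param shape a [shape_control()] list (shape method only).
#' @param seed seed for shape-model training randomness.
#' @param verbose print per-iteration progress.
#' @return object of class `ribofit` with components `abundance` (data.frame
#'   `transcript_id`, `mass`, `abundance`), `codon_mass` (flat per-codon
#'   allocated mass), `shapes` (flat instructive shape values, shape method),
#'   `shape_model`, `iterations`, `delta` (per-iteration max abundance
#'   change), `converged`, `method`. Supports `print`, `summary`, `coef`
#'   (abundances), `fitted` (allocated counts), `plot`, `predict`.
#' @export
ribofit <- function(alignments, txome,
                    method = c("abundance", "shape", "uniform"),
                    iters = 200L, tol = 1e-8, init = NULL,
                    shape = shape_control(), seed = 1L, verbose = FALSE) {
  method <- match.arg(method)
  check_alignments(alignments, txome)
  stopifnot(iters >= 1L)
  co <- codon_offsets(txome)
  n_tx <- nrow(txome$tx)
  fidx <- co$offset[alignments$tx] + alignments$codon + 1L

  r <- if (is.null(init)) initialize_uniform(txome) else {
    v <- if (inherits(init, "ribofit")) coef(init) else init
    v <- v[txome$tx$transcript_id]
    if (anyNA(v)) stop("warm-start abundance does not cover all transcripts")
    unname(v)
  }
  s_flat <- NULL
  model <- NULL
  delta_hist <- numeric(0)
  it_done <- 0L

  if (method == "uniform") {
    w <- alignments$count[alignments$cls] / alignments$size[alignments$cls]
    it_done <- 1L
  } else {
    # last iteration at which a shape refit is scheduled: the loop may not
    # stop on tolerance before then, since a refit changes the allocation
    # weights even at converged abundances
    last_refit <- if (method == "shape")
      (iters %/% shape$retrain_every) * shape$retrain_every else 0L
    for (it in seq_len(iters)) {
      # step 1: allocate under current abundance (and shapes)
      w <- alloc_weights(alignments, r, s_flat, fidx)
      # step 2: refit the shape model from the temporary distribution; the
      # refreshed shapes take effect at the next iteration's allocation
      refit <- method == "shape" && it %% shape$retrain_every == 0L
      if (refit) {
        prof <- flat_rowsum(w, fidx, co$total)
        ts <- build_training_set(prof, txome,
                                 samples_per_bin = shape$samples_per_bin,
                                 n_bins = shape$n_bins, window = shape$window,
                                 kernel = shape$kernel,
                                 seed = seed + 1000L + it)
        model_new <- tryCatch(
          train_shape_model(ts, control = shape, seed = seed + it),
          error = function(e) {
            warning("shape-model training failed at iteration ", it, " (",
                    conditionMessage(e), "); keeping previous shapes")
            NULL
          })
        if (!is.null(model_new)) {
          model <- model_new
          s_flat <- predict_shapes_flat(model, txome)
        }
      }
      # step 3: update abundance from the allocated mass
      tx_mass <- flat_rowsum(w, alignments$tx, n_tx)
      names(tx_mass) <- txome$tx$transcript_id
      r_new <- unname(update_abundance(tx_mass, txome))
      delta <- max(abs(r_new - r)) / 1e6
      delta_hist <- c(delta_hist, delta)
      r <- r_new
      it_done <- it
      if (verbose)
        message(sprintf("iter %d: max |delta r|/1e6 = %.3g", it, delta))
      # a refit changes the weights of the next allocation even at fixed r,
      # so convergence cannot be declared on or before a refit iteration
      if (delta < tol && !refit && it >= last_refit) break
    }
    # final allocation under the converged abundances
    w <- alloc_weights(alignments, r, s_flat, fidx)
  }

  codon_mass <- flat_rowsum(w, fidx, co$total)
  tx_mass <- flat_rowsum(w, alignments$tx, n_tx)
  if (all(tx_mass <= 0)) stop("no mass allocated")
  dens <- tx_mass / txome$tx$cds_length
  r_final <- dens / sum(dens) * 1e6

  structure(list(
    method = method,
    abundance = data.frame(transcript_id = txome$tx$transcript_id,
                           mass = tx_mass, abundance = r_final,
                           stringsAsFactors = FALSE),
    codon_mass = codon_mass,
    offsets = co,
    shapes = s_flat,
    shape_model = model,
    iterations = it_done,
    delta = delta_hist,
    converged = length(delta_hist) > 0 && delta_hist[length(delta_hist)] < tol,
    n_reads = alignments$n_mapped,
    transcript_ids = txome$tx$transcript_id,
    call = match.call()),
    class = "ribofit")
}

#' Per-transcript allocated profile from a fit
#'
#' @param fit a `ribofit`.
#' @param transcript_id one transcript id, or `NULL` for a named list of all
#'   profiles.
#' @return numeric vector of per-codon allocated mass (or list thereof).
#' @export
ribo_profile <- function(fit, transcript_id = NULL) {
  stopifnot(inherits(fit, "ribofit"))
  if (is.null(transcript_id)) {
    idx <- rep.int(seq_along(fit$offsets$n), fit$offsets$n)
    return(split(fit$codon_mass, factor(fit$transcript_ids[idx],
                                        levels = fit$transcript_ids)))
  }
  i <- match(transcript_id, fit$transcript_ids)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  fit$codon_mass[(fit$offsets$offset[i] + 1L):(fit$offsets$offset[i] + fit$offsets$n[i])]
}

#' @export
print.ribofit <- function(x, ...) {
  cat("ribofit (method = \"", x$method, "\"): ",
      nrow(x$abundance), " transcripts, ",
      format(round(x$n_reads), big.mark = ","), " reads allocated\n", sep = "")
  if (x$method != "uniform")
    cat("  iterations: ", x$iterations,
        if (x$converged) " (converged)" else "",
        sprintf("; final max |delta r|/1e6 = %.3g",
                x$delta[length(x$delta)]), "\n", sep = "")
  if (!is.null(x$shape_model))
    cat("  shape model: ", x$shape_model$epochs_run, " epochs, final ",
        "validation loss ", signif(tail_or_na(x$shape_model$val_loss), 4),
        "\n", sep = "")
  invisible(x)
}

tail_or_na <- function(v) if (length(v)) v[length(v)] else NA_real_

#' @export
summary.ribofit <- function(object, ...) {
  ab <- object$abundance
  top <- ab[order(-ab$abundance), ][seq_len(min(5L, nrow(ab))), ]
  out <- list(method = object$method, n_tx = nrow(ab),
              n_reads = object$n_reads, iterations = object$iterations,
              converged = object$converged,
              abundance_quartiles = stats::quantile(ab$abundance),
              top = top)
  class(out) <- "summary.ribofit"
  out
}

#' @export
print.summary.ribofit <- function(x, ...) {
  cat("ribofit summary (method = \"", x$method, "\")\n", sep = "")
  cat("  transcripts: ", x$n_tx, ";  reads allocated: ",
      format(round(x$n_reads), big.mark = ","), "\n", sep = "")
  cat("  iterations: ", x$iterations,
      if (x$converged) " (converged)\n" else "\n", sep = "")
  cat("  abundance quartiles (per million):\n")
  print(signif(x$abundance_quartiles, 4))
  cat("  top transcripts:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ribofit <- function(object, ...) {
  structure(object$abundance$abundance,
            names = object$abundance$transcript_id)
}

#' @export
fitted.ribofit <- function(object, ...) {
  structure(object$abundance$mass, names = object$abundance$transcript_id)
}

#' @export
plot.ribofit <- function(x, transcript_id = NULL, ...) {
  if (is.null(transcript_id)) {
    if (length(x$delta) == 0)
      stop("nothing to plot for a single-pass fit; give a transcript_id")
    plot(seq_along(x$delta), x$delta, type = "b", log = "y",
         xlab = "iteration", ylab = "max |delta abundance| / 1e6",
         main = "allocation convergence", ...)
  } else {
    p <- ribo_profile(x, transcript_id)
    plot(seq_along(p) - 1L, p, type = "h", xlab = "codon index",
         ylab = "allocated read mass", main = transcript_id, ...)
  }
  invisible(x)
}

#' @export
predict.ribofit <- function(object, txome = NULL, transcript_id = NULL, ...) {
  if (is.null(object$shape_model))
    stop("fit has no shape model (method = \"", object$method, "\")")
  predict(object$shape_model, txome = txome, transcript_id = transcript_id, ...)
}

#' Write fit results as TSV tables
#'
#' Writes `abundance.tsv` (`transcript_id`, `mass`, `abundance`) and
#' `profile.tsv` (`transcript_id`, `codon_index`, `mass`; 0-based codon
#' indices).
#'
#' @param fit a `ribofit`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_ribofit <- function(fit, dir) {
  stopifnot(inherits(fit, "ribofit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab <- file.path(dir, "abundance.tsv")
  write.table(fit$abundance, ab, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- rep.int(seq_along(fit$offsets$n), fit$offsets$n)
  prof <- data.frame(transcript_id = fit$transcript_ids[idx],
                     codon_index = unlist(lapply(fit$offsets$n, seq_len),
                                          use.names = FALSE) - 1L,
                     mass = fit$codon_mass)
  pr <- file.path(dir, "profile.tsv")
  write.table(prof, pr, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(abundance = ab, profile = pr))
}
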