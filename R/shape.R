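#' Normalize a per-codon profile to mean 1
#'
#' `x_j = c_j / sum(c) * L` with `L` the CDS length in codons, so the values
#' of a transcript average 1 across its CDS. These dimensionless values are
#' the training targets of the shape model.
#'
#' @param counts per-codon read mass of one transcript.
#' @return numeric vector of the same length summing to `length(counts)`.
#' @export
normalize_profile <- function(counts) {
  s <- sum(counts)
  if (s <= 0) stop("all-zero profile cannot be normalized")
  counts / s * length(counts)
}

#' Squared log-difference loss of the shape model
#'
#' `mean((log(max(1e-8, y_pred)) - log(max(1e-8, y_true)))^2)` with natural
#' logarithms; the clipping makes the loss finite for non-positive values.
#' Symmetric in its arguments.
#'
#' @param y_pred,y_true equal-length numeric vectors.
#' @return non-negative scalar.
#' @examples
#' shape_loss(exp(1), 1)  # == 1
#' @export
shape_loss <- function(y_pred, y_true) {
  stopifnot(length(y_pred) == length(y_true), length(y_pred) >= 1L)
  mean((log(pmax(1e-8, y_pred)) - log(pmax(1e-8, y_true)))^2)
}

# context width in tokens for a window and 3 valid convolutions of width k
shape_ctx <- function(window, kernel) window + 3L * (kernel - 1L)

# Extract codon-token windows (integer matrix, pad = 64) around flat codon
# positions. `flat_pos` is 1-based into the flat codon layout.
extract_windows <- function(flat_pos, txome, window, kernel) {
  co <- codon_offsets(txome)
  glob <- unlist(txome$codons, use.names = FALSE)
  glob[is.na(glob)] <- 64L  # N codons behave like pad in the context
  tx_of <- rep.int(seq_along(co$n), co$n)
  i <- tx_of[flat_pos]
  j <- flat_pos - co$offset[i] - 1L          # 0-based codon within transcript
  half <- (shape_ctx(window, kernel) - 1L) %/% 2L
  rel <- -half:half
  jj <- outer(j, rel, "+")                    # n x ctx codon positions
  valid <- jj >= 0L & jj < co$n[i]            # recycles i down columns
  gidx <- co$offset[i] + jj + 1L
  tok <- matrix(64L, nrow = length(flat_pos), ncol = length(rel))
  tok[valid] <- glob[gidx[valid]]
  tok
}

#' Build the shape-model training set from allocated profiles
#'
#' For every transcript with allocated mass, per-codon values are normalized
#' to mean 1 ([normalize_profile()]). Zero values are discarded; the mean and
#' standard deviation of the log of the remaining targets define the
#' retained range `[mu - 3 sigma, mu + 3 sigma]`, outside of which targets
#' are dropped as outliers. The range is split into `n_bins` equal log-scale
#' bins and each non-empty bin is resampled to `samples_per_bin` points
#' (with replacement when short), balancing the log-normal-shaped target
#' distribution. When `sigma` is 0 (degenerate data) the filter and binning
#' are skipped and `n_bins * samples_per_bin` points are drawn uniformly.
#'
#' A fraction of the source positions is held out *before* resampling and
#' kept as a validation set, so that resampled duplicates of a training point
#' can never leak into validation and defeat early stopping.
#'
#' @param codon_mass flat per-codon allocated mass (as in a `ribofit`), or a
#'   `ribofit` object.
#' @param txome the [transcriptome].
#' @param samples_per_bin,n_bins resampling parameters.
#' @param window,kernel shape-model geometry (tokens per window are
#'   `window + 3 (kernel - 1)` so all convolutions are valid).
#' @param seed resampling seed.
#' @param val_frac fraction of source positions held out for validation
#'   (capped at `max_val` samples).
#' @param max_val validation-set size cap.
#' @return object of class `shape_training`: list with `windows` (integer
#'   token matrix), `target`, `val_windows`, `val_target`, `mu`, `sigma`,
#'   `bin_edges`, `n_source`.
#' @export
build_training_set <- function(codon_mass, txome, samples_per_bin = 2000L,
                               n_bins = 10L, window = 121L, kernel = 7L,
                               seed = 1L, val_frac = 0.1, max_val = 4000L) {
  if (inherits(codon_mass, "ribofit")) codon_mass <- codon_mass$codon_mass
  stopifnot(inherits(txome, "transcriptome"))
  co <- codon_offsets(txome)
  stopifnot(length(codon_mass) == co$total)
  tx_of <- rep.int(seq_along(co$n), co$n)
  tx_sum <- flat_rowsum(codon_mass, tx_of, length(co$n))
  keep_tx <- tx_sum > 0
  x <- codon_mass / ifelse(tx_sum[tx_of] > 0, tx_sum[tx_of], 1) * co$n[tx_of]
  pos <- which(x > 0 & keep_tx[tx_of])
  # center codon must be a real codon
  glob <- unlist(txome$codons, use.names = FALSE)
  pos <- pos[!is.na(glob[pos])]
  if (length(pos) == 0L) stop("no nonzero profile values to train on")
  lx <- log(x[pos])
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  set.seed(seed)
  if (sigma == 0) {
    take <- sample(pos, n_bins * samples_per_bin, replace = TRUE)
    edges <- NULL
    val <- integer(0)
  } else {
    inside <- lx >= mu - 3 * sigma & lx <= mu + 3 * sigma
    pos <- pos[inside]; lx <- lx[inside]
    # hold out source positions for validation before any resampling
    n_val <- min(as.integer(max_val), floor(val_frac * length(pos)))
    val <- if (n_val > 0) sample(pos, n_val) else integer(0)
    train_mask <- !(pos %in% val)
    tpos <- pos[train_mask]; tlx <- lx[train_mask]
    edges <- seq(mu - 3 * sigma, mu + 3 * sigma, length.out = n_bins + 1L)
    bin <- findInterval(tlx, edges, rightmost.closed = TRUE)
    bin[bin < 1L] <- 1L; bin[bin > n_bins] <- n_bins
    take <- unlist(lapply(seq_len(n_bins), function(b) {
      members <- tpos[bin == b]
      if (length(members) == 0L) return(integer(0))
      sample(members, samples_per_bin,
             replace = length(members) < samples_per_bin)
    }), use.names = FALSE)
    take <- take[sample.int(length(take))]  # shuffle bins together
  }
  structure(list(windows = extract_windows(take, txome, window, kernel),
                 target = x[take],
                 val_windows = if (length(val))
                   extract_windows(val, txome, window, kernel) else NULL,
                 val_target = if (length(val)) x[val] else NULL,
                 mu = mu, sigma = sigma, bin_edges = edges,
                 n_source = length(pos), window = as.integer(window),
                 kernel = as.integer(kernel)),
            class = "shape_training")
}

#' Train the codon-context shape model
#'
#' A small 1-D convolutional network over codon tokens (64 codons one-hot
#' plus a pad token for positions outside the CDS): three valid convolutions,
#' a head combining center-position and window-mean features, one fully
#' connected layer, and a positive (exponentiated) scalar output. Trained
#' with Adam on the squared log-difference loss ([shape_loss()]); training
#' stops at the first epoch whose validation loss exceeds the previous
#' epoch's (the weights of the previous epoch are kept), or at the epoch
#' cap. Deterministic given `seed`.
#'
#' @param training a `shape_training` from [build_training_set()], or a list
#'   with `windows` (token matrix) and `target`.
#' @param control a [shape_control()]; its geometry must match the training
#'   windows.
#' @param seed integer seed for weight initialization, shuffling and the
#'   validation split.
#' @return object of class `shape_model` with the network weights, loss
#'   history (`train_loss`, `val_loss`), `epochs_run`, and geometry.
#' @export
train_shape_model <- function(training, control = shape_control(), seed = 1L) {
  stopifnot(!is.null(training$windows), !is.null(training$target),
            nrow(training$windows) == length(training$target))
  ctx <- ncol(training$windows)
  window <- ctx - 3L * (control$kernel - 1L)
  Xval <- training$val_windows
  yval <- training$val_target
  if (is.null(Xval)) {
    Xval <- matrix(integer(0), 0L, ctx)
    yval <- numeric(0)
  }
  fit <- cpp_shape_train(training$windows, as.numeric(training$target),
                         Xval, as.numeric(yval),
                         control$n_filters, control$kernel, control$hidden,
                         control$epochs, control$lr, control$batch,
                         control$val_frac, as.integer(seed))
  structure(list(weights = fit[c("W1", "b1", "W2", "b2", "W3", "b3",
                                 "W4", "b4", "W5", "b5",
                                 "kernel", "n_filters", "hidden")],
                 window = window, kernel = control$kernel,
                 n_filters = control$n_filters, hidden = control$hidden,
                 train_loss = fit$train_loss, val_loss = fit$val_loss,
                 epochs_run = fit$epochs_run),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat("shape_model: window ", x$window, " codons, ", x$n_filters,
      " filters (kernel ", x$kernel, "), hidden ", x$hidden, "\n", sep = "")
  cat("  epochs run: ", x$epochs_run, "; train loss ",
      signif(tail_or_na(x$train_loss), 4), "; validation loss ",
      signif(tail_or_na(x$val_loss), 4), "\n", sep = "")
  invisible(x)
}

#' Predict instructive shape values
#'
#' One positive value per CDS codon; windows at CDS edges are padded with the
#' pad token. By default each transcript's values are renormalized to mean 1,
#' decoupling shape from abundance in the joint allocation weight.
#'
#' @param object a `shape_model`.
#' @param txome a [transcriptome] (give this or `windows`).
#' @param transcript_id one id, or `NULL` for all transcripts.
#' @param windows alternatively, a token matrix of extracted windows (as in
#'   the training set); returns one raw prediction per row.
#' @param renormalize rescale each transcript's values to mean 1.
#' @param ... unused.
#' @return numeric vector (one transcript or `windows`), or a named list of
#'   per-transcript vectors.
#' @export
predict.shape_model <- function(object, txome = NULL, transcript_id = NULL,
                                windows = NULL, renormalize = TRUE, ...) {
  if (!is.null(windows)) {
    stopifnot(ncol(windows) == shape_ctx(object$window, object$kernel))
    return(cpp_shape_predict_windows(object$weights, windows))
  }
  stopifnot(inherits(txome, "transcriptome"))
  one <- function(i) {
    tok <- txome$codons[[i]]
    tok[is.na(tok)] <- 64L
    s <- cpp_shape_predict_seq(object$weights, tok, object$window)
    if (renormalize) s / mean(s) else s
  }
  if (!is.null(transcript_id)) {
    i <- match(transcript_id, txome$tx$transcript_id)
    if (is.na(i)) stop("unknown transcript: ", transcript_id)
    return(one(i))
  }
  out <- lapply(seq_len(nrow(txome$tx)), one)
  names(out) <- txome$tx$transcript_id
  out
}

# flat per-codon shape vector (mean 1 per transcript) for the allocator
predict_shapes_flat <- function(model, txome) {
  unlist(predict(model, txome = txome), use.names = FALSE)
}
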