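test_that("profile normalization yields mean-1 values", {
  expect_equal(normalize_profile(rep(4, 7)), rep(1, 7))
  expect_equal(normalize_profile(c(2, 0, 2)), c(1.5, 0, 1.5))
  x <- normalize_profile(runif(50))
  expect_equal(sum(x), 50)
  expect_error(normalize_profile(c(0, 0)), "all-zero")
})

test_that("the loss is the clipped squared log difference", {
  expect_identical(shape_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(shape_loss(exp(1), 1), 1)            # (ln e - ln 1)^2
  expect_identical(shape_loss(0, 0), 0)             # both clip to 1e-8
  a <- runif(20); b <- runif(20)
  expect_equal(shape_loss(a, b), shape_loss(b, a))  # symmetry
  expect_gte(shape_loss(a, b), 0)
})

test_that("training-set construction filters zeros and outliers and balances bins", {
  set.seed(99)
  txo <- txome_from_seqs(c(t1 = random_cds(2000, seed = 41)))
  x <- rlnorm(2000, 0, 1)
  x[sample(2000, 100)] <- 0                   # zeros must be discarded
  x[1:3] <- exp(c(-20, 20, 15))               # gross outliers
  mass <- x                                    # single transcript: mass == x scale
  ts <- build_training_set(mass, txo, samples_per_bin = 200, seed = 5)
  expect_s3_class(ts, "shape_training")
  expect_true(all(ts$target > 0))
  lt <- log(ts$target)
  expect_true(all(lt >= ts$mu - 3 * ts$sigma - 1e-9))
  expect_true(all(lt <= ts$mu + 3 * ts$sigma + 1e-9))
  # bins over the retained range have equal counts (non-empty ones)
  bin <- findInterval(lt, ts$bin_edges, rightmost.closed = TRUE)
  cnt <- table(bin)
  expect_true(all(cnt == 200))
  expect_identical(ncol(ts$windows), 121L + 3L * 6L)
})

test_that("degenerate constant targets hit the sigma-zero branch", {
  txo <- txome_from_seqs(c(t1 = random_cds(500, seed = 43)))
  mass <- rep(2, 500)
  ts <- build_training_set(mass, txo, samples_per_bin = 50, n_bins = 10,
                           seed = 7)
  expect_identical(length(ts$target), 500L)   # 10 x 50 uniform draws
  expect_true(all(ts$target == 1))            # normalized constant is 1
  expect_identical(ts$sigma, 0)
})

test_that("window extraction pads outside the CDS and centers correctly", {
  txo <- txome_from_seqs(c(t1 = random_cds(5, seed = 47)))
  ts <- build_training_set(rep(1, 5) + c(0.5, 0, 0, 0, -0.2), txo,
                           samples_per_bin = 10, n_bins = 2, window = 3,
                           kernel = 3, seed = 1)
  ctx <- 3 + 3 * 2
  expect_identical(ncol(ts$windows), as.integer(ctx))
  half <- (ctx - 1) %/% 2
  cods <- cds_codons(txo, "t1")
  # center column must always be a real codon of the transcript
  centers <- ts$windows[, half + 1]
  expect_true(all(centers %in% cods))
  # rebuild one window by hand from its center position
  w <- ts$windows[1, ]
  j <- which(cods == w[half + 1])[1] - 1
  expected <- vapply(-half:half, function(k) {
    jj <- j + k
    if (jj < 0 || jj >= 5) 64L else cods[jj + 1]
  }, integer(1))
  # windows with this center are identical to the hand-built one
  cand <- ts$windows[ts$windows[, half + 1] == w[half + 1], , drop = FALSE]
  expect_true(any(apply(cand, 1, function(r) all(r == expected))))
})

test_that("training is deterministic given a seed and early-stops on validation loss", {
  set.seed(1)
  n <- 800
  X <- matrix(sample(0:63, n * 39, replace = TRUE), n, 39)  # window 21, kernel 7
  planted <- exp(rnorm(64, 0, 1))
  y <- planted[X[, 20] + 1]
  ctl <- shape_control(window = 21, kernel = 7, n_filters = 8, hidden = 16,
                       epochs = 3)
  m1 <- train_shape_model(list(windows = X, target = y), ctl, seed = 42)
  m2 <- train_shape_model(list(windows = X, target = y), ctl, seed = 42)
  expect_identical(m1$train_loss, m2$train_loss)
  expect_identical(m1$val_loss, m2$val_loss)
  expect_identical(predict(m1, windows = X[1:5, ]),
                   predict(m2, windows = X[1:5, ]))
  # validation loss decreases from the start of training
  expect_lt(m1$val_loss[length(m1$val_loss)], 5)
  m3 <- train_shape_model(list(windows = X, target = y), ctl, seed = 43)
  expect_false(identical(m1$train_loss, m3$train_loss))
})

test_that("the model recovers a planted center-codon signal", {
  set.seed(11)
  n <- 8000
  X <- matrix(sample(0:63, n * 39, replace = TRUE), n, 39)
  planted <- exp(rnorm(64, 0, 1))
  y <- planted[X[, 20] + 1]
  ctl <- shape_control(window = 21, kernel = 7, n_filters = 16, hidden = 32,
                       epochs = 25, lr = 2e-3)
  m <- train_shape_model(list(windows = X, target = y), ctl, seed = 4)
  Xnew <- matrix(sample(0:63, 2000 * 39, replace = TRUE), 2000, 39)
  pred <- predict(m, windows = Xnew)
  per_codon <- tapply(pred, Xnew[, 20], mean)
  rho <- cor(per_codon, planted[as.integer(names(per_codon)) + 1],
             method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("constant targets are fit to near-zero loss", {
  set.seed(3)
  X <- matrix(sample(0:63, 500 * 39, replace = TRUE), 500, 39)
  y <- rep(2.5, 500)
  ctl <- shape_control(window = 21, kernel = 7, n_filters = 8, hidden = 16,
                       epochs = 30, lr = 5e-3)
  m <- train_shape_model(list(windows = X, target = y), ctl, seed = 8)
  expect_lt(m$train_loss[length(m$train_loss)], 0.01)
  expect_lt(m$val_loss[length(m$val_loss)], m$val_loss[1] + 1e-12)
  pred <- predict(m, windows = X[1:50, ])
  expect_equal(unname(pred), rep(2.5, 50), tolerance = 0.2)
})

test_that("whole-transcript prediction matches batched window prediction", {
  set.seed(5)
  X <- matrix(sample(0:63, 300 * 39, replace = TRUE), 300, 39)
  y <- rlnorm(300)
  ctl <- shape_control(window = 21, kernel = 7, n_filters = 8, hidden = 16,
                       epochs = 2)
  m <- train_shape_model(list(windows = X, target = y), ctl, seed = 6)
  txo <- txome_from_seqs(c(t1 = random_cds(40, seed = 51)))
  s <- predict(m, txome = txo, transcript_id = "t1", renormalize = FALSE)
  expect_identical(length(s), 40L)
  expect_true(all(s > 0 & is.finite(s)))
  # sliding prediction must agree exactly with explicit per-codon windows
  flat_pos <- 1:40
  W <- riboem:::extract_windows(flat_pos, txo, 21L, 7L)
  s2 <- predict(m, windows = W)
  expect_equal(unname(s), unname(s2), tolerance = 1e-12)
  # renormalized values have mean one and identical CDS give identical shapes
  txo2 <- txome_from_seqs(c(a = random_cds(40, seed = 51),
                            b = random_cds(40, seed = 51)))
  sl <- predict(m, txome = txo2)
  expect_equal(mean(sl$a), 1, tolerance = 1e-12)
  expect_identical(sl$a, sl$b)
})

test_that("a three-codon CDS predicts from mostly-pad windows", {
  set.seed(6)
  X <- matrix(sample(0:63, 200 * 39, replace = TRUE), 200, 39)
  ctl <- shape_control(window = 21, kernel = 7, n_filters = 8, hidden = 16,
                       epochs = 1)
  m <- train_shape_model(list(windows = X, target = rlnorm(200)), ctl, seed = 2)
  txo <- txome_from_seqs(c(t = "ATGTGGTAA"))
  s <- predict(m, txome = txo, transcript_id = "t")
  expect_identical(length(s), 3L)
  expect_true(all(is.finite(s) & s > 0))
})
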