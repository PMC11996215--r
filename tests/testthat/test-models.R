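# Recurrent cells against hand oracles; training and prediction harness.

test_that("gru_step matches forced values at zero weights", {
  h_size <- 3L
  zeros <- matrix(0, h_size, h_size)
  p <- gru_params(matrix(0, h_size, 1), matrix(0, h_size, 1),
                  matrix(0, h_size, 1), zeros, zeros, zeros)
  h_prev <- c(0.4, -0.2, 1)
  # all preactivations 0 => z = r = 1/2, candidate = 0, h = h_prev / 2
  expect_equal(gru_step(p, 0, h_prev), h_prev / 2)
  expect_equal(gru_step(p, 5, numeric(h_size)), numeric(h_size))
})

test_that("gru_step matches the scalar hand evaluation", {
  p <- gru_params(0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  got <- gru_step(p, 1, 0)
  sig <- function(v) 1 / (1 + exp(-v))
  expect_equal(got, (1 - sig(0.1)) * tanh(0.1), tolerance = 1e-10)
  expect_equal(got, 0.04734, tolerance = 1e-4)
  expect_equal(got, hand_gru_step(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 1, 0),
               tolerance = 1e-12)
})

test_that("gru sequences match a scalar hand-unrolled oracle to 1e-10", {
  set.seed(8)
  for (i in 1:5) {
    w <- stats::runif(6, -0.6, 0.6)
    xs <- stats::rnorm(7)
    p <- gru_params(w[1], w[2], w[3], w[4], w[5], w[6])
    expect_equal(drop(gru_forward(p, xs)),
                 hand_gru_run(w[1], w[2], w[3], w[4], w[5], w[6], xs),
                 tolerance = 1e-10)
  }
})

test_that("bigru_forward matches the hand-unrolled length-3 oracle", {
  fw <- c(0.2, -0.1, 0.3, 0.15, -0.25, 0.1)
  bw <- c(-0.3, 0.2, 0.05, -0.1, 0.2, 0.25)
  xs <- c(1, -0.5, 0.25)
  pf <- gru_params(fw[1], fw[2], fw[3], fw[4], fw[5], fw[6])
  pb <- gru_params(bw[1], bw[2], bw[3], bw[4], bw[5], bw[6])
  got <- bigru_forward(pf, pb, xs)
  want <- hand_bigru_run(fw, bw, xs)
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
  expect_identical(dim(got), c(3L, 2L))
})

test_that("bigru respects its structural symmetries", {
  set.seed(19)
  h_size <- 4L
  rm_ <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.4), nr, nc)
  pf <- gru_params(rm_(h_size, 1), rm_(h_size, 1), rm_(h_size, 1),
                   rm_(h_size, h_size), rm_(h_size, h_size), rm_(h_size, h_size))
  pb <- gru_params(rm_(h_size, 1), rm_(h_size, 1), rm_(h_size, 1),
                   rm_(h_size, h_size), rm_(h_size, h_size), rm_(h_size, h_size))
  xs <- stats::rnorm(6)
  out <- bigru_forward(pf, pb, xs)
  expect_identical(dim(out), c(6L, 2L * h_size))
  # reversing the input and swapping the cells reverses the output with
  # halves swapped
  swapped <- bigru_forward(pb, pf, rev(xs))
  expect_equal(swapped[rev(seq_len(6)), c(h_size + 1:h_size, 1:h_size)], out,
               tolerance = 1e-12)
  # zero weights, zero input -> all-zero states of width 2H
  zp <- gru_params(matrix(0, h_size, 1), matrix(0, h_size, 1),
                   matrix(0, h_size, 1), matrix(0, h_size, h_size),
                   matrix(0, h_size, h_size), matrix(0, h_size, h_size))
  expect_equal(bigru_forward(zp, zp, numeric(5)),
               matrix(0, 5, 2L * h_size))
  # a length-1 sequence gives both directions the same single step
  one <- bigru_forward(pf, pb, xs[1])
  expect_equal(one[1, 1:h_size], drop(gru_forward(pf, xs[1])),
               tolerance = 1e-12)
  expect_equal(one[1, h_size + 1:h_size], drop(gru_forward(pb, xs[1])),
               tolerance = 1e-12)
})

test_that("lstm_step matches gate semantics and the scalar hand oracle", {
  h_size <- 2L
  zeros <- matrix(0, h_size, h_size)
  zp <- lstm_params(matrix(0, h_size, 1), matrix(0, h_size, 1),
                    matrix(0, h_size, 1), matrix(0, h_size, 1),
                    zeros, zeros, zeros, zeros)
  st <- lstm_step(zp, 0, numeric(h_size), numeric(h_size))
  expect_equal(st$h, numeric(h_size))
  expect_equal(st$c, numeric(h_size))

  # forget gate forced open, input gate forced shut: perfect memory
  big <- 50
  pm <- lstm_params(matrix(0, h_size, 1), matrix(0, h_size, 1),
                    matrix(0, h_size, 1), matrix(0, h_size, 1),
                    zeros, zeros, zeros, zeros,
                    b_i = rep(-big, h_size), b_f = rep(big, h_size))
  c_prev <- c(0.7, -1.2)
  st2 <- lstm_step(pm, 1, c(0.1, 0.2), c_prev)
  expect_equal(st2$c, c_prev, tolerance = 1e-12)

  # scalar fixed-weight case against the hand evaluation
  w <- c(0.2, -0.3, 0.4, 0.1, -0.2, 0.3, 0.25, -0.15)
  ps <- lstm_params(w[1], w[2], w[3], w[4], w[5], w[6], w[7], w[8])
  got <- lstm_step(ps, 0.5, 0.3, -0.4)
  want <- hand_lstm_step(w[1], w[2], w[3], w[4], w[5], w[6], w[7], w[8],
                         0.5, 0.3, -0.4)
  expect_equal(got$h, want$h, tolerance = 1e-10)
  expect_equal(got$c, want$c, tolerance = 1e-10)
})

test_that("softmax is a stable probability map", {
  expect_equal(softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  e <- exp(1)
  expect_equal(softmax(c(1, 0, 0, 0)),
               c(e, 1, 1, 1) / (e + 3), tolerance = 1e-12)
  big <- softmax(c(1000, 0, 0, 0))
  expect_true(all(is.finite(big)))
  expect_equal(big[1], 1, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    s <- stats::rnorm(4, sd = 10)
    p <- softmax(s)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(softmax(s + 123.4), p, tolerance = 1e-12)
  }
  expect_error(softmax(c(1, NA, 0, 0)), class = "pcgseg_error_signal")
})

test_that("the compiled forward pass agrees with the R cell equations", {
  set.seed(23)
  h_size <- 4L
  gmat <- function(g) list(
    W = matrix(stats::rnorm(g * h_size, 0, 0.4), g * h_size, 1),
    U = matrix(stats::rnorm(g * h_size * h_size, 0, 0.4), g * h_size, h_size),
    b = matrix(stats::rnorm(g * h_size, 0, 0.1), g * h_size, 1))
  Wo <- matrix(stats::rnorm(4 * 2 * h_size, 0, 0.4), 4, 2 * h_size)
  bo <- matrix(stats::rnorm(4, 0, 0.1), 4, 1)
  xs <- stats::rnorm(6)
  cf <- gmat(3)
  cb <- gmat(3)
  slice <- function(M, k) M[(k - 1) * h_size + 1:h_size, , drop = FALSE]
  as_gru <- function(cc) gru_params(
    slice(cc$W, 1), slice(cc$W, 2), slice(cc$W, 3),
    slice(cc$U, 1), slice(cc$U, 2), slice(cc$U, 3),
    b_z = slice(cc$b, 1), b_r = slice(cc$b, 2), b_h = slice(cc$b, 3))
  states <- bigru_forward(as_gru(cf), as_gru(cb), xs)
  want <- states %*% t(Wo) + matrix(bo, length(xs), 4, byrow = TRUE)
  got <- pcgseg:::cpp_rnn_logits(
    "bigru", list(Wf = cf$W, Uf = cf$U, bf = cf$b,
                  Wb = cb$W, Ub = cb$U, bb = cb$b, Wo = Wo, bo = bo), xs)
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("training is deterministic and respects the epoch contract", {
  bench <- tiny_benchmark()
  cfg <- model_config("gru", hidden_units = 8L, epochs = 3L, seed = 11L)
  m1 <- train_segmenter(bench, cfg)
  m2 <- train_segmenter(bench, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_identical(nrow(m1$history), 3L)

  m0 <- train_segmenter(bench, model_config("gru", hidden_units = 8L,
                                            epochs = 0L, seed = 11L))
  expect_identical(nrow(m0$history), 0L)

  single <- bench$train[bench$train$record_id == bench$train$record_id[1L], ]
  class(single) <- class(bench$train)
  attr(single, "sampling_rate_hz") <- attr(bench$train, "sampling_rate_hz")
  attr(single, "window_seconds") <- attr(bench$train, "window_seconds")
  expect_error(train_segmenter(single, cfg), class = "pcgseg_error_split")
})

test_that("a linearly separable toy sequence task trains to high accuracy", {
  # label = amplitude band of the input at each step: learnable per step
  set.seed(63)
  make_win <- function() {
    y <- sample(0:3, 40, replace = TRUE)
    x <- c(0.1, 0.4, 0.7, 1.0)[y + 1] + stats::rnorm(40, 0, 0.02)
    list(x = x, y = pcg_classes()[y + 1])
  }
  wins <- replicate(30, make_win(), simplify = FALSE)
  ds <- segment_dataset(
    features = lapply(wins, `[[`, "x"),
    labels = lapply(wins, `[[`, "y"),
    record_id = sprintf("rec%02d", rep(1:10, each = 3)),
    window_seconds = 40 / 100, sampling_rate_hz = 100L)
  # few optimizer steps at this toy scale: a larger step size than the
  # pipeline default is appropriate
  cfg <- model_config("gru", hidden_units = 16L, epochs = 30L, seed = 5L,
                      batch_size = 8L, learning_rate = 0.03)
  m <- train_segmenter(ds, cfg)
  expect_gt(m$history$accuracy[30L], 0.95)
})

test_that("prediction contracts: length, determinism of ties, fingerprints", {
  bench <- tiny_benchmark()
  cfg <- model_config("gru", hidden_units = 8L, epochs = 0L, seed = 1L)
  m <- train_segmenter(bench, cfg)

  # untrained zero-ish model on constant features: constant label stream
  m_zero <- m
  m_zero$params <- lapply(m$params, function(p) p * 0)
  feat <- numeric(500)
  out <- predict_labels(m_zero, feat, check_fingerprint = FALSE)
  expect_identical(length(out), 500L)
  expect_identical(unique(as.character(out)), "S1")  # tie -> lowest class

  # output length always equals input length
  feat2 <- stats::runif(321)
  expect_identical(length(predict_labels(m, feat2,
                                         check_fingerprint = FALSE)), 321L)

  # fingerprint mismatch is refused with an explanation
  wrong <- stats::runif(100)
  attr(wrong, "fingerprint") <- "some-other-pipeline"
  expect_error(predict_labels(m, wrong), "pipeline",
               class = "pcgseg_error_fingerprint")
})

test_that("checkpoints round-trip through disk", {
  bench <- tiny_benchmark()
  m <- train_segmenter(bench, model_config("gru", hidden_units = 8L,
                                           epochs = 1L, seed = 2L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$architecture, m$architecture)
  expect_equal(as.data.frame(m2$history), as.data.frame(m$history))

  expect_identical(glance(m)$epochs, 1L)
  expect_identical(nrow(tidy(m)), 1L)
})
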