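#' Model configuration for the sequence labelers
#'
#' Defaults follow the published training setup: Adam with initial learning
#' rate 0.001, mini-batches of 16 windows, 200 hidden units, 70% of the
#' source records for training; 300 epochs for the unidirectional GRU and
#' 200 for the bidirectional models.
#'
#' @param architecture `"gru"`, `"bigru"`, or `"bilstm"`.
#' @param hidden_units Hidden state width per direction (default 200).
#' @param learning_rate Adam initial learning rate (default 0.001).
#' @param epochs Training epochs; default depends on the architecture
#'   (gru 300, bigru 200, bilstm 200).
#' @param batch_size Mini-batch size in windows (default 16).
#' @param train_fraction Fraction of source *records* assigned to the
#'   training split (default 0.7). Splitting is by record, not by window, so
#'   near-duplicate heart cycles never straddle the split.
#' @param seed Integer seed controlling initialization and batch shuffling;
#'   a fixed seed makes training runs identical.
#' @param grad_clip Global gradient-norm clip (default 1; 0 disables).
#' @param n_classes Number of label classes (always 4 here).
#' @param optimizer Only `"adam"` is implemented.
#' @return A `model_config` list.
#' @export
model_config <- function(architecture = c("bigru", "gru", "bilstm"),
                         hidden_units = 200L, learning_rate = 0.001,
                         epochs = NULL, batch_size = 16L,
                         train_fraction = 0.7, seed = 1L, grad_clip = 1,
                         n_classes = 4L, optimizer = "adam") {
  architecture <- match.arg(architecture)
  optimizer <- match.arg(optimizer, "adam")
  if (is.null(epochs)) {
    epochs <- switch(architecture, gru = 300L, bigru = 200L, bilstm = 200L)
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("`train_fraction` must be in (0, 1).", class = "pcgseg_error_config")
  }
  if (n_classes != length(PCG_CLASSES)) {
    abort("`n_classes` must equal the number of phase labels (4).",
          class = "pcgseg_error_config")
  }
  structure(list(architecture = architecture,
                 hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 grad_clip = grad_clip, n_classes = as.integer(n_classes),
                 optimizer = optimizer),
            class = "model_config")
}

# uniform init in +-1/sqrt(hidden); biases zero except LSTM forget gate (+1,
# the standard aid to gradient flow over long windows)
init_params <- function(architecture, hidden, n_classes) {
  gates <- if (architecture == "bilstm") 4L else 3L
  r <- 1 / sqrt(hidden)
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc, -r, r), nr, nc)
  cell <- function() {
    b <- matrix(0, gates * hidden, 1L)
    if (architecture == "bilstm") {
      b[(hidden + 1L):(2L * hidden), 1L] <- 1  # forget gate rows
    }
    list(W = rmat(gates * hidden, 1L), U = rmat(gates * hidden, hidden), b = b)
  }
  if (architecture == "gru") {
    c1 <- cell()
    list(W = c1$W, U = c1$U, b = c1$b,
         Wo = rmat(n_classes, hidden), bo = matrix(0, n_classes, 1L))
  } else {
    cf <- cell()
    cb <- cell()
    list(Wf = cf$W, Uf = cf$U, bf = cf$b, Wb = cb$W, Ub = cb$U, bb = cb$b,
         Wo = rmat(n_classes, 2L * hidden), bo = matrix(0, n_classes, 1L))
  }
}

dataset_arrays <- function(dataset) {
  T_len <- length(dataset$features[[1L]])
  X <- vapply(dataset$features, as.double, numeric(T_len))
  Y <- vapply(dataset$labels, function(l) as.integer(l) - 1L, integer(T_len))
  list(X = X, Y = Y)  # T x N matrices
}

#' Split a segment dataset by source record
#'
#' Assigns whole records to the training or test split, so windows from one
#' recording never appear on both sides.
#'
#' @param dataset A [segment_dataset()].
#' @param train_fraction Fraction of records for training.
#' @param seed Integer seed for the record shuffle.
#' @return List with `train` and `test` datasets.
#' @export
split_by_record <- function(dataset, train_fraction = 0.7, seed = 1L) {
  ids <- unique(dataset$record_id)
  if (length(ids) < 2L) {
    abort("Need at least 2 source records to split by record.",
          class = "pcgseg_error_split")
  }
  n_train <- max(1L, min(length(ids) - 1L,
                         floor(train_fraction * length(ids))))
  shuffled <- withr::with_seed(seed, sample(ids))
  train_ids <- shuffled[seq_len(n_train)]
  keep <- dataset$record_id %in% train_ids
  subset_ds <- function(m) {
    out <- dataset[m, ]
    for (a in c("window_seconds", "sampling_rate_hz", "fingerprint")) {
      attr(out, a) <- attr(dataset, a)
    }
    class(out) <- unique(c("segment_dataset", class(out)))
    out
  }
  list(train = subset_ds(keep), test = subset_ds(!keep))
}

#' Train a heart-sound sequence labeler
#'
#' Minimizes per-time-step cross-entropy over the four phase classes with
#' Adam, on the training side of a by-record split of `dataset`. Fully
#' deterministic for a fixed seed: initialization and epoch shuffles are
#' drawn from `cfg$seed`.
#'
#' @param dataset A [segment_dataset()] of equal-length windows from at
#'   least two source records (or a pre-split list with elements `train` and
#'   `test`, as returned by [split_by_record()] or [make_benchmark()]).
#' @param cfg A [model_config()].
#' @return A `pcg_model`: architecture tag, configuration, learned
#'   parameters, preprocessing fingerprint, per-epoch training history, and
#'   the record ids of each split. With `cfg$epochs = 0` the model is
#'   returned untrained with an empty history.
#' @export
train_segmenter <- function(dataset, cfg = model_config()) {
  if (is.list(dataset) && !inherits(dataset, "segment_dataset") &&
      all(c("train", "test") %in% names(dataset))) {
    split <- dataset
  } else {
    if (nrow(dataset) == 0L) {
      abort("Dataset is empty.", class = "pcgseg_error_dataset")
    }
    split <- split_by_record(dataset, cfg$train_fraction, cfg$seed)
  }
  train_ds <- split$train
  arr <- dataset_arrays(train_ds)
  n_win <- ncol(arr$X)
  params <- withr::with_seed(
    cfg$seed,
    init_params(cfg$architecture, cfg$hidden_units, cfg$n_classes))
  if (cfg$epochs > 0L) {
    order_mat <- withr::with_seed(
      cfg$seed + 1L,
      matrix(unlist(lapply(seq_len(cfg$epochs),
                           function(e) sample.int(n_win) - 1L)),
             nrow = n_win))
    fit <- cpp_rnn_train(cfg$architecture, params, arr$X,
                         matrix(as.integer(arr$Y), nrow(arr$Y)),
                         matrix(as.integer(order_mat), nrow(order_mat)),
                         cfg$batch_size, cfg$learning_rate, cfg$grad_clip)
    params <- fit$params
    history <- tibble(epoch = seq_len(cfg$epochs),
                      loss = as.double(fit$loss),
                      accuracy = as.double(fit$accuracy))
  } else {
    history <- tibble(epoch = integer(0), loss = double(0),
                      accuracy = double(0))
  }
  structure(
    list(architecture = cfg$architecture, config = cfg, params = params,
         fingerprint = attr(train_ds, "fingerprint", exact = TRUE),
         sampling_rate_hz = attr(train_ds, "sampling_rate_hz", exact = TRUE),
         window_seconds = attr(train_ds, "window_seconds", exact = TRUE),
         history = history,
         train_records = unique(train_ds$record_id),
         test_records = unique(split$test$record_id),
         schema_version = 1L),
    class = "pcg_model")
}

#' @export
print.pcg_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<pcg_model> %s, %d hidden units, %d parameters\n",
              x$architecture, x$config$hidden_units, n_par))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs: loss %.4f, training accuracy %.3f\n",
                nrow(x$history), last$loss, last$accuracy))
  } else {
    cat("  untrained (0 epochs)\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted labeler
#'
#' @param x A `pcg_model`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `loss`, `accuracy`.
#' @export
tidy.pcg_model <- function(x, ...) x$history

#' One-row summary of a fitted labeler
#'
#' @param x A `pcg_model`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, hidden units, parameter count,
#'   epochs run, final training loss and accuracy.
#' @export
glance.pcg_model <- function(x, ...) {
  tibble(
    architecture = x$architecture,
    hidden_units = x$config$hidden_units,
    n_parameters = sum(vapply(x$params, length, 0L)),
    epochs = nrow(x$history),
    final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)] else NA_real_,
    final_accuracy = if (nrow(x$history)) x$history$accuracy[nrow(x$history)] else NA_real_
  )
}

assert_fingerprint <- function(model, fp, check = TRUE) {
  if (!check) return(invisible(TRUE))
  if (!is.null(model$fingerprint) && !is.null(fp) &&
      !identical(model$fingerprint, fp)) {
    abort(paste0(
      "Feature pipeline mismatch: the model was trained on features from\n  ",
      model$fingerprint, "\nbut these features come from\n  ", fp,
      "\nRe-preprocess with the model's configuration or pass ",
      "`check_fingerprint = FALSE`."),
      class = "pcgseg_error_fingerprint")
  }
  invisible(TRUE)
}

#' Predict per-sample phase labels
#'
#' Runs the fitted network over a feature sequence and takes the per-step
#' softmax argmax, mapped to the phase classes; ties break deterministically
#' toward the lower class index (S1 first).
#'
#' @param model A `pcg_model`.
#' @param features Numeric feature sequence (output of
#'   [preprocess_record()]), or a [segment_dataset()] to predict window-wise.
#' @param check_fingerprint Refuse features whose preprocessing fingerprint
#'   differs from the model's (default `TRUE`).
#' @return For a numeric sequence, a [label_seq()] of the same length; for a
#'   dataset, a list of per-window `label_seq` objects.
#' @export
predict_labels <- function(model, features, check_fingerprint = TRUE) {
  stopifnot(inherits(model, "pcg_model"))
  if (inherits(features, "segment_dataset")) {
    assert_fingerprint(model, attr(features, "fingerprint", exact = TRUE),
                       check_fingerprint)
    arr <- dataset_arrays(features)
    cls <- cpp_rnn_predict(model$architecture, model$params, arr$X) + 1L
    rate <- attr(features, "sampling_rate_hz")
    return(lapply(seq_len(ncol(cls)),
                  function(j) label_seq(PCG_CLASSES[cls[, j]], rate)))
  }
  assert_fingerprint(model, attr(features, "fingerprint", exact = TRUE),
                     check_fingerprint)
  x <- matrix(as.double(features), ncol = 1L)
  cls <- cpp_rnn_predict(model$architecture, model$params, x) + 1L
  rate <- attr(features, "sampling_rate_hz", exact = TRUE) %||%
    model$sampling_rate_hz %||% 4000L
  label_seq(PCG_CLASSES[cls[, 1L]], rate)
}

#' @export
predict.pcg_model <- function(object, newdata, ...) {
  predict_labels(object, newdata, ...)
}

#' Save / load a fitted labeler
#'
#' Checkpoints are single-file containers (RDS) holding the architecture
#' tag, configuration, parameters, preprocessing fingerprint and history,
#' with a schema version for forward compatibility.
#'
#' @param model A `pcg_model`.
#' @param path Checkpoint file path.
#' @return `path` (write) or the restored `pcg_model` (read).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pcg_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    abort("Unsupported checkpoint schema.", class = "pcgseg_error_checkpoint")
  }
  obj$history <- as_tibble(obj$history)
  structure(obj, class = "pcg_model")
}
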