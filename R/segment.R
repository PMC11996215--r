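#' Cut a feature sequence and its labels into fixed-duration windows
#'
#' Divides a record into consecutive, non-overlapping windows of
#' `round(window_seconds * rate)` samples. A trailing remainder shorter than
#' one window is dropped, so the window count is
#' `floor(length(features) / window_length)`.
#'
#' @param features Numeric feature sequence (typically the output of
#'   [preprocess_record()]).
#' @param labels A [label_seq()] (or factor) of the same length.
#' @param window_seconds Window duration in seconds (default 2).
#' @param rate Sampling rate in Hz; taken from `labels` if it is a
#'   `label_seq` and `rate` is missing.
#' @param record_id,site Provenance carried onto each window.
#' @return A [segment_dataset()]. A window longer than the record yields an
#'   empty dataset with a warning.
#' @export
segment_record <- function(features, labels, window_seconds = 2, rate = NULL,
                           record_id = "record", site = "unknown") {
  if (is.null(rate)) {
    rate <- attr(labels, "sampling_rate_hz")
    if (is.null(rate)) {
      abort("`rate` must be given when `labels` carries no sampling rate.")
    }
  }
  f <- as_label_factor(labels)
  if (length(features) != length(f)) {
    abort(sprintf("features (%d) and labels (%d) must have equal length.",
                  length(features), length(f)),
          class = "pcgseg_error_dataset")
  }
  wl <- as.integer(round(window_seconds * rate))
  if (wl < 1L) abort("Window must contain at least one sample.")
  n_win <- length(features) %/% wl
  if (n_win == 0L) {
    warn(sprintf(
      "Record '%s' (%d samples) is shorter than one %d-sample window; empty dataset.",
      record_id, length(features), wl))
  }
  idx <- function(k) ((k - 1L) * wl + 1L):(k * wl)
  feats <- lapply(seq_len(n_win), function(k) as.double(features[idx(k)]))
  labs <- lapply(seq_len(n_win), function(k) f[idx(k)])
  segment_dataset(
    features = feats, labels = labs,
    record_id = rep(as.character(record_id), n_win),
    site = rep(as.character(site), length.out = max(n_win, 0L)),
    window_seconds = window_seconds, sampling_rate_hz = rate,
    fingerprint = attr(features, "fingerprint", exact = TRUE)
  )
}

#' Combine segment datasets
#'
#' Row-binds datasets that share window geometry and sampling rate.
#'
#' @param ... [segment_dataset()] objects, or a single list of them.
#' @return A combined [segment_dataset()].
#' @export
bind_segments <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "segment_dataset")) {
    parts <- parts[[1]]
  }
  parts <- parts[vapply(parts, nrow, 0L) > 0L]
  if (length(parts) == 0L) abort("No non-empty datasets to combine.")
  rates <- unique(vapply(parts, function(p) attr(p, "sampling_rate_hz"), 0L))
  ws <- unique(vapply(parts, function(p) attr(p, "window_seconds"), 0))
  if (length(rates) > 1L || length(ws) > 1L) {
    abort("Datasets differ in sampling rate or window duration.",
          class = "pcgseg_error_dataset")
  }
  fps <- unique(unlist(lapply(parts, function(p) attr(p, "fingerprint"))))
  if (length(fps) > 1L) {
    abort("Datasets carry different preprocessing fingerprints.",
          class = "pcgseg_error_dataset")
  }
  out <- dplyr::bind_rows(lapply(parts, function(p) {
    class(p) <- setdiff(class(p), "segment_dataset")
    p
  }))
  segment_dataset(out$features, out$labels, out$record_id, out$site,
                  window_seconds = ws, sampling_rate_hz = rates,
                  fingerprint = if (length(fps)) fps else NULL)
}
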