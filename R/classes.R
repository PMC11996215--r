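#' Construct a PCG record
#'
#' A `pcg_record` bundles a mono heart-sound signal with its sampling rate,
#' an identifier, and the auscultation site it was captured at.
#'
#' @param samples Numeric vector of signal samples (arbitrary amplitude
#'   units). Must be non-empty and finite.
#' @param sampling_rate_hz Positive integer sampling rate in Hz. The corpora
#'   this pipeline targets are sampled at 4000 Hz.
#' @param record_id Character scalar identifier.
#' @param site Auscultation site, one of `"AV"`, `"PV"`, `"TV"`, `"MV"`,
#'   `"other"`, `"unknown"` (aortic, pulmonic, tricuspid, mitral valve
#'   positions).
#'
#' @return An object of class `pcg_record`.
#' @export
#' @examples
#' rec <- pcg_record(sin(2 * pi * 80 * seq(0, 1, by = 1 / 4000)), 4000)
#' rec
pcg_record <- function(samples, sampling_rate_hz, record_id = "record",
                       site = "unknown") {
  samples <- as.double(samples)
  if (length(samples) == 0L) {
    abort("`samples` must be non-empty.", class = "pcgseg_error_record")
  }
  if (!all(is.finite(samples))) {
    abort("`samples` must be finite (no NA/NaN/Inf).",
          class = "pcgseg_error_record")
  }
  rate <- as.integer(sampling_rate_hz)
  if (is.na(rate) || rate <= 0L) {
    abort("`sampling_rate_hz` must be a positive integer.",
          class = "pcgseg_error_record")
  }
  site <- match.arg(site, c("AV", "PV", "TV", "MV", "other", "unknown"))
  structure(
    list(record_id = as.character(record_id), samples = samples,
         sampling_rate_hz = rate, site = site),
    class = "pcg_record"
  )
}

#' @export
print.pcg_record <- function(x, ...) {
  cat(sprintf("<pcg_record '%s'> %d samples @ %d Hz (%.2f s), site %s\n",
              x$record_id, length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz, x$site))
  invisible(x)
}

#' @export
length.pcg_record <- function(x) length(x$samples)

#' Construct and validate a region table
#'
#' A region table is the annotation form used for PCG ground truth: ordered
#' rows of (start, end, class) over 1-based sample indices, where consecutive
#' rows share their boundary (each row's start equals the previous row's end)
#' and classes follow the cardiac cycle S1 -> systolic -> S2 -> diastolic ->
#' S1 ...
#'
#' @param start,end Integer vectors of 1-based sample limits, `start < end`
#'   row-wise.
#' @param class Character vector of phase labels (see [pcg_classes()]).
#' @param phase_order_action How to treat cyclic-phase-order violations:
#'   `"error"` (default) or `"warn"` (used for files holding raw model
#'   predictions, which may break the cycle).
#'
#' @return A tibble of class `region_table` with columns `start`, `end`,
#'   `class`.
#' @export
#' @examples
#' region_table(c(1, 101), c(101, 181), c("S1", "systolic"))
region_table <- function(start, end, class,
                         phase_order_action = c("error", "warn")) {
  rt <- tibble(
    start = as.integer(start),
    end = as.integer(end),
    class = factor(as.character(class), levels = PCG_CLASSES)
  )
  class(rt) <- c("region_table", class(rt))
  validate_region_table(rt, match.arg(phase_order_action))
  rt
}

#' Validate region-table invariants
#'
#' Checks, reporting offending row numbers: starts are positive, `start <
#' end` in every row, consecutive rows abut exactly (`start[k+1] == end[k]`),
#' class names are known, and classes advance in the cyclic phase order
#' (the first row may be any phase).
#'
#' @param rt A `region_table` or a data frame with columns `start`, `end`,
#'   `class`.
#' @param phase_order_action `"error"` (default) or `"warn"` for phase-order
#'   violations; structural violations always error.
#' @return `rt`, invisibly, if valid.
#' @export
validate_region_table <- function(rt, phase_order_action = c("error", "warn")) {
  phase_order_action <- match.arg(phase_order_action)
  if (nrow(rt) == 0L) {
    abort("Region table is empty.", class = "pcgseg_error_region")
  }
  if (anyNA(rt$start) || anyNA(rt$end)) {
    abort("Region limits must be integers.", class = "pcgseg_error_region")
  }
  if (anyNA(rt$class)) {
    bad <- which(is.na(rt$class))
    abort(sprintf("Unknown class name in row(s) %s (expected one of %s).",
                  paste(bad, collapse = ", "),
                  paste(PCG_CLASSES, collapse = ", ")),
          class = "pcgseg_error_region")
  }
  if (any(rt$start < 1L)) {
    abort(sprintf("Row(s) %s: start limit must be >= 1.",
                  paste(which(rt$start < 1L), collapse = ", ")),
          class = "pcgseg_error_region")
  }
  bad <- which(rt$start >= rt$end)
  if (length(bad)) {
    abort(sprintf("Row(s) %s: start must be < end.",
                  paste(bad, collapse = ", ")),
          class = "pcgseg_error_region")
  }
  if (nrow(rt) > 1L) {
    nxt <- rt$start[-1L]
    prv <- rt$end[-nrow(rt)]
    bad <- which(nxt != prv)
    if (length(bad)) {
      kind <- ifelse(nxt[bad] > prv[bad], "gap", "overlap")
      abort(sprintf(
        "Row(s) %s: %s between consecutive regions (start must equal the previous end).",
        paste(bad + 1L, collapse = ", "), paste(unique(kind), collapse = "/")),
        class = "pcgseg_error_region")
    }
    idx <- match(as.character(rt$class), PCG_CLASSES)
    expected <- (idx[-nrow(rt)] %% 4L) + 1L
    bad <- which(idx[-1L] != expected)
    if (length(bad)) {
      msg <- sprintf(
        "Row(s) %s: classes out of cyclic phase order (S1 -> systolic -> S2 -> diastolic).",
        paste(bad + 1L, collapse = ", "))
      if (phase_order_action == "error") {
        abort(msg, class = "pcgseg_error_region")
      } else {
        warn(msg, class = "pcgseg_warning_region")
      }
    }
  }
  invisible(rt)
}

#' Construct a per-sample label sequence
#'
#' One cardiac-phase label per signal sample, the prediction target of the
#' sequence labelers.
#'
#' @param labels Character or factor vector of phase labels.
#' @param sampling_rate_hz Positive integer sampling rate of the originating
#'   signal.
#' @return An object of class `label_seq`: a factor with levels
#'   [pcg_classes()] and a `sampling_rate_hz` attribute.
#' @export
#' @examples
#' label_seq(rep(c("S1", "systolic"), c(5, 5)), 4000)
label_seq <- function(labels, sampling_rate_hz = 4000L) {
  f <- factor(as.character(labels), levels = PCG_CLASSES)
  if (length(f) == 0L) {
    abort("`labels` must be non-empty.", class = "pcgseg_error_labels")
  }
  if (anyNA(f)) {
    abort(sprintf("Unknown label(s): %s.",
                  paste(unique(setdiff(as.character(labels), PCG_CLASSES)),
                        collapse = ", ")),
          class = "pcgseg_error_labels")
  }
  rate <- as.integer(sampling_rate_hz)
  if (is.na(rate) || rate <= 0L) {
    abort("`sampling_rate_hz` must be a positive integer.",
          class = "pcgseg_error_labels")
  }
  structure(f, sampling_rate_hz = rate, class = c("label_seq", "factor"))
}

#' @export
print.label_seq <- function(x, ...) {
  r <- rle(as.integer(x))
  cat(sprintf("<label_seq> %d samples @ %d Hz, %d runs\n",
              length(x), attr(x, "sampling_rate_hz"), length(r$lengths)))
  head_runs <- utils::head(
    sprintf("%s(%d)", PCG_CLASSES[r$values], r$lengths), 8L)
  cat(" ", paste(head_runs, collapse = " "),
      if (length(r$lengths) > 8L) "...\n" else "\n")
  invisible(x)
}

# subsetting keeps the class and rate
#' @export
`[.label_seq` <- function(x, ...) {
  out <- NextMethod()
  structure(factor(out, levels = PCG_CLASSES),
            sampling_rate_hz = attr(x, "sampling_rate_hz"),
            class = c("label_seq", "factor"))
}

as_label_factor <- function(x) {
  if (inherits(x, "label_seq")) {
    factor(as.character(x), levels = PCG_CLASSES)
  } else {
    f <- factor(as.character(x), levels = PCG_CLASSES)
    if (anyNA(f)) abort("Unknown label values.", class = "pcgseg_error_labels")
    f
  }
}

#' Construct a segment dataset
#'
#' A tibble of fixed-duration (feature window, label window) pairs ready for
#' training or evaluation, one row per window, with per-window provenance.
#'
#' @param features List of equal-length numeric vectors (feature windows).
#' @param labels List of factor/character vectors, each the same length as
#'   its feature window.
#' @param record_id Character vector of source-record identifiers.
#' @param site Character vector of auscultation sites (recycled).
#' @param window_seconds Window duration in seconds.
#' @param sampling_rate_hz Sampling rate of the windows.
#' @param fingerprint Optional preprocessing fingerprint string carried from
#'   [preprocess_record()].
#' @return A tibble of class `segment_dataset` with list-columns `features`
#'   and `labels`.
#' @export
segment_dataset <- function(features, labels, record_id, site = "unknown",
                            window_seconds, sampling_rate_hz,
                            fingerprint = NULL) {
  stopifnot(length(features) == length(labels),
            length(features) == length(record_id))
  n <- length(features)
  if (n > 0L) {
    len <- lengths(features)
    if (length(unique(len)) > 1L) {
      abort("All feature windows must have identical length.",
            class = "pcgseg_error_dataset")
    }
    if (any(lengths(labels) != len)) {
      abort("Each label window must match its feature window's length.",
            class = "pcgseg_error_dataset")
    }
    ok <- vapply(features, function(f) all(is.finite(f)), logical(1))
    if (!all(ok)) {
      abort("Feature windows must be finite.", class = "pcgseg_error_dataset")
    }
  }
  out <- tibble(
    record_id = as.character(record_id),
    site = rep_len(as.character(site), n),
    features = features,
    labels = lapply(labels, as_label_factor)
  )
  attr(out, "window_seconds") <- window_seconds
  attr(out, "sampling_rate_hz") <- as.integer(sampling_rate_hz)
  attr(out, "fingerprint") <- fingerprint
  class(out) <- c("segment_dataset", class(out))
  out
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf(
    "<segment_dataset> %d windows of %.3g s @ %d Hz (%d samples each), %d record(s)\n",
    nrow(x), attr(x, "window_seconds"), attr(x, "sampling_rate_hz"),
    if (nrow(x)) length(x$features[[1]]) else 0L,
    length(unique(x$record_id))))
  NextMethod()
}
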