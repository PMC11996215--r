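#' Read a region-label table
#'
#' Parses the three-column annotation format used for PCG ground truth:
#' start limit, end limit, class name, one region per line. Tab- or
#' comma-delimited files are accepted, with or without a header line, and
#' class names may be quoted or bare. Limits are 1-based sample indices and
#' consecutive regions share their boundary sample index.
#'
#' @param path Path to a delimited text file.
#' @return A validated [region_table()].
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path), class = "pcgseg_error_format")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort(sprintf("'%s' is empty: no regions to read.", path),
          class = "pcgseg_error_region")
  }
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else "[\t ]+"
  parse_line <- function(line) {
    f <- strsplit(line, sep)[[1]]
    f <- gsub('^["“”\']+|["“”\']+$', "", trimws(f))
    f[nzchar(f)]
  }
  fields <- lapply(lines, parse_line)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    abort(sprintf("'%s': row(s) %s do not have 3 columns (start, end, class).",
                  path, paste(bad, collapse = ", ")),
          class = "pcgseg_error_region")
  }
  # optional header: first row whose limits are not numeric
  first <- fields[[1]]
  if (is.na(suppressWarnings(as.numeric(first[[1]])))) {
    fields <- fields[-1L]
    if (length(fields) == 0L) {
      abort(sprintf("'%s' contains only a header: no regions to read.", path),
            class = "pcgseg_error_region")
    }
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  cls <- vapply(fields, `[[`, "", 3L)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(sprintf("'%s': non-numeric limits in row(s) %s.",
                  path, paste(bad, collapse = ", ")),
          class = "pcgseg_error_region")
  }
  unknown <- which(!cls %in% PCG_CLASSES)
  if (length(unknown)) {
    abort(sprintf("'%s': unknown class name in row(s) %s: %s.",
                  path, paste(unknown, collapse = ", "),
                  paste(unique(cls[unknown]), collapse = ", ")),
          class = "pcgseg_error_region")
  }
  region_table(start, end, cls, phase_order_action = "warn")
}

#' Write a region table as delimited text
#'
#' Emits the same three-column format accepted by [read_region_table()], so
#' predictions round-trip through files.
#'
#' @param rt A [region_table()].
#' @param path Output path.
#' @param sep Field separator, tab by default.
#' @param header Whether to write a header line.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(rt, path, sep = "\t", header = FALSE) {
  validate_region_table(rt, phase_order_action = "warn")
  lines <- sprintf("%d%s%d%s\"%s\"", rt$start, sep, rt$end, sep,
                   as.character(rt$class))
  if (header) lines <- c(paste("start", "end", "class", sep = sep), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Expand a region table to one label per sample
#'
#' Sample `n` (1-based) receives the class of the region with the largest
#' start limit `<= n`; the final region additionally claims its own end
#' sample. Under the shared-boundary convention (each boundary index is both
#' one region's end and the next region's start) this assigns boundary
#' samples to the *later* region and covers every sample exactly once: the
#' output length equals the table's final end limit.
#'
#' @param rt A valid [region_table()].
#' @param sampling_rate_hz Sampling rate stored on the resulting sequence
#'   (region tables carry sample indices only); defaults to the corpora's
#'   4000 Hz.
#' @return A [label_seq()] of length `max(rt$end)`.
#' @export
#' @examples
#' rt <- region_table(c(1, 11), c(11, 26), c("S1", "systolic"))
#' table(expand_labels(rt, 100))
expand_labels <- function(rt, sampling_rate_hz = 4000L) {
  validate_region_table(rt)
  n <- rt$end[nrow(rt)]
  # region k covers start_k .. (start_{k+1} - 1); the last covers through end
  run_len <- diff(c(rt$start, n + 1L))
  if (rt$start[1L] != 1L) {
    abort(sprintf("First region must start at sample 1 (got %d).", rt$start[1L]),
          class = "pcgseg_error_region")
  }
  label_seq(rep(as.character(rt$class), run_len), sampling_rate_hz)
}

#' Collapse a per-sample label sequence to a region table
#'
#' Run-length encodes a label sequence into the (start, end, class) region
#' form with shared boundaries. This inverts [expand_labels()] exactly:
#' `collapse_labels(expand_labels(rt))` reproduces `rt` for every valid
#' table. Sequences that violate the cyclic phase order (as raw model
#' argmax output can) are still encoded faithfully; the violation is
#' reported as a warning, not an error.
#'
#' @param labels A [label_seq()] or factor/character vector of phase labels.
#' @return A [region_table()].
#' @export
collapse_labels <- function(labels) {
  f <- as_label_factor(labels)
  if (length(f) == 0L) {
    abort("Label sequence is empty.", class = "pcgseg_error_labels")
  }
  r <- rle(as.integer(f))
  # a trailing single-sample run cannot be represented under the
  # shared-boundary convention (start < end); absorb it into its predecessor
  if (length(r$lengths) > 1L && r$lengths[length(r$lengths)] == 1L) {
    warn("Trailing single-sample run absorbed into the preceding region.")
    r$lengths <- r$lengths[-length(r$lengths)]
    r$values <- r$values[-length(r$values)]
  }
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  end <- c(start[-1L], length(f))
  rt <- tibble(start = as.integer(start), end = as.integer(end),
               class = factor(PCG_CLASSES[r$values], levels = PCG_CLASSES))
  class(rt) <- c("region_table", class(rt))
  validate_region_table(rt, phase_order_action = "warn")
  rt
}
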