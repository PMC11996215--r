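#' Confusion matrix over the four cardiac phases
#'
#' @param truth,pred Label sequences (any mix of [label_seq()], factor or
#'   character) of equal length.
#' @return A 4x4 integer matrix of class `pcg_confusion`; rows are the true
#'   class, columns the predicted class, in the order [pcg_classes()].
#' @export
confusion_matrix <- function(truth, pred) {
  t_f <- as_label_factor(truth)
  p_f <- as_label_factor(pred)
  if (length(t_f) != length(p_f)) {
    abort(sprintf("truth (%d) and pred (%d) must have equal length.",
                  length(t_f), length(p_f)),
          class = "pcgseg_error_metrics")
  }
  cm <- table(truth = t_f, pred = p_f)
  cm <- matrix(as.integer(cm), 4L, 4L,
               dimnames = list(truth = PCG_CLASSES, pred = PCG_CLASSES))
  structure(cm, class = c("pcg_confusion", "matrix"))
}

#' Metric panel from a confusion matrix
#'
#' One-vs-rest per class: sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)`, precision `TP / (TP + FP)`, `F1 = 2 * P * Se / (P +
#' Se)`, and per-class accuracy `(TP + TN) / total`. The summary row reports
#' micro accuracy (`trace / total`) together with the unweighted macro means
#' of the other metrics. A class absent from the data yields `NA` (an
#' explicit undefined marker) and is excluded from the macro means, never
#' silently counted as 0 or 100.
#'
#' @param cm A `pcg_confusion` (or any 4x4 count matrix in class order).
#' @param percent Report values in percent (default) rather than fractions.
#' @return A tibble of class `metric_report` with columns `class`,
#'   `accuracy`, `sensitivity`, `precision`, `specificity`, `f1`: one row
#'   per phase plus a `"overall"` row.
#' @export
score_confusion <- function(cm, percent = TRUE) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || !all(dim(cm) == c(4L, 4L))) {
    abort("`cm` must be a 4x4 count matrix.", class = "pcgseg_error_metrics")
  }
  total <- sum(cm)
  if (total <= 0) {
    abort("Empty confusion matrix.", class = "pcgseg_error_metrics")
  }
  tp <- unname(diag(cm))
  fn <- unname(rowSums(cm)) - tp
  fp <- unname(colSums(cm)) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  se <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  pp <- safe_div(tp, tp + fp)
  f1 <- ifelse(!is.na(se) & !is.na(pp) & (se + pp) > 0,
               2 * pp * se / (pp + se), NA_real_)
  acc_class <- (tp + tn) / total
  micro_acc <- sum(tp) / total
  scale <- if (percent) 100 else 1
  out <- tibble(
    class = c(PCG_CLASSES, "overall"),
    accuracy = scale * c(acc_class, micro_acc),
    sensitivity = scale * c(se, mean(se, na.rm = TRUE)),
    precision = scale * c(pp, mean(pp, na.rm = TRUE)),
    specificity = scale * c(sp, mean(sp, na.rm = TRUE)),
    f1 = scale * c(f1, mean(f1, na.rm = TRUE))
  )
  class(out) <- c("metric_report", class(out))
  attr(out, "n_samples") <- total
  attr(out, "percent") <- percent
  out
}

#' Evaluate a fitted labeler on a segment dataset
#'
#' Predicts every window, pools per-sample confusion counts within each
#' group (auscultation site by default), and reports the metric panel per
#' group plus an `"ALL"` aggregate computed from the pooled confusion matrix
#' of all groups together (not the mean of the group metrics).
#'
#' @param model A `pcg_model`.
#' @param dataset A [segment_dataset()] carrying the grouping metadata.
#' @param group_by Column of `dataset` to group on, `"site"` (default) or
#'   `"record_id"`; use `NULL` for a single pooled report.
#' @param detail Return per-class rows (`TRUE`) or only each group's summary
#'   row (default).
#' @param check_fingerprint Passed to [predict_labels()].
#' @return A tibble of class `pcg_evaluation`: columns `group`, `n_samples`,
#'   and the metric panel in the column order accuracy, sensitivity,
#'   precision, specificity, f1 (values in percent). Confusion matrices are
#'   attached as attribute `confusions`.
#' @export
evaluate_model <- function(model, dataset, group_by = "site",
                           detail = FALSE, check_fingerprint = TRUE) {
  if (nrow(dataset) == 0L) {
    abort("Empty dataset.", class = "pcgseg_error_metrics")
  }
  preds <- predict_labels(model, dataset,
                          check_fingerprint = check_fingerprint)
  groups <- if (is.null(group_by)) rep("ALL", nrow(dataset))
            else as.character(dataset[[group_by]])
  group_cm <- function(rows) {
    truth <- unlist(lapply(dataset$labels[rows], as.integer))
    pred <- unlist(lapply(preds[rows], as.integer))
    confusion_matrix(PCG_CLASSES[truth], PCG_CLASSES[pred])
  }
  levels_g <- unique(groups)
  cms <- lapply(levels_g, function(g) group_cm(which(groups == g)))
  names(cms) <- levels_g
  if (length(levels_g) > 1L || !identical(levels_g, "ALL")) {
    pooled <- Reduce(`+`, lapply(cms, unclass))
    cms$ALL <- structure(pooled, class = c("pcg_confusion", "matrix"))
  }
  reports <- purrr::map2(cms, names(cms), function(cm, g) {
    rep_g <- score_confusion(cm)
    rep_g$group <- g
    rep_g$n_samples <- attr(rep_g, "n_samples")
    rep_g
  })
  out <- dplyr::bind_rows(reports)
  if (!detail) out <- dplyr::filter(out, .data$class == "overall")
  out <- dplyr::select(out, "group", "class", "n_samples", "accuracy",
                       "sensitivity", "precision", "specificity", "f1")
  if (!detail) out$class <- NULL
  attr(out, "confusions") <- cms
  class(out) <- c("pcg_evaluation", class(out))
  out
}

#' Write a metric report as delimited text or JSON
#'
#' Emits the panel in the conventional column order Acc, Se, P+, Sp, F1.
#'
#' @param report A `metric_report` or `pcg_evaluation` tibble.
#' @param path Output path; extension `.json` selects JSON, anything else
#'   tab-delimited text.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  df <- as.data.frame(report)
  ord <- intersect(c("group", "class", "n_samples", "accuracy", "sensitivity",
                     "precision", "specificity", "f1"), names(df))
  df <- df[, ord, drop = FALSE]
  names(df) <- sub("^accuracy$", "Acc",
               sub("^sensitivity$", "Se",
               sub("^precision$", "P+",
               sub("^specificity$", "Sp",
               sub("^f1$", "F1", names(df))))))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
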