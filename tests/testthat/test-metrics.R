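# Confusion counting and the Acc/Se/P+/Sp/F1 panel.

test_that("confusion counts match direct enumeration", {
  cls <- pcg_classes()
  same <- label_seq(rep(cls, 5), 100)
  cm <- confusion_matrix(same, same)
  expect_identical(unname(diag(unclass(cm))), rep(5L, 4L))
  expect_identical(sum(cm), 20L)

  # completely disjoint labels: zero diagonal
  shifted <- label_seq(cls[c(2, 3, 4, 1)][match(as.character(same), cls)], 100)
  cm2 <- confusion_matrix(same, shifted)
  expect_identical(unname(diag(unclass(cm2))), rep(0L, 4L))

  # 12-sample hand-built pair verified cell by cell
  truth <- c("S1", "S1", "S1", "systolic", "systolic", "S2", "S2", "S2",
             "diastolic", "diastolic", "diastolic", "diastolic")
  pred <- c("S1", "systolic", "S1", "systolic", "S2", "S2", "S2", "diastolic",
            "diastolic", "diastolic", "S1", "diastolic")
  cm3 <- unclass(confusion_matrix(truth, pred))
  for (i in seq_len(4)) {
    for (j in seq_len(4)) {
      expect_identical(cm3[i, j],
                       sum(truth == cls[i] & pred == cls[j]))
    }
  }
  expect_error(confusion_matrix(truth, pred[1:5]),
               class = "pcgseg_error_metrics")
})

test_that("score_confusion matches brute-force one-vs-rest arithmetic", {
  cls <- pcg_classes()
  set.seed(17)
  truth <- sample(cls, 400, replace = TRUE, prob = c(0.1, 0.25, 0.1, 0.55))
  pred <- ifelse(stats::runif(400) < 0.7, truth, sample(cls, 400, TRUE))
  rep_ <- score_confusion(confusion_matrix(truth, pred))
  for (k in seq_len(4)) {
    want <- brute_metrics(truth, pred, cls[k])
    expect_equal(rep_$sensitivity[k], 100 * want[["se"]], tolerance = 1e-12)
    expect_equal(rep_$specificity[k], 100 * want[["sp"]], tolerance = 1e-12)
    expect_equal(rep_$precision[k], 100 * want[["pp"]], tolerance = 1e-12)
    expect_equal(rep_$f1[k], 100 * want[["f1"]], tolerance = 1e-12)
    expect_equal(rep_$accuracy[k], 100 * want[["acc"]], tolerance = 1e-12)
  }
  # summary row: micro accuracy, macro means of the rest
  expect_equal(rep_$accuracy[5], 100 * mean(truth == pred), tolerance = 1e-12)
  expect_equal(rep_$sensitivity[5], mean(rep_$sensitivity[1:4]),
               tolerance = 1e-12)
})

test_that("perfect predictions score 100 everywhere", {
  cm <- diag(c(10L, 20L, 30L, 40L))
  rep_ <- score_confusion(cm)
  expect_true(all(abs(rep_$accuracy - 100) < 1e-12))
  expect_true(all(abs(rep_$f1 - 100) < 1e-12))
  expect_error(score_confusion(matrix(0L, 4, 4)),
               class = "pcgseg_error_metrics")
})

test_that("uniform random prediction on balanced classes gives ~25% accuracy", {
  set.seed(29)
  n <- 40000
  truth <- sample(pcg_classes(), n, replace = TRUE)
  pred <- sample(pcg_classes(), n, replace = TRUE)
  rep_ <- score_confusion(confusion_matrix(truth, pred))
  # binomial sd of the overall accuracy is ~0.22 points at this n
  expect_lt(abs(rep_$accuracy[5] - 25), 1)
})

test_that("empty classes yield NA, excluded from macro means", {
  cm <- matrix(0L, 4, 4)
  cm[2, 2] <- 50L
  cm[4, 4] <- 40L
  cm[2, 4] <- 10L
  rep_ <- score_confusion(cm)
  expect_true(is.na(rep_$sensitivity[1]))  # S1 absent
  expect_true(is.na(rep_$f1[1]))
  # macro mean over the defined classes only
  expect_equal(rep_$sensitivity[5],
               mean(rep_$sensitivity[1:4], na.rm = TRUE), tolerance = 1e-12)
  expect_false(is.na(rep_$sensitivity[5]))
})

test_that("score_confusion is scale-invariant and permutation-stable", {
  set.seed(37)
  cm <- matrix(sample(1:60, 16), 4, 4)
  r1 <- score_confusion(cm)
  r2 <- score_confusion(cm * 7L)
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # Se and Sp of class k are invariant to permuting the other classes
  for (k in seq_len(4)) {
    others <- setdiff(seq_len(4), k)
    perm <- seq_len(4)
    perm[others] <- sample(others)
    cm_p <- cm[perm, perm]
    r_p <- score_confusion(cm_p)
    pos <- which(perm == k)
    expect_equal(r_p$sensitivity[pos], r1$sensitivity[k], tolerance = 1e-12)
    expect_equal(r_p$specificity[pos], r1$specificity[k], tolerance = 1e-12)
  }
})

test_that("pooled accuracy equals the sample-weighted mean of group accuracies", {
  set.seed(43)
  cls <- pcg_classes()
  cms <- lapply(1:3, function(i) {
    truth <- sample(cls, 200 * i, TRUE)
    pred <- ifelse(stats::runif(200 * i) < 0.6, truth, sample(cls, 200 * i, TRUE))
    confusion_matrix(truth, pred)
  })
  pooled <- Reduce(`+`, lapply(cms, unclass))
  micro <- score_confusion(pooled)$accuracy[5]
  accs <- vapply(cms, function(m) score_confusion(m)$accuracy[5], 0)
  ns <- vapply(cms, sum, 0L)
  expect_equal(micro, sum(accs * ns) / sum(ns), tolerance = 1e-12)
})

test_that("evaluate_model groups by site and pools into ALL", {
  bench <- tiny_benchmark()
  m <- train_segmenter(bench, model_config("gru", hidden_units = 8L,
                                           epochs = 2L, seed = 3L))
  ev <- evaluate_model(m, bench$test, group_by = "site")
  expect_true("ALL" %in% ev$group)
  cms <- attr(ev, "confusions")
  pooled <- Reduce(`+`, lapply(cms[setdiff(names(cms), "ALL")], unclass))
  expect_identical(pooled, unclass(cms$ALL))
  # single group: the group report equals ALL
  one_site <- bench$test[bench$test$site == bench$test$site[1L], ]
  class(one_site) <- class(bench$test)
  for (a in c("window_seconds", "sampling_rate_hz", "fingerprint")) {
    attr(one_site, a) <- attr(bench$test, a)
  }
  ev1 <- evaluate_model(m, one_site, group_by = "site")
  row_site <- ev1[ev1$group != "ALL", -1]
  row_all <- ev1[ev1$group == "ALL", -1]
  expect_equal(as.data.frame(row_site), as.data.frame(row_all),
               tolerance = 1e-12)
  expect_error(evaluate_model(m, bench$test[0, ]),
               class = "pcgseg_error_metrics")
})

test_that("metric reports serialize with the conventional column order", {
  cm <- diag(c(5L, 5L, 5L, 5L))
  rep_ <- score_confusion(cm)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_metrics(rep_, tsv)
  hdr <- strsplit(readLines(tsv, n = 1L), "\t")[[1]]
  expect_identical(hdr, c("class", "Acc", "Se", "P+", "Sp", "F1"))
  js <- withr::local_tempfile(fileext = ".json")
  write_metrics(rep_, js)
  parsed <- jsonlite::read_json(js)
  expect_identical(length(parsed), 5L)
})
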