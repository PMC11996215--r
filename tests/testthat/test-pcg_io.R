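# Record and region-table I/O, label expansion, windowing.

test_that("WAV round trip preserves samples and rate", {
  t <- (0:3999) / 4000
  x <- 0.5 * sin(2 * pi * 90 * t)
  path <- withr::local_tempfile(fileext = ".wav")
  write_record(pcg_record(x, 4000, record_id = "tone"), path)
  rec <- read_record(path)
  expect_equal(rec$samples, x, tolerance = 1e-7)
  expect_identical(rec$sampling_rate_hz, 4000L)

  # pcm16 is quantized but faithful to ~1/32768
  path2 <- withr::local_tempfile(fileext = ".wav")
  write_record(pcg_record(x, 4000), path2, encoding = "pcm16")
  rec2 <- read_record(path2)
  expect_lt(max(abs(rec2$samples - x)), 1 / 32000)
})

test_that("multi-channel and malformed audio are rejected with format errors", {
  stereo <- withr::local_tempfile(fileext = ".wav")
  # interleave two channels by hand through the low-level writer
  pcgseg:::write_wav(rep(c(0.1, -0.1), 100), 4000, stereo, channels = 2L)
  expect_error(read_record(stereo), "channels", class = "pcgseg_error_format")

  junk <- withr::local_tempfile(fileext = ".wav")
  writeLines("not audio at all", junk)
  expect_error(read_record(junk), class = "pcgseg_error_format")
  expect_error(read_record(file.path(tempdir(), "nope.wav")),
               class = "pcgseg_error_format")
})

test_that("an 8000-sample 4000 Hz file reads as a 2-second record", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_record(pcg_record(sin(seq_len(8000) / 20), 4000), path)
  rec <- read_record(path)
  expect_identical(length(rec$samples), 8000L)
  expect_equal(length(rec$samples) / rec$sampling_rate_hz, 2.0)
})

test_that("the printed eight-row example parses to the expected table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_example_region_file(path)
  rt <- read_region_table(path)
  expect_identical(nrow(rt), 8L)
  expect_identical(rt$start[1L], 1L)
  expect_identical(rt$end[1L], 555L)
  expect_identical(as.character(rt$class[1L]), "S1")
  expect_identical(rt$start[8L], 3755L)
  expect_identical(rt$end[8L], 4555L)
  expect_identical(as.character(rt$class[8L]), "diastolic")
})

test_that("region files parse across dialects: csv, header, bare classes", {
  for (sep in c("\t", ",")) {
    for (header in c(FALSE, TRUE)) {
      for (quote in c(TRUE, FALSE)) {
        path <- withr::local_tempfile(fileext = ".txt")
        write_example_region_file(path, sep = sep, header = header,
                                  quote = quote)
        rt <- read_region_table(path)
        expect_identical(nrow(rt), 8L)
        expect_identical(rt$end[8L], 4555L)
      }
    }
  }
})

test_that("structural violations are reported with row numbers", {
  gap <- withr::local_tempfile()
  writeLines(c("1\t555\tS1", "556\t900\tsystolic"), gap)
  expect_error(read_region_table(gap), "2.*gap",
               class = "pcgseg_error_region")

  overlap <- withr::local_tempfile()
  writeLines(c("1\t555\tS1", "500\t900\tsystolic"), overlap)
  expect_error(read_region_table(overlap), "overlap",
               class = "pcgseg_error_region")

  rev_limits <- withr::local_tempfile()
  writeLines("100\t50\tS1", rev_limits)
  expect_error(read_region_table(rev_limits), "start must be < end",
               class = "pcgseg_error_region")

  unknown <- withr::local_tempfile()
  writeLines("1\t100\tS3", unknown)
  expect_error(read_region_table(unknown), "unknown class",
               class = "pcgseg_error_region")

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_error(read_region_table(empty), "empty",
               class = "pcgseg_error_region")

  bad_order <- withr::local_tempfile()
  writeLines(c("1\t100\tS1", "100\t200\tS2"), bad_order)
  expect_warning(read_region_table(bad_order), "phase order")
})

test_that("expand_labels covers every sample under the shared-boundary rule", {
  rt <- example_region_table()
  labels <- expand_labels(rt, 4000)
  expect_identical(length(labels), 4555L)
  # boundary samples belong to the later region, the final row claims its end
  expect_identical(sum(labels == "systolic"), (1035L - 555L) + (3275L - 2795L))
  expect_identical(sum(labels == "S1"), (555L - 1L) + (2795L - 2235L))
  expect_identical(as.character(labels[555L]), "systolic")
  expect_identical(as.character(labels[4555L]), "diastolic")

  single <- region_table(1L, 11L, "S1")
  expect_identical(as.character(expand_labels(single, 100)),
                   rep("S1", 11L))
})

test_that("collapse_labels inverts expand_labels on random valid tables", {
  set.seed(42)
  for (i in 1:50) {
    rt <- random_region_table(sample(1:12, 1L))
    labels <- expand_labels(rt, 1000)
    expect_identical(length(labels), rt$end[nrow(rt)])
    back <- collapse_labels(labels)
    expect_identical(as.data.frame(back), as.data.frame(rt))
  }
})

test_that("collapse_labels handles degenerate sequences", {
  one_run <- label_seq(rep("diastolic", 100L), 1000)
  rt <- collapse_labels(one_run)
  expect_identical(as.data.frame(rt),
                   data.frame(start = 1L, end = 100L,
                              class = factor("diastolic",
                                             levels = pcg_classes())))
  # phase-order violations are encoded faithfully but warned about
  jumbled <- label_seq(rep(c("S1", "S2", "S1", "diastolic"), each = 3L), 1000)
  expect_warning(rt2 <- collapse_labels(jumbled), "phase order")
  expect_identical(nrow(rt2), 4L)
  expect_identical(as.character(rt2$class), c("S1", "S2", "S1", "diastolic"))
  expect_identical(rt2$end[4L], 12L)  # still covers all 12 samples
})

test_that("segment_record windows by floor(N / window) and conserves samples", {
  rate <- 4000L
  labels <- label_seq(rep(pcg_classes(), c(2000L, 2000L, 2000L, 3000L)), rate)
  feats <- seq_len(9000L) / 9000
  ds <- segment_record(feats, labels, window_seconds = 2, rate = rate,
                       record_id = "r1")
  expect_identical(nrow(ds), 1L)
  expect_identical(length(ds$features[[1L]]), 8000L)
  # conservation: windows x length + dropped == input
  expect_identical(nrow(ds) * 8000L + (9000L - nrow(ds) * 8000L), 9000L)

  ds2 <- segment_record(feats[1:8000], labels[1:8000], 2, rate)
  expect_identical(nrow(ds2), 1L)

  expect_warning(
    ds0 <- segment_record(feats[1:4555], labels[1:4555], 2, rate),
    "shorter")
  expect_identical(nrow(ds0), 0L)
})

test_that("segmentation conserves samples across random inputs", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(500:5000, 1L)
    rate <- sample(c(250L, 500L, 1000L), 1L)
    labels <- label_seq(rep(pcg_classes(),
                            c(n %/% 4L, n %/% 4L, n %/% 4L,
                              n - 3L * (n %/% 4L))), rate)
    wl <- as.integer(round(2 * rate))
    suppressWarnings(
      ds <- segment_record(runif(n), labels, 2, rate))
    expect_identical(nrow(ds), n %/% wl)
    expect_true(nrow(ds) * wl <= n)
    expect_true(n - nrow(ds) * wl < wl)
  }
})

test_that("region tables round-trip through files", {
  rt <- example_region_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_region_table(rt, path)
  expect_identical(as.data.frame(read_region_table(path)), as.data.frame(rt))
})

test_that("the shipped example annotation file parses", {
  path <- system.file("extdata", "example_regions.tsv", package = "pcgseg")
  rt <- read_region_table(path)
  expect_identical(nrow(rt), 8L)
  expect_identical(length(expand_labels(rt, 4000)), 4555L)
})
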