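# Shared fixtures and independent oracles for the test suite.

# The printed eight-row annotation example used across the I/O tests:
# four phases of two heart cycles over samples 1..4555.
example_region_rows <- function() {
  data.frame(
    start = c(1L, 555L, 1035L, 1515L, 2235L, 2795L, 3275L, 3755L),
    end = c(555L, 1035L, 1515L, 2235L, 2795L, 3275L, 3755L, 4555L),
    class = c("S1", "systolic", "S2", "diastolic",
              "S1", "systolic", "S2", "diastolic"),
    stringsAsFactors = FALSE
  )
}

example_region_table <- function() {
  rows <- example_region_rows()
  region_table(rows$start, rows$end, rows$class)
}

write_example_region_file <- function(path, sep = "\t", header = FALSE,
                                      quote = TRUE) {
  rows <- example_region_rows()
  cls <- if (quote) sprintf('"%s"', rows$class) else rows$class
  lines <- paste(rows$start, rows$end, cls, sep = sep)
  if (header) lines <- c(paste("start", "end", "class", sep = sep), lines)
  writeLines(lines, path)
  path
}

# random valid region table (cyclic phases, shared boundaries)
random_region_table <- function(n_regions = 8L, max_len = 50L) {
  lens <- sample(2:max_len, n_regions, replace = TRUE)
  start <- cumsum(c(1L, lens[-n_regions]))
  end <- c(start[-1L], start[n_regions] + lens[n_regions])
  first <- sample(4L, 1L)
  cls <- pcg_classes()[((first - 1L + seq_len(n_regions) - 1L) %% 4L) + 1L]
  region_table(start, end, cls)
}

# ---- independent EMD oracle -------------------------------------------------
# Deliberately separate code path from the package: natural-spline envelopes
# anchored at the raw extrema (no mirroring), a fixed number of sifting
# passes, no IMF/SD stopping logic. Used only for correlation-level
# agreement, never for exact values.
oracle_extrema <- function(x) {
  n <- length(x)
  i <- 2:(n - 1)
  list(maxima = i[x[i] > x[i - 1] & x[i] > x[i + 1]],
       minima = i[x[i] < x[i - 1] & x[i] < x[i + 1]])
}

oracle_sift_once <- function(x) {
  ex <- oracle_extrema(x)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L) return(NULL)
  n <- length(x)
  up <- stats::splinefun(ex$maxima, x[ex$maxima], method = "natural")(1:n)
  lo <- stats::splinefun(ex$minima, x[ex$minima], method = "natural")(1:n)
  x - (up + lo) / 2
}

oracle_emd <- function(x, n_imfs = 2L, sifts = 10L) {
  imfs <- list()
  res <- x
  for (k in seq_len(n_imfs)) {
    d <- res
    for (s in seq_len(sifts)) {
      d_new <- oracle_sift_once(d)
      if (is.null(d_new)) break
      d <- d_new
    }
    if (identical(d, res) && is.null(oracle_sift_once(res))) break
    imfs[[k]] <- d
    res <- res - d
  }
  list(imfs = imfs, residual = res)
}

# ---- hand-unrolled recurrent cells ------------------------------------------
# Written from the update equations with scalar arithmetic only; no package
# code, no matrix ops. Bias-free, as the equations are printed.
hand_gru_step <- function(wz, wr, wh, uz, ur, uh, x, h) {
  sig <- function(v) 1 / (1 + exp(-v))
  z <- sig(wz * x + uz * h)
  r <- sig(wr * x + ur * h)
  h_tilde <- tanh(wh * x + r * (uh * h))
  (1 - z) * h_tilde + z * h
}

hand_gru_run <- function(wz, wr, wh, uz, ur, uh, xs) {
  h <- 0
  out <- numeric(length(xs))
  for (t in seq_along(xs)) {
    h <- hand_gru_step(wz, wr, wh, uz, ur, uh, xs[t], h)
    out[t] <- h
  }
  out
}

# scalar bidirectional unroll: forward states then backward states per step
hand_bigru_run <- function(fwd, bwd, xs) {
  hf <- hand_gru_run(fwd[1], fwd[2], fwd[3], fwd[4], fwd[5], fwd[6], xs)
  hb <- rev(hand_gru_run(bwd[1], bwd[2], bwd[3], bwd[4], bwd[5], bwd[6],
                         rev(xs)))
  cbind(hf, hb)
}

hand_lstm_step <- function(wi, wf, wo, wg, ui, uf, uo, ug, x, h, c) {
  sig <- function(v) 1 / (1 + exp(-v))
  i_g <- sig(wi * x + ui * h)
  f_g <- sig(wf * x + uf * h)
  o_g <- sig(wo * x + uo * h)
  g <- tanh(wg * x + ug * h)
  c_new <- f_g * c + i_g * g
  list(h = o_g * tanh(c_new), c = c_new)
}

# ---- metric arithmetic oracle -----------------------------------------------
# Brute-force one-vs-rest counts by explicit enumeration over sample pairs.
brute_metrics <- function(truth, pred, cls) {
  tp <- sum(truth == cls & pred == cls)
  fn <- sum(truth == cls & pred != cls)
  fp <- sum(truth != cls & pred == cls)
  tn <- sum(truth != cls & pred != cls)
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  pp <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(se) && !is.na(pp) && se + pp > 0) {
    2 * pp * se / (pp + se)
  } else NA_real_
  c(se = se, sp = sp, pp = pp, f1 = f1,
    acc = (tp + tn) / length(truth))
}

# ---- small shared training fixture -------------------------------------------
# A compact synthetic benchmark reused by the model tests so the expensive
# training happens once per test run.
tiny_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_benchmark(
        n_records = 8L,
        cfg = synth_config(duration_s = 10, seed = 500),
        window_seconds = 2)
    }
    cache
  }
})
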