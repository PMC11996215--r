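#' Band-pass filter specification
#'
#' Settings for the Butterworth band-pass stage. `order` is the overall
#' filter order (pole count) of the band-pass transfer function; the default
#' is the 4th-order 60--150 Hz design used for heart sounds, whose passband
#' brackets the spectral content of the S1/S2 transients.
#'
#' @param order Even positive integer, total band-pass order (default 4).
#' @param low_cut_hz,high_cut_hz Passband edges in Hz (defaults 60 and 150).
#' @param zero_phase Apply the filter forward and backward (default `TRUE`),
#'   so burst onsets are not shifted relative to sample-aligned labels.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order = 4L, low_cut_hz = 60, high_cut_hz = 150,
                        zero_phase = TRUE) {
  order <- as.integer(order)
  if (is.na(order) || order < 2L || order %% 2L != 0L) {
    abort("`order` must be a positive even integer (band-pass pole count).",
          class = "pcgseg_error_config")
  }
  if (!(low_cut_hz > 0 && high_cut_hz > low_cut_hz)) {
    abort("Cutoffs must satisfy 0 < low_cut_hz < high_cut_hz.",
          class = "pcgseg_error_config")
  }
  structure(list(order = order, low_cut_hz = low_cut_hz,
                 high_cut_hz = high_cut_hz, zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Envelope extraction specification
#'
#' @param fir_length Length of the FIR Hilbert-transformer approximation
#'   (default 200). Internally the tap count is rounded up to the next odd
#'   number so the group delay is an integer number of samples and can be
#'   compensated exactly.
#' @param backend `"fir"` (windowed FIR Hilbert transformer, default) or
#'   `"fft"` (frequency-domain analytic signal). The two agree in the
#'   interior of a band-limited signal.
#' @return An `envelope_spec` list.
#' @export
envelope_spec <- function(fir_length = 200L, backend = c("fir", "fft")) {
  fir_length <- as.integer(fir_length)
  if (is.na(fir_length) || fir_length < 2L) {
    abort("`fir_length` must be an integer >= 2.",
          class = "pcgseg_error_config")
  }
  structure(list(fir_length = fir_length, backend = match.arg(backend)),
            class = "envelope_spec")
}

butter_design <- function(spec, rate) {
  nyq <- rate / 2
  if (spec$high_cut_hz >= nyq) {
    abort(sprintf(
      "high_cut_hz (%g) must be below the Nyquist frequency (%g Hz).",
      spec$high_cut_hz, nyq), class = "pcgseg_error_config")
  }
  signal::butter(spec$order %/% 2L,
                 c(spec$low_cut_hz, spec$high_cut_hz) / nyq, type = "pass")
}

#' Apply the Butterworth band-pass filter
#'
#' Filters a signal with the design in `spec`; with `zero_phase` the filter
#' runs forward and backward (squaring the magnitude response, cancelling
#' phase). Output length equals input length.
#'
#' @param x Numeric signal.
#' @param rate Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, rate, spec = filter_spec()) {
  if (length(x) < 3L * spec$order) {
    abort(sprintf("Signal too short to filter (%d samples, need >= %d).",
                  length(x), 3L * spec$order),
          class = "pcgseg_error_signal")
  }
  bf <- butter_design(spec, rate)
  y <- if (spec$zero_phase) signal::filtfilt(bf, as.double(x))
       else as.double(signal::filter(bf, as.double(x)))
  y[seq_along(x)]
}

#' Magnitude response of the band-pass design
#'
#' Evaluates the designed transfer function at given frequencies; with
#' `zero_phase` the forward-backward application squares the magnitude.
#'
#' @inheritParams bandpass
#' @param freq_hz Frequencies (Hz) at which to evaluate.
#' @return Numeric vector of gains in dB.
#' @export
bandpass_response_db <- function(freq_hz, rate, spec = filter_spec()) {
  bf <- butter_design(spec, rate)
  z <- exp(-1i * 2 * pi * freq_hz / rate)
  num <- vapply(z, function(zz) sum(bf$b * zz^(seq_along(bf$b) - 1L)),
                complex(1))
  den <- vapply(z, function(zz) sum(bf$a * zz^(seq_along(bf$a) - 1L)),
                complex(1))
  g <- 20 * log10(Mod(num / den))
  if (spec$zero_phase) 2 * g else g
}

#' Rescale a signal to a fixed amplitude range
#'
#' The default symmetric map `2 * (x - min) / (max - min) - 1` sends the
#' minimum to -1 and the maximum to +1. `method = "unit"` applies the plain
#' min-max map `(x - min) / (max - min)` onto `[0, 1]` instead. Both are
#' invariant under affine rescaling of the input, and the symmetric map is
#' idempotent.
#'
#' @param x Numeric signal, non-constant.
#' @param method `"symmetric"` (default, range `[-1, 1]`) or `"unit"`
#'   (range `[0, 1]`).
#' @return Rescaled numeric vector.
#' @export
normalize_signal <- function(x, method = c("symmetric", "unit")) {
  method <- match.arg(method)
  rng <- range(x)
  if (!all(is.finite(rng))) {
    abort("Signal contains non-finite values.", class = "pcgseg_error_signal")
  }
  if (rng[1] == rng[2]) {
    abort("Constant signal: amplitude range is zero, cannot normalize.",
          class = "pcgseg_error_degenerate")
  }
  u <- (x - rng[1]) / (rng[2] - rng[1])
  if (method == "symmetric") 2 * u - 1 else u
}

# windowed ideal Hilbert transformer, odd tap count => integer group delay
fir_hilbert_taps <- function(fir_length) {
  n_taps <- if (fir_length %% 2L == 0L) fir_length + 1L else fir_length
  m <- (n_taps - 1L) %/% 2L
  k <- -m:m
  h <- ifelse(k %% 2L != 0L, 2 / (pi * k), 0)
  w <- 0.54 + 0.46 * cos(pi * k / m)  # Hamming, centered
  list(h = h * w, delay = m)
}

#' Analytic signal of a real sequence
#'
#' Returns the complex analytic signal `x + i * H(x)`, where `H` is the
#' Hilbert transform. The `"fir"` backend convolves with a windowed FIR
#' Hilbert-transformer approximation (group delay compensated); the `"fft"`
#' backend zeroes the negative-frequency half of the spectrum. Away from the
#' sequence edges the two agree closely for band-limited signals.
#'
#' @param x Numeric signal, longer than the FIR length.
#' @param spec An [envelope_spec()].
#' @return Complex vector, same length as `x`; its modulus is the amplitude
#'   envelope.
#' @export
analytic_signal <- function(x, spec = envelope_spec()) {
  x <- as.double(x)
  n <- length(x)
  if (spec$backend == "fir") {
    if (n <= spec$fir_length) {
      abort(sprintf(
        "Signal (%d samples) must be longer than the FIR length (%d).",
        n, spec$fir_length), class = "pcgseg_error_signal")
    }
    ht <- fir_hilbert_taps(spec$fir_length)
    m <- ht$delay
    xp <- c(rep(0, m), x, rep(0, m))
    # full linear convolution, then take the delay-compensated center
    full <- stats::convolve(xp, rev(ht$h), type = "open")
    im <- full[(2L * m + 1L):(2L * m + n)]
    complex(real = x, imaginary = im)
  } else {
    if (n < 2L) {
      abort("Signal must have at least 2 samples.",
            class = "pcgseg_error_signal")
    }
    X <- stats::fft(x)
    mult <- numeric(n)
    if (n %% 2L == 0L) {
      mult[1L] <- 1
      mult[2:(n / 2)] <- 2
      mult[n / 2 + 1L] <- 1
    } else {
      mult[1L] <- 1
      mult[2:((n + 1L) / 2)] <- 2
    }
    stats::fft(X * mult, inverse = TRUE) / n
  }
}

#' Amplitude envelope via the analytic signal
#'
#' Pointwise modulus of [analytic_signal()]: non-negative, same length as
#' the input, and equal for `x` and `-x`.
#'
#' @inheritParams analytic_signal
#' @return Non-negative numeric vector.
#' @export
envelope_signal <- function(x, spec = envelope_spec()) {
  Mod(analytic_signal(x, spec))
}

#' Anti-aliased integer-factor decimation
#'
#' Optional rate reduction before model input (an 8th-order Chebyshev
#' low-pass at `0.8 / (2 * factor)` of the original rate, applied zero-phase,
#' then take every `factor`-th sample). The pipeline default is no
#' decimation.
#'
#' @param x Numeric signal.
#' @param factor Positive integer decimation factor; 1 is a no-op.
#' @return Numeric vector of length `ceiling(length(x) / factor)`.
#' @export
decimate_signal <- function(x, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    abort("`factor` must be a positive integer.", class = "pcgseg_error_config")
  }
  if (factor == 1L) return(as.double(x))
  signal::decimate(as.double(x), factor)
}

#' Full preprocessing configuration
#'
#' Defaults for the signal-conditioning chain and the EMD stage. Keys mirror
#' the config-file schema: `filter.order`, `filter.low_hz`, `filter.high_hz`,
#' `filter.zero_phase`, `envelope.fir_length`, `envelope.backend`,
#' `emd.levels`, `emd.sd_threshold`, `emd.max_sift_iterations`,
#' `decimate.factor`, `normalize.method`.
#'
#' @param filter A [filter_spec()].
#' @param envelope An [envelope_spec()].
#' @param emd A [sift_config()] plus decomposition `levels`.
#' @param decimate_factor Integer decimation factor applied to the raw
#'   signal before filtering (default 1 = none).
#' @param normalize_method Passed to [normalize_signal()].
#' @return A `pcg_config` list.
#' @export
pcg_config <- function(filter = filter_spec(), envelope = envelope_spec(),
                       emd = sift_config(), decimate_factor = 1L,
                       normalize_method = "symmetric") {
  structure(list(filter = filter, envelope = envelope, emd = emd,
                 decimate_factor = as.integer(decimate_factor),
                 normalize_method = normalize_method),
            class = "pcg_config")
}

#' Fingerprint of a preprocessing configuration
#'
#' A canonical string identifying the feature pipeline. Trained models store
#' it and refuse feature sequences produced under a different pipeline.
#'
#' @param cfg A [pcg_config()].
#' @return Character scalar.
#' @export
preprocess_fingerprint <- function(cfg) {
  paste0(
    "bp", cfg$filter$order, ":", cfg$filter$low_cut_hz, "-",
    cfg$filter$high_cut_hz, if (cfg$filter$zero_phase) "zp" else "",
    "|norm:", cfg$normalize_method,
    "|emd:L", cfg$emd$levels, ",sd", cfg$emd$sd_threshold,
    ",it", cfg$emd$max_sift_iterations,
    "|env:", cfg$envelope$backend, cfg$envelope$fir_length,
    "|dec:", cfg$decimate_factor
  )
}

#' Run the full signal-conditioning chain on a record
#'
#' Applies, in order: optional decimation, band-pass filter, amplitude
#' normalization, empirical mode decomposition keeping the first intrinsic
#' mode function, and the analytic-signal amplitude envelope. The result is
#' the non-negative feature sequence consumed by the sequence labelers, the
#' same length as the (possibly decimated) input.
#'
#' @param rec A [pcg_record()] or numeric vector (then `rate` is required).
#' @param cfg A [pcg_config()].
#' @param rate Sampling rate when `rec` is a bare vector.
#' @return Numeric feature vector with attributes `sampling_rate_hz` and
#'   `fingerprint`.
#' @export
preprocess_record <- function(rec, cfg = pcg_config(), rate = NULL) {
  if (is.numeric(rec)) {
    if (is.null(rate)) abort("`rate` is required for a bare numeric vector.")
    rec <- pcg_record(rec, rate)
  }
  x <- rec$samples
  rate <- rec$sampling_rate_hz
  if (cfg$decimate_factor > 1L) {
    x <- decimate_signal(x, cfg$decimate_factor)
    rate <- as.integer(round(rate / cfg$decimate_factor))
  }
  x <- bandpass(x, rate, cfg$filter)
  x <- normalize_signal(x, cfg$normalize_method)
  x <- first_imf(x, cfg$emd)
  feat <- envelope_signal(x, cfg$envelope)
  attr(feat, "sampling_rate_hz") <- rate
  attr(feat, "fingerprint") <- preprocess_fingerprint(cfg)
  feat
}

#' Per-stage outputs of the preprocessing chain
#'
#' Returns every intermediate stage (filtered, normalized, first IMF,
#' envelope) in long form, for diagnostics and plotting.
#'
#' @inheritParams preprocess_record
#' @return A tibble with columns `sample`, `time_s`, `stage`, `value`, of
#'   class `pcg_stages`.
#' @export
preprocess_stages <- function(rec, cfg = pcg_config(), rate = NULL) {
  if (is.numeric(rec)) {
    if (is.null(rate)) abort("`rate` is required for a bare numeric vector.")
    rec <- pcg_record(rec, rate)
  }
  x <- rec$samples
  rate <- rec$sampling_rate_hz
  if (cfg$decimate_factor > 1L) {
    x <- decimate_signal(x, cfg$decimate_factor)
    rate <- as.integer(round(rate / cfg$decimate_factor))
  }
  filtered <- bandpass(x, rate, cfg$filter)
  normalized <- normalize_signal(filtered, cfg$normalize_method)
  imf1 <- first_imf(normalized, cfg$emd)
  env <- envelope_signal(imf1, cfg$envelope)
  n <- length(x)
  out <- tibble(
    sample = rep(seq_len(n), 4L),
    time_s = rep((seq_len(n) - 1L) / rate, 4L),
    stage = factor(rep(c("filtered", "normalized", "imf1", "envelope"),
                       each = n),
                   levels = c("filtered", "normalized", "imf1", "envelope")),
    value = c(filtered, normalized, as.double(imf1), env)
  )
  class(out) <- c("pcg_stages", class(out))
  out
}
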