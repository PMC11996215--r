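#' Synthetic phonocardiogram configuration
#'
#' The generator emulates the statistical structure the segmentation
#' pipeline assumes: alternating S1 -> systole -> S2 -> diastole cycles;
#' S1/S2 as Gaussian-amplitude-modulated sinusoidal bursts whose spectral
#' content lies inside the 60--150 Hz analysis band; quieter systolic and
#' diastolic intervals; per-cycle heart-rate jitter absorbed by diastole
#' (where physiological rate variation mostly lives); optional murmur-band
#' noise in one interval; and additive broadband noise at a configurable
#' SNR.
#'
#' @param sampling_rate_hz Sampling rate (default 1000; use 4000 to mimic
#'   the public heart-sound corpora).
#' @param duration_s Record duration in seconds.
#' @param heart_rate_bpm Mean heart rate.
#' @param hr_jitter Standard deviation of the per-cycle multiplicative
#'   jitter applied to the diastolic interval (0 disables).
#' @param s1,s2 Lists with `duration_ms`, `freq_hz`, `amplitude` for the two
#'   heart-sound bursts (defaults: S1 120 ms at 80 Hz, amplitude 1; S2 90 ms
#'   at 110 Hz, amplitude 0.8).
#' @param systole_fraction Fraction of the nominal cycle from S1 onset to S2
#'   onset (default 0.35); diastole takes the remainder.
#' @param murmur `"off"` (default), `"systolic"` or `"diastolic"`: adds
#'   band-limited noise of `murmur_amplitude` to that interval.
#' @param murmur_amplitude RMS amplitude of the murmur noise.
#' @param noise_snr_db Additive white-noise level: the noise standard
#'   deviation is `A_S1 * 10^(-snr/20)` relative to the S1 burst peak
#'   (default 20 dB).
#' @param seed Integer seed; the same seed reproduces the same record.
#' @return A `synth_config` list.
#' @export
synth_config <- function(sampling_rate_hz = 1000L, duration_s = 20,
                         heart_rate_bpm = 70, hr_jitter = 0.05,
                         s1 = list(duration_ms = 120, freq_hz = 80,
                                   amplitude = 1),
                         s2 = list(duration_ms = 90, freq_hz = 110,
                                   amplitude = 0.8),
                         systole_fraction = 0.35,
                         murmur = c("off", "systolic", "diastolic"),
                         murmur_amplitude = 0.15,
                         noise_snr_db = 20, seed = 1L) {
  murmur <- match.arg(murmur)
  cfg <- list(sampling_rate_hz = as.integer(sampling_rate_hz),
              duration_s = duration_s, heart_rate_bpm = heart_rate_bpm,
              hr_jitter = hr_jitter,
              s1 = utils::modifyList(list(duration_ms = 120, freq_hz = 80,
                                          amplitude = 1), s1),
              s2 = utils::modifyList(list(duration_ms = 90, freq_hz = 110,
                                          amplitude = 0.8), s2),
              systole_fraction = systole_fraction, murmur = murmur,
              murmur_amplitude = murmur_amplitude,
              noise_snr_db = noise_snr_db, seed = as.integer(seed))
  cycle_s <- 60 / cfg$heart_rate_bpm
  s1_s <- cfg$s1$duration_ms / 1000
  s2_s <- cfg$s2$duration_ms / 1000
  if (s1_s + s2_s >= cycle_s * 0.9) {
    abort("Burst durations do not fit in one cycle at this heart rate.",
          class = "pcgseg_error_config")
  }
  if (cfg$systole_fraction * cycle_s <= s1_s) {
    abort("systole_fraction too small: systolic interval underflows S1.",
          class = "pcgseg_error_config")
  }
  structure(cfg, class = "synth_config")
}

# Gaussian-windowed sinusoidal burst of n samples (sd = duration / 6)
gauss_burst <- function(n, freq_hz, rate, amplitude) {
  t <- (seq_len(n) - 1) / rate
  center <- (n - 1) / (2 * rate)
  sd_s <- (n / rate) / 6
  amplitude * exp(-(t - center)^2 / (2 * sd_s^2)) * sin(2 * pi * freq_hz * t)
}

# phase durations (samples) for one cycle; jitter multiplies diastole only
cycle_phases <- function(cfg, jitter_factor = 1) {
  rate <- cfg$sampling_rate_hz
  cycle_s <- 60 / cfg$heart_rate_bpm
  n_s1 <- max(2L, round(cfg$s1$duration_ms / 1000 * rate))
  n_s2 <- max(2L, round(cfg$s2$duration_ms / 1000 * rate))
  n_sys <- max(2L, round(cfg$systole_fraction * cycle_s * rate) - n_s1)
  n_dia_nominal <- round(cycle_s * rate) - n_s1 - n_sys - n_s2
  n_dia <- max(2L, round(n_dia_nominal * jitter_factor))
  c(S1 = n_s1, systolic = n_sys, S2 = n_s2, diastolic = n_dia)
}

#' Simulate one heart cycle
#'
#' One heartbeat: an S1 burst, a low-level systolic interval (optionally
#' carrying murmur-band noise), an S2 burst, and a longer low-level
#' diastolic interval. Region rows abut with shared boundaries. Broadband
#' noise is *not* added here — [simulate_record()] adds it over the whole
#' record so the noise floor is stationary.
#'
#' @param cfg A [synth_config()].
#' @param jitter_factor Multiplicative factor on the diastolic duration.
#' @return List with `samples` (numeric) and `regions` (start/end/class
#'   tibble rows for the cycle, 1-based, shared boundaries).
#' @export
simulate_cycle <- function(cfg, jitter_factor = 1) {
  rate <- cfg$sampling_rate_hz
  ph <- cycle_phases(cfg, jitter_factor)
  n <- sum(ph)
  x <- numeric(n)
  i_s1 <- seq_len(ph[["S1"]])
  x[i_s1] <- gauss_burst(ph[["S1"]], cfg$s1$freq_hz, rate, cfg$s1$amplitude)
  i_s2 <- ph[["S1"]] + ph[["systolic"]] + seq_len(ph[["S2"]])
  x[i_s2] <- gauss_burst(ph[["S2"]], cfg$s2$freq_hz, rate, cfg$s2$amplitude)
  if (cfg$murmur != "off") {
    idx <- if (cfg$murmur == "systolic") {
      ph[["S1"]] + seq_len(ph[["systolic"]])
    } else {
      ph[["S1"]] + ph[["systolic"]] + ph[["S2"]] + seq_len(ph[["diastolic"]])
    }
    # murmur: band-limited noise inside the analysis band
    raw <- stats::rnorm(length(idx) + 200L)
    bf <- signal::butter(2, c(60, min(150, rate / 2 - 1)) / (rate / 2), "pass")
    flt <- signal::filtfilt(bf, raw)[100L + seq_along(idx)]
    x[idx] <- x[idx] + cfg$murmur_amplitude * flt / stats::sd(flt)
  }
  # shared-boundary rows: phase k occupies exactly ph[k] samples, so the
  # row limits are run boundaries (boundary sample belongs to the later
  # region; the final row claims its end sample)
  starts <- cumsum(c(1L, ph[-4L]))
  ends <- c(starts[-1L], n)
  regions <- tibble(start = as.integer(starts), end = as.integer(ends),
                    class = factor(PCG_CLASSES, levels = PCG_CLASSES))
  list(samples = x, regions = regions, phase_lengths = ph)
}

#' Simulate a labeled PCG record
#'
#' Concatenates per-cycle simulations with jittered diastole until the
#' requested duration is reached, truncates to the exact sample count,
#' adds white noise at the configured SNR, and emits the matching region
#' table covering every sample. Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param record_id,site Provenance for the emitted [pcg_record()].
#' @return List with `record` ([pcg_record()]) and `regions`
#'   ([region_table()]).
#' @export
simulate_record <- function(cfg = synth_config(), record_id = "synthetic",
                            site = "unknown") {
  n_total <- round(cfg$duration_s * cfg$sampling_rate_hz)
  if (n_total < sum(cycle_phases(cfg))) {
    abort("duration_s is shorter than one heart cycle.",
          class = "pcgseg_error_config")
  }
  sim <- withr::with_seed(cfg$seed, {
    samples <- numeric(0)
    run_len <- integer(0)
    n_acc <- 0L
    while (n_acc < n_total) {
      jf <- if (cfg$hr_jitter > 0) {
        max(0.2, 1 + stats::rnorm(1L, 0, cfg$hr_jitter))
      } else 1
      cyc <- simulate_cycle(cfg, jf)
      samples <- c(samples, cyc$samples)
      run_len <- c(run_len, cyc$phase_lengths)
      n_acc <- n_acc + length(cyc$samples)
    }
    noise_sd <- cfg$s1$amplitude * 10^(-cfg$noise_snr_db / 20)
    samples <- samples + stats::rnorm(length(samples), 0, noise_sd)
    list(samples = samples, run_len = run_len)
  })
  # per-sample label runs across cycles, truncated to the exact duration,
  # then run-length encoded into the shared-boundary region form
  labels <- rep(rep(PCG_CLASSES, length.out = length(sim$run_len)),
                sim$run_len)[seq_len(n_total)]
  regions <- suppressWarnings(collapse_labels(label_seq(labels,
                                                        cfg$sampling_rate_hz)))
  rec <- pcg_record(sim$samples[seq_len(n_total)], cfg$sampling_rate_hz,
                    record_id = record_id, site = site)
  list(record = rec, regions = regions)
}

#' Build a train/test benchmark from synthetic records
#'
#' Generates `n_records` synthetic PCGs (seeds derived from `cfg$seed`,
#' sites cycled AV/PV/TV/MV), runs the full preprocessing chain on each,
#' expands the region tables to per-sample labels, windows everything with
#' [segment_record()], and splits by record at `train_fraction`.
#'
#' @param n_records Number of records (>= 2).
#' @param cfg A [synth_config()]; per-record seeds are `cfg$seed + i`.
#' @param preprocess_cfg A [pcg_config()] for the feature chain.
#' @param window_seconds Window duration (default 2 s).
#' @param train_fraction Fraction of records in the training split.
#' @param split_seed Seed for the record-level split shuffle.
#' @return List with `train` and `test` [segment_dataset()]s.
#' @export
make_benchmark <- function(n_records = 10L, cfg = synth_config(),
                           preprocess_cfg = pcg_config(),
                           window_seconds = 2, train_fraction = 0.7,
                           split_seed = cfg$seed) {
  if (n_records < 2L) {
    abort("`n_records` must be >= 2 (the split needs both sides).",
          class = "pcgseg_error_config")
  }
  sites <- rep(c("AV", "PV", "TV", "MV"), length.out = n_records)
  parts <- lapply(seq_len(n_records), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    sim <- simulate_record(cfg_i, record_id = sprintf("synth%03d", i),
                           site = sites[i])
    feat <- preprocess_record(sim$record, preprocess_cfg)
    labels <- expand_labels(sim$regions, cfg$sampling_rate_hz)
    segment_record(feat, labels, window_seconds = window_seconds,
                   rate = attr(feat, "sampling_rate_hz"),
                   record_id = sim$record$record_id, site = sites[i])
  })
  all_ds <- bind_segments(parts)
  split_by_record(all_ds, train_fraction = train_fraction, seed = split_seed)
}
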