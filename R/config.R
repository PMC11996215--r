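#' Load a pipeline configuration file
#'
#' Reads a YAML file whose sections override the package defaults. The
#' schema (all keys optional):
#'
#' ```yaml
#' filter:    {order: 4, low_hz: 60, high_hz: 150, zero_phase: true}
#' envelope:  {fir_length: 200, backend: fir}
#' emd:       {levels: 3, sd_threshold: 0.2, max_sift_iterations: 100}
#' decimate:  {factor: 1}
#' normalize: {method: symmetric}
#' model:     {architecture: bigru, hidden_units: 200, learning_rate: 0.001,
#'             epochs: 200, batch_size: 16, train_fraction: 0.7, seed: 1}
#' synth:     {sampling_rate_hz: 1000, duration_s: 20, heart_rate_bpm: 70,
#'             noise_snr_db: 20, seed: 1}
#' window_seconds: 2
#' ```
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list merged over the file values (CLI flags).
#' @return A list with elements `preprocess` ([pcg_config()]), `model`
#'   ([model_config()]), `synth` ([synth_config()]), and `window_seconds`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  raw <- if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("Config file not found: '%s'.", path),
            class = "pcgseg_error_config")
    }
    yaml::read_yaml(path)
  } else {
    list()
  }
  raw <- utils::modifyList(raw, overrides)
  g <- function(section, key, default) {
    v <- raw[[section]][[key]]
    if (is.null(v)) default else v
  }
  filter <- filter_spec(
    order = g("filter", "order", 4L),
    low_cut_hz = g("filter", "low_hz", 60),
    high_cut_hz = g("filter", "high_hz", 150),
    zero_phase = g("filter", "zero_phase", TRUE))
  env <- envelope_spec(
    fir_length = g("envelope", "fir_length", 200L),
    backend = g("envelope", "backend", "fir"))
  emd <- sift_config(
    sd_threshold = g("emd", "sd_threshold", 0.2),
    max_sift_iterations = g("emd", "max_sift_iterations", 100L),
    levels = g("emd", "levels", 3L))
  pre <- pcg_config(filter = filter, envelope = env, emd = emd,
                    decimate_factor = g("decimate", "factor", 1L),
                    normalize_method = g("normalize", "method", "symmetric"))
  model <- model_config(
    architecture = g("model", "architecture", "bigru"),
    hidden_units = g("model", "hidden_units", 200L),
    learning_rate = g("model", "learning_rate", 0.001),
    epochs = raw[["model"]][["epochs"]],
    batch_size = g("model", "batch_size", 16L),
    train_fraction = g("model", "train_fraction", 0.7),
    seed = g("model", "seed", 1L))
  synth_keys <- raw[["synth"]] %||% list()
  synth <- do.call(synth_config, synth_keys)
  list(preprocess = pre, model = model, synth = synth,
       window_seconds = raw[["window_seconds"]] %||% 2)
}
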