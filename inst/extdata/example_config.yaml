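# Example pipeline configuration: every key is optional and defaults to the
# values shown in ?load_config.
filter:    {order: 4, low_hz: 60, high_hz: 150, zero_phase: true}
envelope:  {fir_length: 200, backend: fir}
emd:       {levels: 3, sd_threshold: 0.2, max_sift_iterations: 100}
normalize: {method: symmetric}
decimate:  {factor: 1}
model:     {architecture: bigru, hidden_units: 200, learning_rate: 0.001,
            batch_size: 16, train_fraction: 0.7, seed: 1}
synth:     {sampling_rate_hz: 1000, duration_s: 20, heart_rate_bpm: 70,
            noise_snr_db: 20, seed: 1}
window_seconds: 2
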