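# pcgseg

Per-sample segmentation of phonocardiogram (PCG) recordings into the four
cardiac phases: **S1** (first heart sound), **systole**, **S2** (second
heart sound), **diastole**.

Automated auscultation analysis — murmur detection, valve-disease
screening — starts by locating these phases. `pcgseg` implements a complete
segmentation pipeline:

1. **Conditioning.** A 4th-order Butterworth band-pass (60–150 Hz, applied
   zero-phase) isolates the heart-sound band; amplitudes are normalized to
   [−1, +1]; empirical mode decomposition (EMD, the sifting procedure)
   extracts the first intrinsic mode function; the Hilbert analytic-signal
   envelope |x + i·H(x)| (length-200 FIR transformer, or an FFT backend)
   yields a non-negative feature sequence in which the S1/S2 bursts stand
   out.
2. **Labeling.** A recurrent sequence labeler — GRU, bidirectional GRU or
   bidirectional LSTM, written from the gate equations with
   backpropagation-through-time and Adam in compiled code — assigns each
   sample one of the four classes through a shared per-step linear layer
   and softmax:

   z_t = σ(w_zx·x_t + u_zh·h_{t−1}),  r_t = σ(w_rx·x_t + u_rh·h_{t−1}),
   h̃_t = tanh(w_hx·x_t + r_t ⊙ u_hh·h_{t−1}),  h_t = (1−z_t)⊙h̃_t + z_t⊙h_{t−1};

   bidirectional variants concatenate a start→end and an end→start pass.
3. **Evaluation.** Per-class one-vs-rest accuracy, sensitivity (Se),
   precision (P+), specificity (Sp) and F1, reported per auscultation site
   (AV/PV/TV/MV) and pooled.

Recordings are plain mono WAV; annotations are three-column region tables
(start limit, end limit, class) over 1-based sample indices with shared
boundaries. A synthetic PCG generator with exact labels makes every stage —
including end-to-end training — runnable with no external data.

## Worked example

Simulate a labeled record, preprocess it, train a small bidirectional GRU
on a synthetic benchmark, and segment a fresh recording:

```r
library(pcgseg)

# a 30-record benchmark: simulate, preprocess, window, split 70/30 by record
# (about two minutes of training on one core)
bench <- make_benchmark(n_records = 30,
                        cfg = synth_config(duration_s = 20, seed = 100))
model <- train_segmenter(bench, model_config("bigru", hidden_units = 50,
                                             epochs = 30, seed = 42))
glance(model)
#> # A tibble: 1 × 6
#>   architecture hidden_units n_parameters epochs final_loss final_accuracy
#>   <chr>               <int>        <int>  <int>      <dbl>          <dbl>
#> 1 bigru                  50        16004     30      0.161          0.947

evaluate_model(model, bench$test, group_by = NULL)
#>   group n_samples accuracy sensitivity precision specificity   f1
#> 1   ALL    180000    94.92        91.4     93.77       97.96 92.5
```

`accuracy` is the fraction of individual samples labeled correctly (94.92%
of the 180 000 held-out samples here); the other columns are macro averages
of the per-class one-vs-rest panel. Segmenting a fresh recording and
collapsing the per-sample labels back to region rows:

```r
sim <- simulate_record(synth_config(duration_s = 10, seed = 777))
feat <- preprocess_record(sim$record)
pred <- predict_labels(model, feat)
head(collapse_labels(pred), 5)   # raw argmax stream; short spurious runs
#>   start end    class          # are kept (and warned about), no smoothing
#> 1     1   3 systolic
#> 2     3 120       S1
#> 3   120 303 systolic
#> 4   303 311       S1
#> 5   311 386       S2
```

At the package's benchmark scale (100 records of 20 s at 1000 Hz, 50 hidden
units, 30 epochs) the bidirectional GRU reaches ~99% held-out per-sample
accuracy, and at a matched 15-epoch budget on 50 records the architectures
rank Bi-GRU > Bi-LSTM > GRU by macro F1; see the vignette for what the
synthetic benchmark does and does not demonstrate.

There is also a command-line interface over the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pcgseg", package = "pcgseg"))')
$CLI simulate --out data --n 4 --seed 5
$CLI train --data data --out run
$CLI segment --model run/checkpoint.rds data/synth001_AV.wav --out out
```

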