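# driftgate

Drift-gated incremental classification of fixed-length time series.

## The problem

A classifier trained once on a batch of biosignal recordings — periodic
plant surface potentials, ECG beats, speech-emotion features, crop
reflectance series — is deployed against a stream of new data. Over time
the incoming distribution moves: concept drift, elevated noise, anomalous
spikes, missing points. Retraining a deep network for every batch is
expensive; ignoring the drift costs accuracy.

`driftgate` implements a middle road: the deep classifier stays frozen, and
a cheap, statistically controlled gate decides per update window whether a
lightweight preprocessor should rewrite the window toward training-data
dynamics before classification.

## The method

For training data X_train and each new window X_new (both min-max
normalized with the training statistics, Eq. `X' = (X − X_min)/(X_max −
X_min)`):

1. **Binned feature distributions.** Each of the L time points is a
   feature. Equal-interval bins are fit per feature on the old data
   (`(Max − Min)/N` bin width, N = 10 by default) and frozen; histograms
   are smoothed with a pseudo-count ε per bin.
2. **Drift score.** Per feature i, the Kullback–Leibler divergence
   `KL(f_i_old ‖ f_i_new) = Σ p ln(p/q)` (nats); the drift score is the
   mean over features, `D = (1/n) Σ_i KL_i`.
3. **Gate.** If `D ≥ t` the window is rewritten by the preprocessor, else
   it is classified as-is. The threshold t can be set per dataset (see
   `dataset_presets()`) or calibrated as a quantile of the bootstrap null
   distribution of D (`calibrate_threshold()`).
4. **Preprocessor.** An extreme learning machine (5 inputs, 32 sigmoid
   hidden nodes, 1 output; random frozen input weights, least-squares
   output weights) regresses every point on its surrounding context, and a
   residual-gated repair cascade plus an adaptive smoothing stage replaces
   anomalous points and suppresses excess noise.
5. **Classifier.** Two stacked LSTM layers (dropout 0.5 after each), dense
   softmax output, Adam with learning-rate decay, categorical
   cross-entropy — trained exactly once on the old data and never refit.
6. **Metrics.** Accuracy, sensitivity, specificity, F1 (one-vs-rest, micro
   or macro averaged) and the rank-form AUC
   `(Σ_{i∈pos} rank_i − M(1+M)/2)/(M·N)` per window.

## Worked example

```r
library(driftgate)

# a synthetic stream: 3 sinusoid classes, 300 training samples,
# 5 windows of 150; windows 2 and 4 carry extra noise + 5% spikes
g <- generate_scenario(default_scenario(seed = 1))

cfg <- pipeline_config(
  classifier = classifier_config(units = 16, epochs = 25, seed = 1),
  seed = 1)
pipe <- fit_pipeline(g$train, cfg, window_size = 150)
res <- run_stream(pipe, g$windows)
res
```

```
<stream_result> 5 windows, 2 updates (t = 0.05722)
  win 1: D = 0.04107 [pass]   ACC 1.0000 AUC 1.0000
  win 2: D = 0.14500 [UPDATE] ACC 0.9667 AUC 0.9907
  win 3: D = 0.03237 [pass]   ACC 1.0000 AUC 1.0000
  win 4: D = 0.13776 [UPDATE] ACC 0.9667 AUC 1.0000
  win 5: D = 0.03738 [pass]   ACC 1.0000 AUC 1.0000
```

Reading: the calibrated gate (t = 0.057, the 0.95 null quantile) stays
silent on the three clean windows (D ≈ 0.04) and fires on the two
corrupted ones (D ≈ 0.14). With the preprocessor the corrupted windows
classify at 96.7% against 93.7% for the same frozen classifier on the raw
windows (`run_stream(pipe, g$windows, threshold = Inf)`).

## Data formats

`read_series()` / `write_series()` support a wide CSV
(`id,label,t0,...,t{L-1}`, header mandatory, comma delimiter, period
decimal separator):

```
id,label,t0,t1,t2
0,0,0.12,0.54,0.33
1,1,0.98,0.11,0.07
2,0,0.25,0.61,0.40
```

and a binary array bundle (RDS) holding `values`, `labels`, `class_names`
that round-trips bit-exactly.

## Command line

```sh
inst/exec/driftgate simulate out/sim 1          # write a synthetic stream
inst/exec/driftgate train data.csv cfg.json out/run
inst/exec/driftgate stream out/run              # JSONL + metrics CSV
inst/exec/driftgate calibrate data.csv cfg.json 150
inst/exec/driftgate report out/run
```

The JSON config mirrors `pipeline_config()`; see `?read_config`.

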