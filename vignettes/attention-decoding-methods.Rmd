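---
title: "Decoding auditory attention from EEG correlation graphs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding auditory attention from EEG correlation graphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aadgraph)
```

## The problem

In a two-speaker ("cocktail party") listening situation, a listener's
scalp EEG carries a signature of which speaker they attend to.
Decoding that signature — selective auditory attention detection — is
the core measurement behind neuro-steered hearing aids and several
brain–computer interface designs.  Classical decoders (temporal
response functions) need the speech stimuli; this package implements a
stimulus-free alternative that classifies attend-left versus
attend-right from the EEG alone, using the spatial structure of
functional connectivity together with temporal self-attention.

## The pipeline

1. **Preprocessing** (`normalize_recording()`, `window_segments()`).
   Each trial is z-scored per channel (population convention, divisor
   $n$) and sliced into Hann-windowed segments of configurable duration.
   Normalization statistics are computed per trial, not pooled across
   trials or subjects: slow amplitude drift between recordings is the
   dominant nuisance in EEG classification, and per-trial scaling
   removes it without leaking information across the dataset.  Pooled
   normalization would be a reasonable sensitivity analysis but is not
   the default.
   The periodic Hann convention $w_k = \tfrac12(1 - \cos 2\pi k/N)$,
   $k = 0,\dots,N-1$, is used, so the first taper coefficient is exactly
   zero and the last is $O(1/N^2)$.

2. **Graph generation** (`pcc_matrix()`, `build_graph()`).  For every
   segment the Pearson correlation
   $$ r_{xy} = \frac{n\sum x_i y_i - \sum x_i \sum y_i}
      {\sqrt{n\sum x_i^2 - (\sum x_i)^2}\sqrt{n\sum y_i^2 - (\sum y_i)^2}} $$
   is evaluated for every electrode pair.  Electrode pairs with
   $r > 0.7$ become edges; electrodes left without any edge are removed.
   The result is one binary electrode graph per segment, with each
   surviving electrode's windowed series as its node feature.

3. **Classification** (`model_forward()`, `run_cv()`).  A hybrid
   network: transformer encoder layers over the time axis produce a
   contextualized series per electrode; GraphSAGE, GCN and multi-head
   graph-attention layers propagate information over the electrode
   graph; global mean pooling and a linear head produce the two class
   logits.  Training is mini-batch Adam on cross-entropy under k-fold
   cross-validation.

## The model, precisely

**Temporal module.**  A segment with $n$ surviving electrodes and $T$
samples enters as a $T \times n$ matrix (tokens = time steps).  It is
projected to width $d_{\text{model}}$ by the rows of a montage-indexed
input matrix — each electrode owns one row, which is how electrode
identity survives variable graph sizes — plus an optional sinusoidal
positional encoding.  Each encoder layer is standard post-norm
multi-head self-attention,
$\mathrm{Attention}(Q,K,V) = \mathrm{softmax}(QK^\top/\sqrt{d_k})\,V$,
followed by a position-wise feed-forward sublayer, both with residual
connections and layer normalization.  Two encoder layers are the
default.  The output is un-projected back to the surviving electrodes
(montage-indexed columns) and transposed, so each electrode receives
its contextualized series; a learned $T \times d_{\text{node}}$
projection turns that series into the node feature.

An `encoder_decoder` mode adds one decoder layer: a single learned
query cross-attends to the encoder states and the resulting context
row is broadcast-added back onto the states.  For a classification
task no output sequence exists, so a single-query decoder is the
closest well-defined reading; `encoder_only` is the default because
it needs no such interpretive choice.

**Spatial module.**  On the electrode graph with binary adjacency $A$:

* GraphSAGE (×2): $x_i' = W_1 x_i + W_2 \cdot
  \operatorname{mean}_{j \in N(i)} x_j$, with an empty neighborhood
  contributing a zero vector (unreachable in practice, since isolated
  nodes are pruned).
* GCN (×1): $H' = \sigma(\tilde D^{-1/2}\tilde A \tilde D^{-1/2} H W)$
  with $\tilde A = A + I$ and $\sigma$ = LeakyReLU.
* Graph attention (×2): per head
  $\alpha_{ij} = \operatorname{softmax}_j
  (\mathrm{LeakyReLU}(a^\top[Wx_i \,\|\, Wx_j]))$ over $N(i)$ *plus a
  self-loop*, then $x_i' = \sum_j \alpha_{ij} W x_j$.  Hidden layers
  concatenate the $K$ heads; the final layer averages them.  With
  $K = 1$ and identity activation the update is exactly the
  single-head attention rule (asserted to $10^{-12}$ in the tests).
  The self-loop is added because the bare rule discards the node's
  own features and makes degree-1 graphs brittle.

The aggregation rule of GraphSAGE carries no activation of its own; the
network applies LeakyReLU (the single activation used throughout,
negative slope 0.01) between stacked spatial layers.  The readout is
global mean pooling over nodes, dropout, and a linear map to two
logits — the published architecture leaves the readout unspecified,
and mean pooling is the minimal permutation-invariant choice.

**Training.**  Adam (lr $10^{-3}$, canonical moment constants),
softmax cross-entropy, batch size 64, 15 epochs per fold, dropout 0.2
on the pooled vector, 4-fold cross-validation, every fold trained from
a fresh fold-seeded initialization.  All forward/backward arithmetic
is implemented in the package (analytic backpropagation through every
layer) and validated against finite differences and brute-force layer
oracles in the test suite.

## Tunable parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `graph.threshold` | 0.7 | edge rule $r > 0.7$; `absolute` mode thresholds the magnitude |
| `preprocess.window_s` | 10 s | segment (and token-sequence) length |
| `preprocess.overlap` | 0 | windows do not cross trial boundaries |
| `model.d_model` | 64 | transformer token width |
| `model.gat_heads` / `gat_head_dim` | 4 / 16 | graph-attention geometry |
| `train.lr`, `batch_size`, `epochs` | 1e-3, 64, 15 | published recipe |
| `train.group_by` | `"trial"` | fold granularity (see below) |

The signed threshold is the default because it is the literal pruning
rule; `absolute` mode is provided as an ablation switch since strong
anti-correlation is plausibly informative.  Fold assignment defaults to
trial granularity: segment-level splits of overlapping windows leak
information between train and validation; `"none"` restores
segment-level splitting for comparability.

The positive class for precision/recall/F1 is attend-left,
configurable via `train_config(positive_class=)` — class-anchored
metrics require a convention and the published tables do not name one.

## What the synthetic generator emulates — and what it does not

`generate_trial()` implements a latent-source model
$x = w\,s_{\text{block}} + v\,g + u\,e$ per channel, all sources being
unit-variance $1/f$-colored noise.  With
$w = \sqrt{\rho_{\text{in}} - \rho_{\text{out}}}$,
$v = \sqrt{\rho_{\text{out}}}$, and $u$ chosen for unit variance, the
pairwise correlation is exactly $\rho_{\text{in}}$ (default 0.9)
inside the attended side's electrode block (left hemisphere F3/C3/P3/T7
for attend-left, right hemisphere F4/C4/P4/T8 for attend-right) and
$\rho_{\text{out}}$ (default 0.1) for every other pair.  Since
$\rho_{\text{out}} < 0.7 < \rho_{\text{in}}$, pruning separates the
blocks by design: at 10 s windows and 64 Hz the surviving node set
equals the active block in ≥ 99% of trials.

Deliberate properties: the class signal lives *only* in second-order
spatial structure — channel means and variances are identical across
classes (verified by a two-sample test in the suite) — because that is
precisely the mechanism a correlation-graph pipeline claims to exploit.
An amplitude artifact would make the benchmark trivially separable by
other means.

Deliberate non-properties: no auditory-cortex forward model, no speech
envelopes, no HRTF or ear geometry, no artifacts, no inter-subject
variability beyond independent noise.  Passing the end-to-end checks
therefore demonstrates that the architecture can learn the stated
connectivity mechanism, not that it reaches any particular accuracy on
real competing-speaker EEG.

## Numerical choices and degenerate inputs

* Zero-variance channels: z-scoring maps them to zeros with a flag;
  the correlation of a flat channel is defined as 0, so it can never
  pass the edge threshold and never divides by zero.
* Correlations are clamped to $[-1, 1]$ only against floating-point
  overshoot; every softmax (temporal and graph attention) is
  max-stabilized, which is mathematically a no-op.
* Empty graphs (possible at high thresholds) are skipped with a logged
  warning and recorded in the dataset manifest; an all-skipped dataset
  is an explicit error naming the threshold.
* A node that passes the threshold with one partner but fails with
  another is kept (degree ≥ 1 rule).  The published pruning prose reads
  ambiguously — it could also mean deleting any node involved in a
  failing pair — but that strict reading would routinely empty the
  graph, so the degree rule is used and noted here rather than guessed
  silently.
* Resampling is Fourier-domain (brick-wall anti-alias, no phase
  delay).  LayerNorm uses $\varepsilon = 10^{-5}$; Glorot-uniform
  initialization throughout, seeded per fold.
* Ties in `which.max` over logits resolve to the first class;
  attention ties (identical keys) are handled by the softmax itself.

## Problem sizes used by the shipped checks

The package's own verification runs at desk scale, chosen once:

* End-to-end cross-validation: 16-channel reduced montage, 4 subjects
  × 50 trials of 50 s, working rate 8 Hz, 10 s windows (80 tokens,
  1000 graph samples), model widths `d_model` 16 / 2 heads / hidden 16
  / 2 GAT heads × 8.  At these margins
  ($\rho_{\text{in}} = 0.9$ vs threshold 0.7 at $n = 80$ samples per
  window) pruning still identifies the planted block essentially
  always, and the published training recipe (batch 64, 15 epochs,
  4 folds) is used unchanged.
* Duration sweep: 4 subjects × 10 trials of 20 s at 16 Hz, durations
  10 s vs 1 s, batch 8, 8 epochs, 5 seeds.  1 s windows at 16 Hz give
  very noisy correlation estimates — the intended difficulty
  mechanism, mirroring the published observation that accuracy falls
  as segments shorten.
* Layer oracles: 100 random graphs of ≤ 8 nodes per operator,
  agreement to $10^{-10}$; gradient checks by central finite
  differences on every parameter tensor.

## Known limitations

* The full-scale published experiment (64-channel recordings at
  512 Hz, tens of subjects, GPU training) is out of scope here; the
  synthetic benchmark validates mechanism, not clinical performance.
* The transformer consumes raw projected series (no patch embedding);
  token counts therefore scale linearly with window length × sampling
  rate, which is why a working rate is configurable.
* Trial-level metrics by majority vote over segments are available in
  principle (segment predictions are exposed) but the shipped reports
  are segment-level; whether published numbers are segment- or
  trial-level is not stated, so no fidelity claim is made either way.
* Edge weights are discarded at pruning (binary adjacency), and no
  directed/effective connectivity (e.g. Granger) is computed — those
  belong to a different family of decoders.
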