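# aadgraph

Selective auditory attention decoding from EEG via correlation graphs
and attention networks.

## What this is for

In a two-speaker listening situation ("cocktail party"), scalp EEG
carries a decodable signature of which speaker the listener attends
to.  `aadgraph` implements a stimulus-free decoder of that signature
for researchers working on auditory attention, neuro-steered hearing
devices and EEG-based brain–computer interfaces: it classifies each
EEG segment as *attend-left* vs *attend-right* without access to the
speech signals.

The pipeline:

1. **Preprocess** — per-channel z-scoring and Hann-windowed
   segmentation of each trial (`normalize_recording()`,
   `window_segments()`), with EDF/BDF and matrix+JSON readers
   (`read_recording()`).
2. **Graph generation** — one electrode graph per segment: nodes are
   electrodes, and an edge is kept where the Pearson correlation of
   two electrodes' windowed series exceeds 0.7,

   ```
   r_xy = (n Σ x_i y_i − Σ x_i Σ y_i) /
          ( sqrt(n Σ x_i² − (Σ x_i)²) · sqrt(n Σ y_i² − (Σ y_i)²) )
   ```

   with isolated nodes removed (`build_graph()`, `build_dataset()`).
3. **Classification** — a hybrid network written entirely in this
   package (including analytic backpropagation): transformer encoder
   layers over the time axis (softmax(QKᵀ/√d_k)V self-attention), then
   GraphSAGE (x′ᵢ = W₁xᵢ + W₂·mean_{j∈N(i)} xⱼ), a GCN layer
   (σ(D̃^{-1/2}ÃD̃^{-1/2}HW)), multi-head graph attention
   (αᵢⱼ = softmaxⱼ LeakyReLU(aᵀ[Wxᵢ‖Wxⱼ])), mean pooling and a linear
   head.  Training: Adam, lr 1e-3, cross-entropy, batch 64, 15
   epochs/fold, dropout 0.2, 4-fold cross-validation (`run_cv()`).
4. **Synthetic benchmark** — a dichotic-listening EEG generator whose
   class signal lives purely in spatial correlation structure
   (`synth_config()`, `generate_dataset()`), so the whole pipeline is
   testable without any external recordings.

See the vignette (`vignettes/attention-decoding-methods.Rmd`) for the
model details, parameter meanings and design rationale.

## Worked example

Generate a small synthetic dataset, build the graph dataset, and run a
quick 4-fold cross-validation (desk-scale model widths):

```r
library(aadgraph)

synth <- synth_config(n_subjects = 2, trials_per_subject = 10,
                      fs = 8, trial_s = 50, seed = 7)
gen <- generate_dataset(synth)
ds  <- build_dataset(gen$recordings,
                     dataset_config(window_s = 10, montage = synth$montage))
print(ds)
#> <graph_dataset> 100 samples (50 left / 50 right), 0 skipped

mc <- model_config(n_channels = 16, d_model = 16, n_heads_temporal = 2,
                   d_ff = 32, d_node = 16, sage_hidden = 16,
                   gcn_hidden = 16, gat_heads = 2, gat_head_dim = 8)
tc <- train_config(batch_size = 16, epochs_per_fold = 15, n_folds = 4,
                   seed = 7)
run_cv(ds, mc, tc)
#> <cv_report> 4 folds
#>   accuracy  1.0000 +/- 0.0000
#>   precision 1.0000 +/- 0.0000
#>   recall    1.0000 +/- 0.0000
#>   f1        1.0000 +/- 0.0000
```

Each trial's attended side plants high correlation (ρ = 0.9) inside
one hemisphere's electrode block; pruning at r > 0.7 turns that into a
class-specific graph, and the network recovers the label from held-out
trials — on this deliberately clean benchmark, perfectly.  A
label-shuffled control stays at chance (~50%), confirming the decoder
reads connectivity structure rather than any amplitude artifact;
`scripts/acceptance.R` runs that control at a larger scale.

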