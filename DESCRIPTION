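Package: aadgraph
Title: Selective Auditory Attention Decoding from EEG via Correlation
    Graphs and Attention Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for decoding which of two competing
    speakers a listener attends to, from multichannel scalp EEG alone.
    Continuous recordings are z-scored, sliced into Hann-windowed
    segments, and converted to per-segment electrode graphs by pruning
    Pearson-correlation functional connectivity at a fixed threshold.
    A hybrid neural network -- transformer encoder layers over the time
    axis followed by GraphSAGE, graph-convolution and multi-head
    graph-attention layers over the electrode graph -- classifies each
    segment as attend-left or attend-right.  Includes readers for
    EDF/BDF and a plain matrix+JSON exchange format, k-fold
    cross-validated training with confusion-matrix metrics, a
    segment-duration sweep, and a synthetic dichotic-listening EEG
    generator with planted class-dependent spatial correlation
    structure so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
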