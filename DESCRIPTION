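Package: canet
Title: Constructive Autoassociative Neural Networks for One-Class Image
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements CANet, a constructive autoassociative neural
    network for one-class learning of visual patterns. A single hidden
    layer of neurons with non-overlapping quadtree receptive fields
    reconstructs the input image through a laterally inhibited output
    layer; a constructive-pruning algorithm grows the hidden layer where
    the reconstruction error is most uneven and trims the least reliable
    output neurons. Committees of per-class networks perform multi-class
    recognition by minimum reconstruction dissimilarity. Includes
    resilient-backpropagation training, grayscale image I/O and
    preprocessing (crop, rescale, histogram equalization), a synthetic
    labelled-image fixture generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    optparse,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
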