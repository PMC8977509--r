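Package: plausnet
Title: Biologically Plausible Self-Supervised Training for Small Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying biologically plausible credit assignment in
    self-supervised learning of small convolutional networks. Implements
    deformation-based contrastive pretraining with a local contrastive hinge
    loss whose error signals are simple Hebbian sign terms, interchangeable
    error-propagation rules (backpropagation, fixed random feedback, updated
    random feedback), single-step difference target propagation with pooling
    forward stages and learned strided-deconvolution inverses, and greedy or
    randomized layer-wise training with auxiliary projection heads. Includes
    a synthetic labeled-image generator with parameterized deformation
    nuisances, linear-probe and deformation-robustness evaluation protocols,
    and a command-line interface for pretraining and evaluation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    tibble,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
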