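Package: ocra
Title: Object-Centric Recurrent Attention for Multiobject Recognition and
    Visual Reasoning
Version: 0.1.0
Authors@R:
    person("OCRA", "Maintainers", email = "ocra@example.org", role = c("aut", "cre"))
Description: An encoder-decoder model of object-based visual attention that
    takes sequential variable-resolution glimpses of an image through a grid
    of Gaussian filters, binds glimpse features into capsule "object files"
    via dynamic routing with max-min normalized coupling coefficients, and
    decodes them into attention plans and a reconstruction canvas. Ships
    procedural generators for overlapping-digit (MultiMNIST-style),
    cluttered-digit and same-different (SVRT-Task-1-style) benchmarks,
    margin and reconstruction losses, a pure-R reverse-mode autodiff engine
    used for end-to-end training, and a command-line harness for dataset
    generation, training, evaluation and glimpse-trajectory visualization.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
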