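Package: uedtune
Title: Robust Hyperparameter Optimization of Residual Image Classifiers
    by Uniform Experimental Design
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Robust (Taguchi-style) hyperparameter optimization of small
    residual convolutional networks using mixed-level uniform experimental
    designs. Provides good-lattice-point construction of uniform layouts with
    centered L2 discrepancy scoring and pseudo-level collapsing, a six-factor
    hyperparameter space for residual networks, a deterministic CPU trainer
    for parametric residual classifiers, signal-to-noise-ratio robustness
    statistics over replicate trainings with summed train+validation SNR
    selection, confusion-matrix metrics, a synthetic four-class retinal
    OCT-like grayscale image generator, report rendering, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    EBImage,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
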