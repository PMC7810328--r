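Package: gacodes
Title: Genetic-Algorithm Code Sets for Correlation-Based Sequence Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs low-cross-talk binary code sets for biological alphabets
    with a genetic algorithm (GAC) and uses them in a simulated optical
    (Vander Lugt style) cross-correlator for substring detection and k-mer
    counting in DNA, RNA and protein sequences. Includes the overlap-noise
    cost function that the genetic algorithm minimises, FFT-based 2D
    cross-correlation in ideal and pupil-band-limited modes, a
    mutation-robust peak-value model with an empirically calibrated
    cross-talk constant, a synthetic benchmark harness reporting
    sensitivity/specificity/exactitude/error across substitution-rate
    sweeps, relative-error assessment of k-mer counting, and an optical
    throughput model (scene counts and predicted search times).
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
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
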