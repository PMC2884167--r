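Package: gstackr
Title: Positional Sensitivity Models and NN+GGG Calibration for Short-Oligonucleotide Arrays
Version: 0.9.0
Authors@R:
    person("gstackr", "maintainers", email = "gstackr@example.org", role = c("aut", "cre"))
Description: Quantifies, diagnoses and removes sequence-dependent probe effects
    from probe-level intensity data of short (25-mer) oligonucleotide expression
    arrays. Implements positional- and motif-dependent sensitivity models of rank
    one to four (single base, nearest neighbor, next-nearest neighbor and
    quadruple motifs), a two-species Langmuir hybridization model with optical
    background and saturation handling, motif-resolved goodness-of-fit
    diagnostics, and a hybrid-rank NN+GGG calibration algorithm that corrects the
    anomalous intensity of probes carrying runs of three or more guanines, in
    particular triple guanines at the solution end of the probe. Includes readers
    and writers for the Affymetrix probe-tab annotation dialect, ASCII CEL
    (version 3) and plain TSV intensity files, plus a fully specified synthetic
    chip generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
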