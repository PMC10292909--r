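Package: masv
Title: Structural-Variant Simulation, Benchmarking, and Rate Estimation
    for Bacterial Mutation-Accumulation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying de novo structural variation (SV) in
    bacterial mutation-accumulation (MA) experiments. Implants known
    insertions, deletions, tandem duplications, and inversions into a
    reference genome with breakpoint-flanking small-variant noise and
    emits truth sets; matches SV call sets against truth under
    type/breakpoint/length tolerances and computes sensitivity,
    precision, and F1; runs the MA candidate-filtering cascade
    (ancestor subtraction, cross-line recurrence removal, imprecise-call
    removal, platform merging, Sanger-style validation); estimates SV
    and mutation rates per genome per cell division with exact
    (Garwood) Poisson confidence intervals; and classifies SVs as
    insertion-sequence (IS) mediated with per-family activity
    summaries. A synthetic MA-experiment generator supports end-to-end
    testing of the cascade and estimators without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
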