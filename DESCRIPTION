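Package: denoise454
Title: Two-Stage Error Correction for 454 Pyrosequencing Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and corrects sequencing errors in 454 pyrosequencing 16S
    rRNA amplicon reads. A support vector machine with a Pearson VII universal
    kernel, trained on thirteen per-position flowgram features, flags likely
    erroneous nucleotides; a masking-aware abundance-sorted preclustering then
    merges flagged reads into reliable high-abundance reads, restoring any
    unmerged masked positions. Includes a Standard Flowgram Format (SFF)
    reader/writer, basic and quality-window read trimming, a flowgram
    simulator with exact ground-truth error annotation, reference-based error
    labelling, two-parent chimera detection, and per-position error-rate
    profiling for mock-community evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    kernlab,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
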