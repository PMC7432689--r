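Package: lncfuse
Title: Multimodal Classification of Long Non-Coding RNA Transcripts
Version: 0.1.0
Authors@R:
    person("lncfuse", "developers", email = "lncfuse@example.org",
           role = c("aut", "cre"))
Description: Alignment-free discrimination of long non-coding RNAs from
    protein-coding transcripts. Transcript sequences are represented through
    three modalities - an ORF/Fickett/hexamer feature vector, k-mer
    frequencies, and a one-hot sequence encoding - each feeding a small
    neural submodel whose last-hidden-layer descriptors are fused by a dense
    classifier trained with a two-step (pretrain, then fine-tune) schedule.
    Includes stratified cross-validation, McNemar paired-classifier tests,
    a synthetic transcript generator for download-free end-to-end testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
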