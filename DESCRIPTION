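Package: cuebind
Title: Cue-Based Retrieval Modeling of Reflexive Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte-Carlo simulation of ACT-R style cue-based memory retrieval
    applied to the binding of English reflexive pronouns. Implements the
    declarative-memory activation calculus (base-level decay, fan-limited
    spreading activation, partial-match penalties, logistic activation noise
    and the activation-to-latency mapping), encodings of three reflexive
    binding experimental designs as chunk and cue sets, per-condition
    retrieval-error and retrieval-time predictions with the five derived
    interference and mismatch effects, and a grid sweep over the noise,
    associative-strength and mismatch-penalty parameters. Also provides the
    companion eye-movement analysis toolkit: fixation-to-word assignment,
    first-pass reading measures (FFD, FPRT, RRT, TRT, FPRP, RRP), cumulative
    progression curves, nested contrast coding for the 2x2 design, and a
    synthetic fixation generator for end-to-end testing of the measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
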