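Package: blinkcr
Title: Eyeblink Conditioning Simulation, Detection and Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delay eyeblink classical conditioning studies run
    under a 50% partial reinforcement schedule. Generates constrained
    pseudorandom trial schedules, simulates band-limited periocular EMG with
    conditioned and unconditional blink responses, detects conditioned
    responses with a multi-criterion peak detector (amplitude threshold,
    baseline-plus-2SD criterion, waveform slope), aggregates trial calls into
    blockwise CR percentages, scores PCL-5, PHQ-8, AMBI and a concussion
    screen, fits mixed repeated-measures ANCOVA models with Mauchly and
    Greenhouse-Geisser sphericity handling, and stratifies subjects into
    learning profiles by complete-linkage hierarchical clustering with
    majority-rule selection of the number of clusters over a panel of
    internal validity indices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    car,
    mclust,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
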