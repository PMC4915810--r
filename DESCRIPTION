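Package: vmdetect
Title: Membrane-Potential Analysis for Head-Fixed Whisker Detection Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-cell membrane-potential (Vm)
    recordings made while head-fixed mice perform a go/no-go whisker
    detection task. Parses lick-sensor traces into trial tables, gates
    recordings by signal-detection performance (d-prime with the 1/(2N)
    rate correction), removes action potentials by median filtering to
    obtain the subthreshold Vm, quantifies stimulus-evoked postsynaptic
    potentials and depolarization in early/late/lick windows together
    with baseline-subtracted spike rates and PSTHs, selects spontaneous
    unrewarded lick bouts and measures lick-aligned depolarization and
    its pre-movement onset, and aggregates cells and mice with
    non-parametric group statistics. A companion simulator generates
    complete synthetic sessions (trial scheduler with catch trials and
    an abort rule, reaction-time model, Ornstein-Uhlenbeck background
    Vm, PSP/late/lick-ramp kernels, phenomenological spiking) with full
    ground truth, so every stage of the pipeline can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
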