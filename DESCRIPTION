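Package: flexdetect
Title: Detection Toolkit for Deformable Marine Organisms in Underwater Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Building blocks for detecting soft-bodied (flexible) marine
    organisms in degraded underwater imagery. Provides a contrast-limited
    adaptive histogram equalization (CLAHE) enhancer with a boundary-detection
    enhancement channel, a reference deformable 2-D convolution and residual
    DCN block, the parameter-free SimAM attention operator, Wise-IoU (v1/v3)
    bounding-box losses with dynamic non-monotonic focusing, bi-directional
    concatenation (BiC) and SlimCSPSPPF feature-fusion blocks, a mAP50
    detection evaluator with precision-recall curves and confusion matrices,
    and a synthetic underwater-scene generator so the whole pipeline is
    testable without external data. A miniature anchor-free demo detector
    wires the blocks together for end-to-end smoke experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    EBImage
Config/testthat/edition: 3
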