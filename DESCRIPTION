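Package: relrbl
Title: Length-Adjusted Radiographic Bone Level Measurement and
    Projection-Geometry Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based morphometry for periodontal bone level
    assessment on intraoral radiographs.  Computes tooth length, direct
    radiographic bone level (RBL) and the length-adjusted ratio relRBL
    from annotated landmark coordinates by projection onto the
    receptor-vertical axis; simulates X-ray projection geometry
    (parallel and point-source) with receptor and tooth tilt to study
    elongation, foreshortening and magnification; generates complete
    synthetic multi-reader dual-angle studies; and quantifies examiner
    reliability with intraclass correlation coefficients and
    paired-design inference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
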