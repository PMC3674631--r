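Package: ancaiif
Title: Automated Interpretation of ANCA Indirect Immunofluorescence Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated reading of antineutrophil cytoplasmic antibody (ANCA)
    indirect immunofluorescence (IIF) on ethanol- and formalin-fixed
    neutrophil substrates. Provides DAPI-driven autofocus scoring, tile-based
    scene quality control and watershed nucleus segmentation; FITC-driven
    per-cell intensity quantification, six-level ordinal grading and
    cytoplasmic / perinuclear / atypical / negative pattern classification;
    rater-agreement statistics (weighted Cohen's kappa, exact McNemar,
    Fisher's exact test, inter-assay CV and functional assay sensitivity);
    and a deterministic two-channel synthetic neutrophil image generator with
    ground truth for end-to-end validation without instrument hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
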