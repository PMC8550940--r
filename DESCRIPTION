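Package: porescope
Title: Subtomogram Averaging and Geometric Analysis of Nuclear Pore Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-situ structural analysis of the nuclear pore complex
    (NPC) from cryo-electron tomography style data: parametric NPC phantom and
    subtomogram simulation with a Fourier-space missing wedge, missing-wedge
    weighted constrained cross-correlation alignment and C8-symmetric
    averaging, protomer (asymmetric unit) expansion and exclusion, Fourier
    shell correlation and windowed local resolution, B-factor sharpening,
    rigid-body fitting of point models with CAM/overlap scoring and
    Benjamini-Hochberg corrected significance, and geometric quantification of
    NPC architecture (pore and channel diameters, ring spacing, membrane
    angles, channel cylinder volume, ring-presence classes).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
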