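Package: tomogold
Title: Nanogold Label Detection and Quantification in Cryo-Electron Tomograms
Version: 0.1.0
Authors@R:
    person("tomogold", "developers", email = "tomogold@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying nanogold labeling of macromolecules in
    cryo-electron tomograms: whole-tomogram gold-particle detection by
    intensity thresholding, connected components and voxel-count gating;
    per-subtomogram gold-signal randomization so downstream alignment is
    driven by the macromolecule rather than the label; gold-to-target
    distance geometry with tag-site re-centering and a worm-like-chain
    tether bound; labeling-efficiency estimation; fluorescence-calibration
    and copy-number arithmetic; and a synthetic tomogram generator with
    ground truth for validation.  Reads and writes MRC2014 volumes and
    STAR/CSV particle tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
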