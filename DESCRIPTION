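Package: oxpclib
Title: Structural Libraries, Annotation and Imaging Support for Oxidized
    Phosphatidylcholines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-resolution mass-spectrometry studies of oxidized
    phosphatidylcholines (oxPCs). Enumerates oxPC species from a catalogue of
    oxidized-acyl modifications, computes exact monoisotopic masses and adduct
    ions, predicts diagnostic MS/MS fragments with rule-based head-group and
    fatty-acyl chemistry, runs a simplified nontargeted differential
    (oxidized versus nonoxidized) feature workflow, semiquantifies against a
    deuterated internal standard, and supports heavy-oxygen (18O) labeling for
    MALDI-MS/MS imaging: shifted precursor/product transitions,
    labeling-efficiency estimation, and pseudocolor ion-image rendering. A
    synthetic-data module generates paired LC-MS runs, DDA-style MS/MS spectra
    and zonated imaging grids with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mzR,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
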