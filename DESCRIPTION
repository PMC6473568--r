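Package: camola
Title: Carbon Module Labeling Analysis of GC-MS Volatile Isotopologues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for carbon module labeling (CAMOLA) experiments on
    flavour volatiles analysed by electron-impact GC-MS. Reads NIST-style
    MSP spectra and delimited peak tables, computes linear (van den Dool)
    retention indices against an n-alkane ladder, performs
    internal-standard semi-quantitation and odor activity values,
    normalizes molecular-ion isotopologue clusters into isotopomer
    fraction tables with optional natural-isotope-abundance deconvolution
    by non-negative least squares, and attributes each product's carbon
    skeleton to labeled sugar versus unlabeled amino-acid or lipid-derived
    precursor modules. Includes a forward simulator for paired
    labeled/unlabeled experiments so the full pipeline can be exercised
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
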