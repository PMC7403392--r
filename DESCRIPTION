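Package: chitoMRM
Title: In-Silico MRM Detection of Lipo-Chitooligosaccharides and
    Chitooligosaccharides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for targeted mass-spectrometric detection of
    lipo-chitooligosaccharides (LCOs, Nod factors) and short
    chitooligosaccharides (COs) in culture exudates: exact monoisotopic
    mass arithmetic over elemental formulas, combinatorial enumeration of
    the LCO structure space (backbone length, fatty acyl chain, positional
    substituents), theoretical precursor [M+H]+ and glycosidic B-ion m/z
    computation, multiple-reaction-monitoring (MRM) transition database
    construction and panel selection, chromatographic peak extraction with
    co-elution grouping and tiered detection confidence, untargeted
    precursor/product spectrum annotation restricted to 3-6 GlcNAc
    backbones, ground-truth-labelled synthetic chromatogram and spectrum
    simulation, and per-sample evidence-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    knitr,
    mzR,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
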