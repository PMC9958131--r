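Package: citmap
Title: Citrullination-Modulated Antigen Processing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of how citrullination reshapes the proteolytic peptide
    repertoire of an antigen, as measured by label-free quantitative mass
    spectrometry of paired native and citrullinated in vitro digests.
    Provides citrullination-site filtering with dual abundance/frequency
    thresholds, per-residue log2 enrichment profiles, calling of created and
    destroyed regions and cleavage sites, bootstrap null models for
    citrulline association at cut sites, linear and 3D distance-to-citrulline
    analyses against bootstrap expectations, antigen processing change
    scores with regressions on arginine content and structural deviation,
    and classification of MHC class II binding-core repertoires.  A
    synthetic digest generator with known ground truth supports testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
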