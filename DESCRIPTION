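Package: aiblpka
Title: pKa Prediction for Tautomerizable Cyclic 1,3-Diketones from
    Equilibrium Bond Lengths
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the AIBL (ab initio bond lengths) approach to
    aqueous pKa prediction for cyclic 1,3-diketones that tautomerize
    between diketo and keto-enol forms.  Parses quantum-chemically
    optimized 3D geometries (XYZ, SDF/MOL V2000), perceives covalent
    bonds, locates the cyclic keto-enol fragment and measures its five
    diagnostic bond lengths, then regresses pKa on those lengths with
    single-bond ordinary least squares, partial least squares, support
    vector regression, random forests and a Gaussian process with a
    squared-exponential automatic-relevance-determination kernel.
    Includes exhaustive feature-subset selection under k-fold
    cross-validation, outlier flagging against the five single-bond
    models, a congeneric-series synthetic data generator, and a bundled
    22-compound external test table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    ranger,
    igraph
Suggests:
    testthat (>= 3.0.0),
    ChemmineR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
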