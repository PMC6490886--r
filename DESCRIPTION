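Package: pksdecode
Title: Decoding Modular Polyketide Synthase Assembly Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding modular type I polyketide synthase (PKS)
    biosynthetic gene clusters from annotation tables and multienzyme protein
    sequences. Classifies cluster genes into biosynthetic roles, locates PKS
    catalytic domains by anchored active-site motif scanning, calls
    acyltransferase extender-unit specificity, ketoreductase activity and
    stereotype (Keatinge-Clay A1/A2/B1), dehydratase and enoylreductase
    activity from fingerprint residues, groups domains into extension modules,
    infers the order of multienzymes against a target backbone, detects
    programmed iteration (module stuttering), assembles the predicted
    polyketide chain, macrolactonizes it, applies post-PKS tailoring including
    deoxyaminosugar attachment, and computes molecular formulae and
    monoisotopic masses. Includes a rule engine for dTDP-deoxyaminosugar
    pathways and a seeded generator of synthetic multienzymes with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    rtracklayer,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
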