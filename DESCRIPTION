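Package: glycoMotif
Title: Cleavage Motif Discovery for O-Glycoproteases from Glycopeptide
    Identifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines substrate cleavage preferences of O-glycoproteases
    (StcE, OgpA, IMPa and related enzymes) from site-localized O-glycopeptide
    identification tables. Identifications are quality-filtered (q-value,
    localization level and probability, target/decoy, N-sequon exclusion),
    mapped onto protein sequences, classified by tryptic versus non-tryptic
    termini, and aligned in P5 to P5' windows around inferred cleavage points
    to produce sequence-logo matrices, position-specific percent-glycosylation
    and glycan composition distributions. A declarative protease rule engine
    performs full, semi-specific and non-specific in-silico digestion with
    missed-cleavage and length accounting, and a glycan-conditional
    proteolysis simulator generates synthetic glycoproteins and
    identification tables with controlled noise so that motif recovery can be
    tested end to end without mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Collate:
    'utils.R'
    'AllClasses.R'
    'glycan.R'
    'psm-io.R'
    'filters.R'
    'protease.R'
    'mapping.R'
    'motif.R'
    'simulate.R'
    'pipeline.R'
RoxygenNote: 7.3.3
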