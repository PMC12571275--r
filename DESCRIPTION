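Package: ppiface
Title: Predict and Validate Protein-Protein Interaction Interfaces from
    Domain and Motif Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate protein-protein interaction interfaces from
    sequence annotations by matching catalogued domain-domain (Pfam pair) and
    domain-motif (ELM class to Pfam domain) interactions, and validates the
    candidates on a 3D dimer model by minimum alpha-carbon contact distance
    with contact-residue labeling and a descending distance sweep. Includes
    parsers for InterProScan and ELM-Predict style TSV annotations, a short
    linear motif (SLiM) regular-expression scanner with overlapping-match
    semantics, deterministic synthetic-fixture generators for offline
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
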