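Package: molfrag
Title: Ring and Acyclic Fragment Analysis of Compound Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deconstructs small molecules into ring fragments (RFs, the ring
    systems of a molecule together with their directly attached acyclic
    atoms) and acyclic fragments (AFs, the connected components of the
    non-ring atoms), indexes fragment occurrence across compound
    collections, scores fragments for bioactivity enrichment
    (R_bioactive), profiles fragment structure and synthesizability, and
    selects novel bioactive-like fragments by structural constraints and
    MinHashed atom-pair fingerprint similarity. Includes a deterministic
    generator of synthetic compound libraries with known ground-truth
    fragment composition and planted activity enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
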