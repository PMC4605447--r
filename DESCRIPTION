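Package: lingomcc
Title: LINGO-Based Multiple Compound Comparison of SMILES Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Text-based chemical similarity screening for SMILES libraries.
    Each molecule's SMILES string is fragmented into overlapping q-character
    substrings (Lingos, q = 4 by default), each packed into a 32-bit integer
    score; sorted score profiles support linear-time multiset Tanimoto
    coefficients between compounds. A partitioned comparison engine performs
    one-to-all and all-to-all library screening with four workload-estimation
    strategies (score sum, Lingo count, string length, distinct-Lingo count)
    for balancing work across an abstract worker pool, and reports database
    hits above a similarity threshold. Includes a deterministic synthetic
    SMILES library generator and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
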