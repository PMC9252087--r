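Package: genefamdb
Title: Curated Gene-Family Reference Databases with Homologue Decoys for
    Metagenome Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building curated functional-gene reference databases
    (representative sequences plus nontarget homologue decoys), annotating
    protein queries against them with best-hit filtering on identity, hit
    length and e-value, quantifying gene-family abundance as read coverage
    per gigabase, and validating annotation accuracy with simulated gene
    sets (confusion-metric threshold sweeps) and mock genomes (detection
    ratios). Includes a seeded synthetic-data generator so the complete
    pipeline runs without external downloads, and a command-line entry
    point wiring the modules into reproducible workflows.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
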