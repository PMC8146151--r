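Package: polymap
Title: Evidence-Based Cleavage Mapping of Viral Polyproteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping the proteolytic processing of picorna-like
    viral polyproteins from orthogonal protein-chemistry evidence. Combines
    N-terminal (Edman) decapeptide reads, tryptic peptide-mass-fingerprint
    matching with ppm tolerance and decoy-based false-discovery estimation,
    and positional scanning for 3C-like protease cleavage motifs into a
    single evidence-tagged cleavage map with calculated molecular weights
    and isoelectric points. Includes supporting genome arithmetic (ORF
    finding, translation, UTR and base-composition statistics), in silico
    tryptic digestion, distance-based phylogenetics (p-distance,
    neighbor joining, nonparametric bootstrap), and seeded synthetic-data
    generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
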