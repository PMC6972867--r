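Package: flapr
Title: Design of Fluctuation-Regulated Affinity Proteins by CDR Hexapeptide Grafting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies graft-acceptor sites in small protein scaffolds that
    structurally immobilise grafted hexapeptides, extracts antigen-binding
    CDR hexapeptides from antibody-antigen complexes by alanine-hexapeptide
    binding-energy scanning, and builds and evaluates grafted antibody-mimetic
    designs. Includes PDB structure input/output, Kabsch-Sander secondary
    structure assignment, Shrake-Rupley solvent-accessible surface area,
    Gaussian-network and ensemble root-mean-square-fluctuation backends,
    in-silico side-chain mutagenesis with a discrete rotamer search, and a
    synthetic-fixture generator so the whole pipeline is testable without
    external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
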