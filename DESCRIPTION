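Package: symbiovar
Title: Organelle Genetic Variation and RNA-Editing Correspondence in Coral Symbionts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts Symbiodiniaceae organelle gene variation from coral
    holobiont whole-genome shotgun reads and relates it to known RNA-editing
    sites. Provides a k-mer seed-and-extend read mapper with per-site pileups,
    dominant-nucleotide consensus calling with low-coverage sample filtering,
    multi-sample SNP detection, correspondence of SNP sites with an
    RNA-editing catalogue, nonsynonymous/synonymous classification,
    neighbor-joining population structure with column bootstraps, ITS2 type
    assignment by best local-alignment score, and a fully specified synthetic
    holobiont cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
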