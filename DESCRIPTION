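Package: ecisfinder
Title: Detection and Comparative Genomics of Extracellular Contractile
    Injection System Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Mines annotated microbial genomes for extracellular contractile
    injection system (eCIS) loci and characterizes them. Detects candidate
    operons from pfam/COG gene annotations and percentile-filtered HMM hits
    against the Afp1-16 core profiles, screens out bacteriophage, type VI
    secretion system and R-type pyocin look-alikes, and reports loci with
    their core-gene census and boundaries. Downstream statistics include
    per-pfam Fisher enrichment with Benjamini-Hochberg correction and
    core/shell/cloud pan-classification by phylum spread, genus and trait
    association with a phylogeny-aware contrasting-pairs (pairwise
    comparison) test, and tail-fiber (Afp13) target classification from
    dual-database BLAST bitscores. A synthetic-data generator plants
    ground-truth operons, decoy loci, trees, trait tables and hit tables so
    the whole pipeline can be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
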