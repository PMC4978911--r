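Package: driftbarrier
Title: Drift-Barrier Analysis of Insertion-Deletion Mutation-Rate Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating insertion-deletion (indel) and
    base-substitution mutation rates from mutation-accumulation (MA) line
    sequencing data, deriving effective population sizes from silent-site
    diversity, and testing the drift-barrier hypothesis of mutation-rate
    evolution. Includes a synthetic-data generator for MA experiments
    (per-site read-count configurations, dual-aligner indel call sets,
    coalescent population samples), a consensus mutation caller with
    shared-variant screening, Watterson's theta and nucleotide-diversity
    estimators, log-log cross-species regressions of genome-wide indel
    burden on effective population size, phylogenetically independent
    contrasts, and antimutator selection thresholds, together with a
    packaged 15-species comparative table and phylogeny.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
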