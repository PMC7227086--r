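Package: duophase
Title: Two-Frame phasiRNA Detection and Cis-Cleavage Validation for
    Plant Small RNA Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects phased small interfering RNA (phasiRNA) production
    from loci that carry two miRNA target sites and therefore two
    simultaneous 21-nt phasing frames. Implements the windowed phasing
    score P = (n-2)*ln(1+k), de novo and anchored register detection,
    phasiRNA calling and naming, miRNA and phasiRNA target scanning with
    G:U wobble handling and the guide nt 10/11 slicer convention,
    degradome-based cis-cleavage validation (upstream filtering, RPKM,
    peak checks, rank-sum enrichment), RLM-RACE clone tallying, and
    gene-set overlap and enrichment reporting. Includes a synthetic-data
    generator producing two-frame loci, phased duplex reads with 2-nt
    3'-overhangs, degradome peaks and RACE clones with known ground
    truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
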