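Package: bsmapr
Title: Bisulfite Read Mapping and Methylation Calling in Base and Color Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps bisulfite-treated sequencing reads onto C-to-T converted
    reference genomes and calls per-cytosine methylation in CpG, CHG and CHH
    contexts. Supports Illumina base-space reads (four-orientation hit
    counting with list filtering and bisulfite-aware mismatch verification)
    and SOLiD color-space reads (dual fully-converted / non-CpG-converted
    indexes, dynamic-programming color-to-base decoding with zero-cost
    bisulfite mismatches, adjacent-color mismatch counting, mismatch stage
    filtering and complement-strand noise estimation). Includes a seeded
    bisulfite read simulator and an evaluation harness for recovery and
    accuracy on synthetic genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
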