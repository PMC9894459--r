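Package: mpass
Title: Metagenomic Phylogeny by Average Sequence Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the distance between whole metagenome-derived proteomes by
    coverage-weighted average protein similarity (the MPASS distance), builds
    neighbor-joining metagenomic trees, and compares their topology against
    dendrograms of environmental parameters by the Robinson-Foulds symmetric
    difference. Includes per-gene conservation tracing across samples, simulated
    metagenome generators (convergent and Gaussian-noise abundance schemes, a
    read sampler, and synthetic genomes with embedded protein-coding genes), and
    the supporting preprocessing steps (read trimming, down-sampling, removal of
    partial and short predicted proteins).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
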