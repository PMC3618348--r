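Package: plastomekit
Title: Plastome Assembly, Structure and Comparative Analysis from Shotgun Reads
Version: 0.1.0
Authors@R: person("Plastome", "Kit", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing and comparing circular plastid genomes
    (plastomes) from total-DNA shotgun sequencing reads. Includes a synthetic
    data generator for quadripartite plastomes, evolutionary events and
    paired-end reads; read quality control; k-mer based read-origin
    classification against a labelled reference panel; plastome read
    recruitment and de Bruijn graph assembly with k-sweep selection, contig
    merging, iterative relative-guided gap closure and inverted-repeat
    resolution; quadripartite partitioning and genome-space accounting;
    homology-based annotation transfer and grass-specific feature calling;
    anchor-based whole-plastome alignment with sliding-window identity tracks
    and deletion cataloguing; and maximum-parsimony phylogenomics with
    bootstrap support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    rtracklayer,
    withr
Config/testthat/edition: 3
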