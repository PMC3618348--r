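# Published reference tables for the six Lolium-Festuca plastomes, shipped
# as plain TSV under extdata: quadripartite region sizes with space
# percentages, and the per-species gene lengths (in codons) of the
# variable protein genes. These serve as desk-scale inputs for arithmetic
# and bookkeeping checks.

#' Published quadripartite geometry table
#'
#' @return Data frame: `species`, `plastome_size`, `lsc_size`, `ssc_size`,
#'   `ir_size` and the gene/intron/intergenic space percentages.
#' @export
load_published_geometry <- function() {
  read.delim(system.file("extdata", "published_quadripartite_sizes.tsv",
                         package = "plastomekit"),
             stringsAsFactors = FALSE)
}

#' Published variable-gene codon lengths
#'
#' @return Data frame with one row per length-variable protein gene, codon
#'   lengths for six species (NA where the gene is absent) and the reported
#'   `size_difference` column.
#' @export
load_published_gene_lengths <- function() {
  read.delim(system.file("extdata", "published_gene_lengths_codons.tsv",
                         package = "plastomekit"),
             stringsAsFactors = FALSE)
}
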