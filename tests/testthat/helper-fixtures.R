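# Small fixtures built in code: a miniature quadripartite plastome keeps
# the module tests fast while preserving the full region structure.

mini_inventory <- function() {
  gene <- function(name, region, kind, codons = NA_integer_,
                   length_bp = NA_integer_, strand = "+",
                   introns = list(integer(0)), spacer_after = NA_integer_) {
    data.frame(name = name, region = region, kind = kind,
               codons = as.integer(codons), length_bp = as.integer(length_bp),
               strand = strand, introns = I(introns),
               spacer_after = as.integer(spacer_after), stringsAsFactors = FALSE)
  }
  inv <- rbind(
    gene("psbA", "LSC", "protein", codons = 120L),
    gene("atpA", "LSC", "protein", codons = 200L, introns = list(300L)),
    gene("trnH", "LSC", "tRNA", length_bp = 75L, strand = "-"),
    gene("rbcL", "LSC", "protein", codons = 150L, spacer_after = 80L),
    gene("rpl23_remnant", "LSC", "pseudogene", length_bp = 55L,
         spacer_after = 100L),
    gene("accD", "LSC", "pseudogene", length_bp = 200L, spacer_after = 165L),
    gene("psaI", "LSC", "protein", codons = 36L),
    gene("ndhF", "SSC", "protein", codons = 180L),
    gene("rps15", "SSC", "protein", codons = 90L, strand = "-"),
    gene("rrn16", "IR", "rRNA", length_bp = 400L),
    gene("ndhB", "IR", "protein", codons = 120L, strand = "-"))
  inv$length_bp <- ifelse(inv$kind == "protein", 3L * inv$codons, inv$length_bp)
  inv
}

mini_spec <- function(seed = 1L, lsc = 8000L, ssc = 2400L, ir = 1500L) {
  plastome_spec(lsc, ssc, ir, gene_inventory = mini_inventory(), seed = seed)
}

mini_plastome <- function(seed = 1L, ...) generate_plastome(mini_spec(seed, ...))

# a ReadSet wrapper for bare sequence vectors (single-end style pairs)
reads_from_seqs <- function(seqs) {
  n <- length(seqs)
  out <- data.frame(id = sprintf("r%05d", seq_len(n)), seq1 = seqs,
                    seq2 = seqs, qual1 = strrep("I", nchar(seqs)),
                    qual2 = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

# simple read record constructors for QC tests
qual_str <- function(q) intToUtf8(q + 33L)

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("pkttest")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
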