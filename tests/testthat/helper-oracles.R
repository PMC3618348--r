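# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain loops, explicit sorts and exhaustive
# enumeration at tiny sizes.

# QC decision oracle: evaluates every prefix with naive loops.
qc_oracle <- function(bases, quals, min_len = 25L) {
  n <- nchar(bases)
  if (n == 0) return(list(action = "discard", trim_to = NA_integer_))
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  fires <- function(L) {
    run <- 0L; maxr <- 0L
    for (i in seq_len(L)) {
      run <- if (ch[i] == "N") run + 1L else 0L
      if (run > maxr) maxr <- run
    }
    q <- quals[seq_len(L)]
    med <- sort(q)[floor((L + 1) / 2)]
    (maxr > 3) || (sum(q <= 20) > 3) || (med < 20)
  }
  if (n < min_len) return(list(action = "discard", trim_to = NA_integer_))
  if (!fires(n)) return(list(action = "pass", trim_to = NA_integer_))
  if (n - 1L >= min_len) {
    for (L in seq(n - 1L, min_len, by = -1L)) {
      if (!fires(L)) return(list(action = "trim", trim_to = L))
    }
  }
  list(action = "discard", trim_to = NA_integer_)
}

# Fitch score oracle: exhaustive minimisation over all internal-node state
# assignments (tiny trees only).
fitch_oracle <- function(tree, mat) {
  bases <- c("A", "C", "G", "T")
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  edges <- tree$edge
  total <- 0L
  for (col in seq_len(ncol(mat))) {
    tipstate <- mat[match(tree$tip.label, rownames(mat)), col]
    best <- Inf
    grid <- expand.grid(rep(list(bases), nnode), stringsAsFactors = FALSE)
    for (g in seq_len(nrow(grid))) {
      states <- c(tipstate, unlist(grid[g, ], use.names = FALSE))
      cost <- 0L
      for (e in seq_len(nrow(edges))) {
        if (states[edges[e, 1]] != states[edges[e, 2]]) cost <- cost + 1L
      }
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

# Per-base genome-space labelling oracle (exon > intron > intergenic).
space_oracle <- function(genome) {
  n <- genome$length
  lab <- rep("intergenic", n)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    for (p in f$start[i]:(f$end[i] - 1L)) lab[(p %% n) + 1L] <- "intron_maybe"
  }
  for (i in seq_len(nrow(f))) {
    ex <- f$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      for (p in ex[j, 1]:(ex[j, 2] - 1L)) lab[(p %% n) + 1L] <- "exon"
    }
  }
  lab[lab == "intron_maybe"] <- "intron"
  c(gene = sum(lab == "exon"), intron = sum(lab == "intron"),
    intergenic = sum(lab == "intergenic"))
}

# Six-frame ORF scanner: does the sequence contain a complete reading frame
# covering (almost) the whole feature?  Used to check pseudogene calls.
orf_complete_oracle <- function(seq) {
  for (s in list(seq, as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq))))) {
    n <- nchar(s)
    if (n %% 3 == 0 && substr(s, 1, 3) == "ATG") {
      codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
      stops <- codons %in% c("TAA", "TAG", "TGA")
      if (stops[length(codons)] && !any(stops[-length(codons)])) return(TRUE)
    }
  }
  FALSE
}

# naive k-mer membership scan over a panel (forward and reverse strands)
kmer_in_panel_oracle <- function(kmer, refs) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
  for (r in refs) {
    if (grepl(kmer, r, fixed = TRUE) || grepl(rc, r, fixed = TRUE)) return(TRUE)
  }
  FALSE
}
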