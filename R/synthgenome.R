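# Synthetic plastome generator: quadripartite genomes with a packed gene
# inventory, descendant genomes evolved under logged events, and paired-end
# read simulation with contaminants. Provides ground truth for every
# downstream stage of the pipeline.

#' Specification of a synthetic quadripartite plastome
#'
#' Geometry defaults follow the perennial ryegrass plastome: a 79,972 bp
#' large single-copy (LSC) region and a 12,428 bp small single-copy (SSC)
#' region separated by a pair of identical 21,441 bp inverted repeats
#' (IRa/IRb), for a 135,282 bp circle.
#'
#' @param lsc_len,ssc_len,ir_len Region lengths in bases (`ir_len` is one
#'   repeat copy; it must be at least 1000).
#' @param gene_inventory Data frame describing the genes to place; see
#'   [default_gene_inventory()].
#' @param seed Integer seed; the same spec always generates the same genome.
#' @return An object of class `plastome_spec`.
#' @export
plastome_spec <- function(lsc_len = 79972L, ssc_len = 12428L, ir_len = 21441L,
                          gene_inventory = default_gene_inventory(),
                          seed = 1L) {
  lsc_len <- as.integer(lsc_len); ssc_len <- as.integer(ssc_len)
  ir_len <- as.integer(ir_len)
  if (ir_len < 1000L) stop_pk("ir_len must be >= 1000", class = "spec_error")
  if (lsc_len <= 0L || ssc_len <= 0L) stop_pk("region lengths must be positive",
                                              class = "spec_error")
  if (lsc_len <= ssc_len)
    stop_pk("lsc_len must exceed ssc_len", class = "spec_error")
  stopifnot(is.data.frame(gene_inventory) || nrow(gene_inventory) == 0)
  out <- list(lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len,
              total = lsc_len + ssc_len + 2L * ir_len,
              gene_inventory = gene_inventory, seed = as.integer(seed))
  class(out) <- "plastome_spec"
  out
}

#' @export
print.plastome_spec <- function(x, ...) {
  cat(sprintf("plastome_spec: %d bp (LSC %d / SSC %d / IR %d x2), %d genes, seed %d\n",
              x$total, x$lsc_len, x$ssc_len, x$ir_len,
              nrow(x$gene_inventory), x$seed))
  invisible(x)
}

# Deterministic split of `total` into n parts with plausible variation.
split_sizes <- function(total, n, base) {
  if (n == 0) return(integer(0))
  v <- rep_len(base, n - 1)
  v <- c(v, total - sum(v))
  stopifnot(all(v > 0))
  v
}

#' Default synthetic gene inventory
#'
#' Builds a 114-gene inventory (82 LSC, 12 SSC, 20 IR-duplicated; the IR
#' genes appear twice in the annotation for a total of 134 gene copies),
#' plus two pseudogene remnants (an rpl23 translocation trace and an accD
#' remnant) planted in the rbcL--psaI intergenic spacer, a mutational
#' hot-spot in grass plastomes. Gene, intron and pseudogene base budgets are
#' balanced so that, with the default geometry, gene space is about 54.3%,
#' intron space about 11.9% and intergenic space about 33.8% of the genome.
#'
#' @param rbcl_psai_len Length in bases of the rbcL--psaI intergenic region
#'   (distance from the rbcL stop to the psaI start).
#' @return A data frame with columns `name`, `region` (LSC/SSC/IR), `kind`
#'   (protein/tRNA/rRNA/pseudogene), `codons` (protein genes; length
#'   includes the stop codon), `length_bp`, `strand`, `introns` (list column
#'   of intron lengths) and `spacer_after` (explicit downstream filler, NA
#'   for automatic).
#' @export
default_gene_inventory <- function(rbcl_psai_len = 1183L) {
  gene <- function(name, region, kind, codons = NA_integer_,
                   length_bp = NA_integer_, strand = "+",
                   introns = list(integer(0)), spacer_after = NA_integer_) {
    data.frame(name = name, region = region, kind = kind,
               codons = as.integer(codons), length_bp = as.integer(length_bp),
               strand = strand, introns = I(introns),
               spacer_after = as.integer(spacer_after),
               stringsAsFactors = FALSE)
  }
  rows <- list()

  ## --- LSC: 82 genes (62 protein, 20 tRNA) + 2 pseudogene remnants -------
  # named anchor genes used by the annotation / comparison stages
  lsc_anchor <- data.frame(
    name = c("psbA", "matK", "rpoC2", "rpoB", "psbC", "rps4", "atpA", "clpP",
             "rbcL", "psaI"),
    codons = c(353L, 509L, 1467L, 1076L, 473L, 201L, 508L, 196L, 478L, 36L),
    stringsAsFactors = FALSE)
  lsc_protein_budget_codons <- 13219L # total protein codons in LSC
  n_filler_prot <- 52L
  pat <- rep_len(c(120L, 150L, 180L, 200L, 110L, 90L, 140L, 160L, 130L, 170L),
                 n_filler_prot - 1L)
  filler_codons <- c(pat, lsc_protein_budget_codons - sum(lsc_anchor$codons) - sum(pat))
  stopifnot(filler_codons[length(filler_codons)] > 30)
  lsc_names <- c(paste0("psb", c("B", "D", "E", "F", "H", "I", "J", "K", "L", "M", "N")),
                 paste0("pet", LETTERS[1:7]),
                 paste0("atp", c("B", "E", "F", "H", "I")),
                 paste0("rps", c(2, 3, 8, 11, 14, 16, 18)),
                 paste0("rpl", c(14, 16, 20, 22, 33, 36)),
                 paste0("ndh", c("C", "J", "K")),
                 paste0("ycf", c(3, 4)), "cemA", "ccsA", "infA",
                 paste0("orf", sprintf("%03d", 1:14)))
  lsc_names <- lsc_names[seq_len(n_filler_prot)]
  strands <- rep_len(c("+", "+", "-", "+", "-"), n_filler_prot)
  # ten filler proteins carry one intron each (budget 9912 bp)
  intr_lens <- c(rep(991L, 9L), 993L)
  introns <- rep(list(integer(0)), n_filler_prot)
  intron_idx <- seq(3, by = 5, length.out = 10)
  for (i in seq_along(intron_idx)) introns[[intron_idx[i]]] <- intr_lens[i]

  for (i in 1:8) # anchors before rbcL
    rows[[length(rows) + 1]] <- gene(lsc_anchor$name[i], "LSC", "protein",
                                     codons = lsc_anchor$codons[i],
                                     strand = if (i %% 3 == 0) "-" else "+")
  for (i in seq_len(n_filler_prot))
    rows[[length(rows) + 1]] <- gene(lsc_names[i], "LSC", "protein",
                                     codons = filler_codons[i],
                                     strand = strands[i],
                                     introns = list(introns[[i]]))
  for (i in 1:20)
    rows[[length(rows) + 1]] <- gene(sprintf("trnL%02d", i), "LSC", "tRNA",
                                     length_bp = 75L,
                                     strand = if (i %% 2 == 0) "-" else "+")
  # the rbcL--psaI hot-spot: rbcL, rpl23' trace, accD remnant, psaI.
  # Explicit spacers pin the rbcL stop -> psaI start distance.
  accd_len <- 300L
  sp <- rbcl_psai_len - 180L - 55L - 200L - accd_len
  stopifnot(sp > 0)
  rows[[length(rows) + 1]] <- gene("rbcL", "LSC", "protein", codons = 478L,
                                   spacer_after = 180L)
  rows[[length(rows) + 1]] <- gene("rpl23_remnant", "LSC", "pseudogene",
                                   length_bp = 55L, spacer_after = 200L)
  rows[[length(rows) + 1]] <- gene("accD", "LSC", "pseudogene",
                                   length_bp = accd_len, spacer_after = sp)
  rows[[length(rows) + 1]] <- gene("psaI", "LSC", "protein", codons = 36L)

  ## --- SSC: 12 genes (protein), one with an intron ------------------------
  ssc_codons <- c(739L, 503L, 181L, 112L, 393L, 99L, 130L, 236L, 160L, 40L, 30L)
  ssc_codons <- c(ssc_codons, 2666L - sum(ssc_codons))
  stopifnot(ssc_codons[12] > 30)
  ssc_names <- c("ndhF", "ndhD", "ndhA", "ndhE", "ndhH", "ndhI", "ndhG",
                 "rps15", "rpl32", "psaC", "ccsA2", "orfS01")
  for (i in 1:12)
    rows[[length(rows) + 1]] <- gene(ssc_names[i], "SSC", "protein",
                                     codons = ssc_codons[i],
                                     strand = if (i %% 4 == 0) "-" else "+",
                                     introns = if (i == 3) list(1000L) else list(integer(0)))

  ## --- IR: 20 genes per copy (4 rRNA, 8 tRNA, 8 protein, 2 introns) ------
  rrna <- data.frame(name = c("rrn16", "rrn23", "rrn4.5", "rrn5"),
                     bp = c(1491L, 2811L, 95L, 121L), stringsAsFactors = FALSE)
  ir_trna_bp <- 75L
  ir_prot_codons <- c(150L, 253L, 180L, 500L, 120L, 300L, 400L)
  ir_prot_codons <- c(ir_prot_codons,
                      (12000L - sum(rrna$bp) - 8L * ir_trna_bp) %/% 3L - sum(ir_prot_codons))
  stopifnot(ir_prot_codons[8] > 30,
            (12000L - sum(rrna$bp) - 8L * ir_trna_bp) %% 3L == 0L)
  for (i in 1:4)
    rows[[length(rows) + 1]] <- gene(rrna$name[i], "IR", "rRNA",
                                     length_bp = rrna$bp[i])
  for (i in 1:8)
    rows[[length(rows) + 1]] <- gene(sprintf("trnI%02d", i), "IR", "tRNA",
                                     length_bp = ir_trna_bp,
                                     strand = if (i %% 2 == 0) "-" else "+")
  ir_names <- c("ndhB", "rps12", "rps7", "ycf2", "rpl2", "rpl23", "ycf15", "ycf68")
  for (i in 1:8)
    rows[[length(rows) + 1]] <- gene(ir_names[i], "IR", "protein",
                                     codons = ir_prot_codons[i],
                                     strand = if (i %% 3 == 0) "-" else "+",
                                     introns = if (i <= 2) list(1300L) else list(integer(0)))

  inv <- do.call(rbind, rows)
  inv$length_bp <- ifelse(inv$kind == "protein", 3L * inv$codons, inv$length_bp)
  rownames(inv) <- NULL
  inv
}

# sense codons excluding the three stops
.SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  cods <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
}

# A random open reading frame of `codons` codons (ATG ... TAA, no internal
# stop in frame), total length 3 * codons.
random_orf <- function(codons) {
  stopifnot(codons >= 2)
  mid <- sample(.SENSE_CODONS, codons - 2L, replace = TRUE)
  paste0("ATG", paste(mid, collapse = ""), "TAA")
}

# Build one region: filler + genes in inventory order + filler. Returns the
# region sequence and its features with region-local 0-based coordinates.
build_region <- function(genes, region_len, region_name) {
  n <- nrow(genes)
  spans <- integer(n)
  bodies <- character(n)
  exon_local <- vector("list", n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    body <- switch(g$kind,
                   protein = random_orf(g$codons),
                   random_dna(g$length_bp))
    intr <- genes$introns[[i]]
    if (length(intr) > 0 && sum(intr) > 0) {
      # split the body into length(intr)+1 exons with introns between
      nex <- length(intr) + 1L
      cut <- round(seq_len(nex - 1L) * nchar(body) / nex)
      cut <- 3L * (cut %/% 3L) # keep codon phase at exon boundaries
      starts <- c(1L, cut + 1L)
      ends <- c(cut, nchar(body))
      pieces <- substring(body, starts, ends)
      seq_parts <- character(0)
      exons <- matrix(0L, nrow = nex, ncol = 2)
      pos <- 0L
      for (j in seq_len(nex)) {
        exons[j, ] <- c(pos, pos + nchar(pieces[j]))
        seq_parts <- c(seq_parts, pieces[j])
        pos <- pos + nchar(pieces[j])
        if (j < nex) {
          seq_parts <- c(seq_parts, random_dna(intr[j]))
          pos <- pos + intr[j]
        }
      }
      body <- paste(seq_parts, collapse = "")
      exon_local[[i]] <- exons
    } else {
      exon_local[[i]] <- cbind(0L, nchar(body))
    }
    if (g$strand == "-") {
      len <- nchar(body)
      body <- revcomp(body)
      exon_local[[i]] <- cbind(len - exon_local[[i]][, 2], len - exon_local[[i]][, 1])
      exon_local[[i]] <- exon_local[[i]][rev(seq_len(nrow(exon_local[[i]]))), , drop = FALSE]
    }
    bodies[i] <- body
    spans[i] <- nchar(body)
  }
  n_slots <- n + 1L
  filler_total <- region_len - sum(spans)
  fixed <- rep(NA_integer_, n_slots) # slot i+1 follows gene i
  if (n > 0) fixed[1 + which(!is.na(genes$spacer_after))] <-
      genes$spacer_after[!is.na(genes$spacer_after)]
  free <- which(is.na(fixed))
  remaining <- filler_total - sum(fixed, na.rm = TRUE)
  if (remaining < 2L * length(free) || filler_total < 0)
    stop_pk("gene inventory does not fit in region %s (%d bp needed, %d available)",
            region_name, sum(spans) + sum(fixed, na.rm = TRUE) + 2L * length(free),
            region_len, class = "packing_error")
  per <- remaining %/% length(free)
  fixed[free] <- per
  fixed[free[length(free)]] <- remaining - per * (length(free) - 1L)
  parts <- character(2L * n + 1L)
  feats <- vector("list", n)
  pos <- 0L
  for (i in seq_len(n_slots)) {
    fl <- random_dna(fixed[i])
    parts[2L * i - 1L] <- fl
    pos <- pos + fixed[i]
    if (i <= n) {
      g <- genes[i, ]
      feats[[i]] <- data.frame(name = g$name, kind = g$kind, strand = g$strand,
                               start = pos, end = pos + spans[i],
                               exons = I(list(exon_local[[i]] + pos)),
                               region = region_name, copy = 1L,
                               truncated = FALSE, stringsAsFactors = FALSE)
      parts[2L * i] <- bodies[i]
      pos <- pos + spans[i]
    }
  }
  list(seq = paste(parts, collapse = ""),
       features = if (n > 0) do.call(rbind, feats) else empty_features())
}

#' Generate a synthetic annotated plastome
#'
#' Packs the gene inventory into the LSC, IRb and SSC regions (genes in
#' inventory order, separated by uniform-random intergenic filler), then
#' completes the circle as LSC + IRb + SSC + IRa with IRa the exact reverse
#' complement of IRb (IR gene copies are mirrored into the annotation). The
#' origin (position 0) is the first base of the LSC. Boundary filler bases
#' are adjusted where needed so that the planted repeat pair is maximal,
#' i.e. cannot be extended by chance matches.
#'
#' @param spec A [plastome_spec()].
#' @return An object of class `plastome`: a list with elements `seq`
#'   (upper-case circular sequence), `length`, `features` (data frame with
#'   0-based half-open `start`/`end`, an `exons` list column, `region` and
#'   `copy`), and `regions` (LSC/IRb/SSC/IRa intervals).
#' @export
generate_plastome <- function(spec) {
  stopifnot(inherits(spec, "plastome_spec"))
  inv <- spec$gene_inventory
  with_seed(spec$seed, {
    lsc <- build_region(inv[inv$region == "LSC", , drop = FALSE], spec$lsc_len, "LSC")
    irb <- build_region(inv[inv$region == "IR", , drop = FALSE], spec$ir_len, "IRb")
    ssc <- build_region(inv[inv$region == "SSC", , drop = FALSE], spec$ssc_len, "SSC")
  })
  lsc_seq <- lsc$seq; irb_seq <- irb$seq; ssc_seq <- ssc$seq
  # prevent chance extension of the IR pair across region boundaries:
  # the pair grows into the LSC iff last(LSC) == comp(first(LSC)) and into
  # the SSC iff first(SSC) == comp(last(SSC)).
  fix_last_base <- function(s) {
    # ensure last(s) != comp(first(s)) by editing the trailing filler base
    if (substr(s, nchar(s), nchar(s)) == comp_base_r(substr(s, 1, 1))) {
      substr(s, nchar(s), nchar(s)) <- setdiff(
        c("A", "C", "G", "T"),
        c(comp_base_r(substr(s, 1, 1)), substr(s, nchar(s), nchar(s))))[1]
    }
    s
  }
  lsc_seq <- fix_last_base(lsc_seq)
  ssc_seq <- fix_last_base(ssc_seq)
  ira_seq <- revcomp(irb_seq)
  seqs <- paste0(lsc_seq, irb_seq, ssc_seq, ira_seq)
  stopifnot(nchar(seqs) == spec$total)

  off_irb <- spec$lsc_len
  off_ssc <- off_irb + spec$ir_len
  off_ira <- off_ssc + spec$ssc_len
  shift_feats <- function(f, off, region) {
    if (nrow(f) == 0) return(f)
    f$start <- f$start + off; f$end <- f$end + off
    f$exons <- I(lapply(f$exons, function(m) m + off))
    f$region <- region
    f
  }
  f_lsc <- shift_feats(lsc$features, 0L, "LSC")
  f_irb <- shift_feats(irb$features, off_irb, "IRb")
  f_ssc <- shift_feats(ssc$features, off_ssc, "SSC")
  # mirror IRb features into IRa
  f_ira <- f_irb
  if (nrow(f_ira) > 0) {
    irb_end <- off_ssc
    mirror <- function(x) off_ira + (irb_end - x)
    ns <- mirror(f_ira$end); ne <- mirror(f_ira$start)
    f_ira$start <- ns; f_ira$end <- ne
    f_ira$exons <- I(lapply(f_ira$exons, function(m) {
      mm <- cbind(mirror(m[, 2]), mirror(m[, 1]))
      mm[rev(seq_len(nrow(mm))), , drop = FALSE]
    }))
    f_ira$strand <- ifelse(f_ira$strand == "+", "-", "+")
    f_ira$region <- "IRa"
    f_ira$copy <- 2L
  }
  features <- rbind(f_lsc, f_irb, f_ssc, f_ira)
  rownames(features) <- NULL
  genome <- list(
    seq = seqs,
    length = nchar(seqs),
    features = features,
    regions = list(lsc = c(start = 0L, len = spec$lsc_len),
                   irb = c(start = off_irb, len = spec$ir_len),
                   ssc = c(start = off_ssc, len = spec$ssc_len),
                   ira = c(start = off_ira, len = spec$ir_len)),
    circular = TRUE)
  class(genome) <- "plastome"
  genome
}

comp_base_r <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("plastome: %d bp, %d feature(s)%s\n", x$length, nrow(x$features),
              if (!is.null(x$regions)) sprintf(
                " [LSC %d / SSC %d / IR %d]", x$regions$lsc[["len"]],
                x$regions$ssc[["len"]], x$regions$irb[["len"]]) else ""))
  invisible(x)
}

#' Coerce a bare sequence to a `plastome` object
#'
#' @param seq Character scalar (A/C/G/T).
#' @param features Optional feature data frame.
#' @param circular Is the sequence circular?
#' @return A `plastome` object (without region assignments).
#' @export
as_plastome <- function(seq, features = empty_features(), circular = TRUE) {
  seq <- toupper(seq)
  out <- list(seq = seq, length = nchar(seq), features = features,
              regions = NULL, circular = circular)
  class(out) <- "plastome"
  out
}
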