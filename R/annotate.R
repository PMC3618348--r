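# Homology-based annotation transfer from an annotated reference plastome
# to a newly assembled one, the cross-species gene-length (codon) table,
# and the grass-specific feature calls for the rbcL--psaI hot-spot region.

#' Transfer gene models from an annotated reference
#'
#' Each reference exon is located on the target by k-mer diagonal voting
#' and refined by a global-local alignment of the exon against the
#' candidate window; hits above the identity and coverage thresholds become
#' transferred exons. Protein features whose spliced sequence no longer
#' forms a clean reading frame (start codon, in-frame terminal stop, no
#' internal stop) are flagged truncated; genes with no acceptable hit are
#' listed as missing.
#'
#' @param target Target genome (`plastome` or sequence).
#' @param reference Annotated reference `plastome`.
#' @param min_identity Minimum alignment identity (matches / exon length).
#' @param min_coverage Minimum fraction of the exon that must align.
#' @param k Seed k-mer size for locating.
#' @return List with `features` (transferred annotation) and `missing`
#'   (names of reference genes without an acceptable hit).
#' @export
transfer_annotation <- function(target, reference, min_identity = 0.8,
                                min_coverage = 0.7, k = 15L) {
  tseq <- if (inherits(target, "plastome")) target$seq else toupper(target)
  stopifnot(inherits(reference, "plastome"))
  rfeat <- reference$features
  if (nrow(rfeat) == 0) return(list(features = rfeat, missing = character(0)))
  idx <- build_panel_index(c(target = tseq), c(target = "plastid"), k)
  n <- nchar(tseq)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)

  out_rows <- list()
  missing <- character(0)
  for (i in seq_len(nrow(rfeat))) {
    ex <- rfeat$exons[[i]]
    new_ex <- NULL
    strands <- character(0)
    found_all <- TRUE
    for (j in seq_len(nrow(ex))) {
      q <- substr_circular(reference$seq, ex[j, 1], ex[j, 2] - ex[j, 1])
      loc <- assign_reads(q, idx, min_hit_fraction = 0, max_edit_distance = 0L,
                          verify = FALSE)
      if (loc$ref[1] == 0 || is.na(loc$pos[1])) { found_all <- FALSE; next }
      # repeat copies (the IR duplicates) share the same exon sequence: of
      # the two candidate loci take the one colinear with the reference
      pos <- loc$pos[1]; str_rc <- loc$strand[1] == 1L
      if (!is.na(loc$pos2[1])) {
        circ_d <- function(p) { d <- abs(p - ex[j, 1]); min(d, n - d) }
        if (circ_d(loc$pos2[1]) < circ_d(pos)) {
          pos <- loc$pos2[1]; str_rc <- loc$strand2[1] == 1L
        }
      }
      qa <- if (str_rc) revcomp(q) else q
      pad <- max(30L, nchar(q) %/% 10L)
      w0 <- max(0L, pos - pad)
      w1 <- min(n, pos + nchar(q) + pad)
      window <- substr(tseq, w0 + 1L, w1)
      aln <- Biostrings::pairwiseAlignment(qa, window, type = "global-local",
                                           substitutionMatrix = sub_mat,
                                           gapOpening = 6, gapExtension = 1)
      ident <- Biostrings::nmatch(aln) / nchar(q)
      cov <- (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)) / nchar(q)
      if (ident < min_identity || cov < min_coverage) { found_all <- FALSE; next }
      ss <- w0 + Biostrings::start(Biostrings::subject(aln)) - 1L
      se <- w0 + Biostrings::end(Biostrings::subject(aln))
      new_ex <- rbind(new_ex, c(ss, se))
      strands <- c(strands,
                   if (xor(rfeat$strand[i] == "-", str_rc)) "-" else "+")
    }
    if (is.null(new_ex)) {
      missing <- c(missing, rfeat$name[i])
      next
    }
    o <- order(new_ex[, 1])
    new_ex <- new_ex[o, , drop = FALSE]
    strand <- strands[1]
    truncated <- !found_all
    if (rfeat$kind[i] == "protein") {
      cds <- spliced_seq(tseq, new_ex, strand)
      if (!is_clean_orf(cds)) truncated <- TRUE
    }
    out_rows[[length(out_rows) + 1]] <- data.frame(
      name = rfeat$name[i], kind = rfeat$kind[i], strand = strand,
      start = min(new_ex[, 1]), end = max(new_ex[, 2]),
      exons = I(list(new_ex)),
      region = if ("region" %in% names(rfeat)) rfeat$region[i] else NA_character_,
      copy = if ("copy" %in% names(rfeat)) rfeat$copy[i] else 1L,
      truncated = truncated, stringsAsFactors = FALSE)
  }
  feats <- if (length(out_rows)) do.call(rbind, out_rows) else empty_features()
  rownames(feats) <- NULL
  list(features = feats, missing = unique(missing))
}

# spliced sequence of an exon matrix in reading orientation
spliced_seq <- function(seq, exons, strand) {
  pieces <- substring(seq, exons[, 1] + 1L, exons[, 2])
  s <- paste(pieces, collapse = "")
  if (strand == "-") revcomp(s) else s
}

is_clean_orf <- function(cds) {
  nc <- nchar(cds)
  if (nc < 6 || nc %% 3 != 0) return(FALSE)
  if (substr(cds, 1, 3) != "ATG") return(FALSE)
  codons <- substring(cds, seq(1, nc, 3), seq(3, nc, 3))
  stops <- codons %in% c("TAA", "TAG", "TGA")
  stops[length(codons)] && !any(stops[-length(codons)])
}

#' Codon length of a protein feature
#' @param seq Genome sequence.
#' @param feature One row of a feature data frame.
#' @return Length in codons (spliced exon length / 3).
#' @export
feature_codons <- function(seq, feature) {
  sum(feature$exons[[1]][, 2] - feature$exons[[1]][, 1]) / 3
}

#' Cross-species gene-length table
#'
#' Tabulates protein gene lengths in codons across species annotations and
#' reports, for genes present in at least one species, the size difference
#' (max - min over species carrying the gene). Genes with no length
#' variation are excluded from the returned table.
#'
#' @param annotations Named list of annotations (feature data frames or
#'   `plastome` objects).
#' @return Data frame: `gene`, one codon-length column per species, and
#'   `difference`.
#' @export
gene_length_table <- function(annotations) {
  if (length(annotations) < 2)
    stop_pk("need at least two species", class = "parameter_error")
  feats <- lapply(annotations, function(a) if (inherits(a, "plastome")) a$features else a)
  genes <- unique(unlist(lapply(feats, function(f) f$name[f$kind == "protein"])))
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(feats),
                dimnames = list(genes, names(feats)))
  for (s in seq_along(feats)) {
    f <- feats[[s]]
    pr <- f[f$kind == "protein", , drop = FALSE]
    for (g in genes) {
      rows <- which(pr$name == g)
      if (length(rows)) {
        lens <- vapply(rows, function(r)
          sum(pr$exons[[r]][, 2] - pr$exons[[r]][, 1]) / 3, numeric(1))
        mat[g, s] <- lens[1]
      }
    }
  }
  d <- gene_length_differences(mat)
  out <- data.frame(gene = genes, mat, difference = d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[out$difference > 0 & !is.na(out$difference), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Size difference per gene from a codon-length matrix
#'
#' @param mat Numeric matrix (genes x species), NA where a gene is absent.
#' @return Named numeric vector: per gene, max - min over species with the
#'   gene present (NA if present in fewer than one species).
#' @export
gene_length_differences <- function(mat) {
  apply(mat, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    max(x) - min(x)
  })
}

#' Call grass-specific plastome features
#'
#' Reports the rbcL--psaI intergenic length, the presence of an rpl23/rpl32
#' translocation remnant inside that region, the state of the accD gene
#' (present / pseudogene / absent, a pseudogene being an incomplete reading
#' frame), and, when flank anchors are supplied, the rpoC2 insertion length
#' measured between them.
#'
#' @param genome A `plastome`.
#' @param annotation Feature data frame (defaults to the genome's).
#' @param flank_library Optional `list(left=, right=)` anchor sequences
#'   delimiting the rpoC2 insertion.
#' @param accd_reference_codons Optional reference length used for the
#'   `< 70%% of reference` pseudogene criterion.
#' @return An object of class `feature_report`.
#' @export
call_grass_features <- function(genome, annotation = NULL, flank_library = NULL,
                                accd_reference_codons = NULL) {
  stopifnot(inherits(genome, "plastome"))
  if (is.null(annotation)) annotation <- genome$features
  n <- genome$length
  rbcl <- annotation[annotation$name == "rbcL", , drop = FALSE]
  psai <- annotation[annotation$name == "psaI", , drop = FALSE]
  if (nrow(rbcl) == 0 || nrow(psai) == 0)
    stop_pk("rbcL and psaI must both be annotated to define the region",
            class = "region_undefined")
  # the intergenic arc between the two genes: shorter of the two directions
  d1 <- (psai$start[1] - rbcl$end[1]) %% n   # rbcL -> psaI
  d2 <- (rbcl$start[1] - psai$end[1]) %% n   # psaI -> rbcL
  if (d1 <= d2) {
    region <- c(start = rbcl$end[1] %% n, len = d1)
  } else {
    region <- c(start = psai$end[1] %% n, len = d2)
  }
  in_region <- function(s, e) {
    off <- (s - region[["start"]]) %% n
    off + (e - s) <= region[["len"]]
  }
  remn <- annotation[grepl("^rpl23|^rpl32", annotation$name), , drop = FALSE]
  remnant_present <- FALSE
  if (nrow(remn)) {
    for (i in seq_len(nrow(remn)))
      if (in_region(remn$start[i], remn$end[i])) remnant_present <- TRUE
  }
  accd <- annotation[annotation$name == "accD", , drop = FALSE]
  if (nrow(accd) == 0) {
    accd_state <- "absent"
    accd_why <- "no hit"
  } else {
    cds <- spliced_seq(genome$seq, accd$exons[[1]], accd$strand[1])
    clean <- is_clean_orf(cds)
    long_enough <- is.null(accd_reference_codons) ||
      nchar(cds) / 3 >= 0.7 * accd_reference_codons
    trunc_flag <- isTRUE(accd$truncated[1])
    if (clean && long_enough && !trunc_flag) {
      accd_state <- "present"; accd_why <- "complete reading frame"
    } else {
      accd_state <- "pseudo"
      accd_why <- if (!clean) "incomplete reading frame"
                  else if (!long_enough) "below 70% of reference length"
                  else "truncated in transfer"
    }
  }
  rpoc2 <- NA_integer_
  rpoc2_reason <- "no flank anchors supplied"
  if (!is.null(flank_library)) {
    pos_l <- locate_anchor(genome$seq, flank_library$left)
    pos_r <- locate_anchor(genome$seq, flank_library$right)
    if (is.na(pos_l[1]) || is.na(pos_r[1])) {
      rpoc2_reason <- "anchor not found"
    } else {
      rpoc2 <- abs(pos_r[1] - (pos_l[1] + pos_l[2]))
      rpoc2_reason <- NA_character_
    }
  }
  out <- list(rbcl_psai_len = unname(region[["len"]]),
              rpl23_remnant = if (remnant_present) "present" else "absent",
              accd = accd_state, accd_reason = accd_why,
              rpoc2_insertion_len = rpoc2, rpoc2_reason = rpoc2_reason)
  class(out) <- "feature_report"
  out
}

# exact anchor match on either strand; returns c(start0, len) or NA
locate_anchor <- function(seq, anchor) {
  if (is.null(anchor)) return(c(NA_integer_, NA_integer_))
  p <- regexpr(anchor, seq, fixed = TRUE)
  if (p > 0) return(c(p - 1L, nchar(anchor)))
  p <- regexpr(revcomp(anchor), seq, fixed = TRUE)
  if (p > 0) return(c(p - 1L, nchar(anchor)))
  c(NA_integer_, NA_integer_)
}

#' @export
print.feature_report <- function(x, ...) {
  cat(sprintf("feature_report: rbcL-psaI %d bp | rpl23' %s | accD %s (%s) | rpoC2 insertion %s\n",
              x$rbcl_psai_len, x$rpl23_remnant, x$accd, x$accd_reason,
              ifelse(is.na(x$rpoc2_insertion_len), "n/a", x$rpoc2_insertion_len)))
  invisible(x)
}
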