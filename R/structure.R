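# Quadripartite structure: detection of the inverted repeat pair on the
# circle, partition into LSC / IRb / SSC / IRa, canonical rotation, and the
# gene/intron/intergenic space accounting.

#' Detect the inverted repeat pair
#'
#' Finds the maximal pair of disjoint intervals on the circle whose
#' sequences are exact reverse complements of each other, seeded by k-mers
#' shared between the sequence and its reverse complement and extended
#' maximally. Plastome IR copies are identical, so the default mismatch
#' tolerance is zero.
#'
#' @param genome A `plastome` or character sequence (treated as circular).
#' @param min_len Minimum IR length in bases.
#' @param k Seed k-mer length.
#' @return List with `start1`, `start2` (0-based starts of the two copies)
#'   and `len`; errors if none or if two non-equivalent maximal pairs are
#'   found.
#' @export
detect_inverted_repeat <- function(genome, min_len = 1000L, k = 31L) {
  s <- if (inherits(genome, "plastome")) genome$seq else toupper(genome)
  n <- nchar(s)
  if (n < 2L * min_len)
    stop_pk("sequence shorter than two IR copies", class = "parameter_error")
  m <- cpp_revcomp_selfmatches(s, as.integer(k), as.integer(min_len), TRUE)
  if (nrow(m) > 0) {
    # require the two copies to be disjoint on the circle
    ok <- logical(nrow(m))
    for (i in seq_len(nrow(m))) {
      a <- m[i, "start1"]; b <- m[i, "start2"]; L <- m[i, "len"]
      ia <- intervals_disjoint_circular(a, L, b, L, n)
      ok[i] <- ia
    }
    m <- m[ok, , drop = FALSE]
  }
  if (nrow(m) == 0)
    stop_pk("no inverted repeat of length >= %d found", min_len,
            class = "no_ir_error")
  best <- m[m[, "len"] == m[1, "len"], , drop = FALSE]
  if (nrow(best) > 1)
    stop_pk("ambiguous inverted repeat: %d equally maximal pairs", nrow(best),
            class = "ambiguous_ir_error")
  list(start1 = unname(best[1, "start1"]), start2 = unname(best[1, "start2"]),
       len = unname(best[1, "len"]))
}

intervals_disjoint_circular <- function(s1, l1, s2, l2, n) {
  # positions covered, modular
  e1 <- s1 + l1; e2 <- s2 + l2
  overlap_lin <- function(a1, b1, a2, b2) a1 < b2 && a2 < b1
  for (shift in c(-n, 0, n)) {
    if (overlap_lin(s1, e1, s2 + shift, e2 + shift)) return(FALSE)
  }
  TRUE
}

#' Partition a circular plastome into its quadripartite regions
#'
#' The two arcs between the IR copies become the LSC (longer) and SSC
#' (shorter); IRb is the repeat copy that follows the LSC.
#'
#' @param genome A `plastome` or character sequence.
#' @param ir Result of [detect_inverted_repeat()] (detected automatically
#'   when omitted).
#' @return An object of class `quadripartite`: intervals (`start`, `len`,
#'   0-based on the circle) for `lsc`, `irb`, `ssc`, `ira`, plus `sizes`.
#' @export
partition_quadripartite <- function(genome, ir = NULL) {
  s <- if (inherits(genome, "plastome")) genome$seq else toupper(genome)
  n <- nchar(s)
  if (is.null(ir)) ir <- detect_inverted_repeat(s)
  a <- ir$start1; b <- ir$start2; L <- ir$len
  # arcs between the copies (may wrap)
  arc1 <- c(start = (a + L) %% n, len = (b - (a + L)) %% n)
  arc2 <- c(start = (b + L) %% n, len = (a - (b + L)) %% n)
  if (arc1[["len"]] == arc2[["len"]])
    stop_pk("the two single-copy arcs are equal (%d bp): LSC/SSC labelling is ambiguous",
            arc1[["len"]], class = "tie_error")
  lsc <- if (arc1[["len"]] > arc2[["len"]]) arc1 else arc2
  ssc <- if (arc1[["len"]] > arc2[["len"]]) arc2 else arc1
  # IRb immediately follows the LSC
  irb_start <- (lsc[["start"]] + lsc[["len"]]) %% n
  irb <- c(start = irb_start, len = L)
  ira_start <- if (irb_start == a %% n) b %% n else a %% n
  ira <- c(start = ira_start, len = L)
  stopifnot(lsc[["len"]] + ssc[["len"]] + 2L * L == n)
  out <- list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
              sizes = c(total = n, lsc = unname(lsc[["len"]]),
                        ssc = unname(ssc[["len"]]), ir = unname(L)))
  class(out) <- "quadripartite"
  out
}

#' @export
print.quadripartite <- function(x, ...) {
  cat(sprintf("quadripartite: total %d = LSC %d + SSC %d + 2 x IR %d\n",
              x$sizes[["total"]], x$sizes[["lsc"]], x$sizes[["ssc"]],
              x$sizes[["ir"]]))
  invisible(x)
}

#' Canonically rotate, strand and orient a plastome
#'
#' Reports the genome with origin at the LSC start. Because short-read data
#' cannot distinguish the two single-copy-region orientation isomers that
#' plastomes adopt in vivo (the "flip-flop" forms differing in SSC
#' orientation), the canonical form considers both strands and both SSC
#' orientations and keeps the lexicographically smallest of the rotated
#' sequences; assemblies and truth genomes then compare equal.
#'
#' @param genome A `plastome` (features, if any, are dropped: canonical
#'   form is for sequence comparison).
#' @param min_ir Minimum IR length for detection.
#' @return A `plastome` with `regions` set.
#' @export
canonical_plastome <- function(genome, min_ir = 1000L) {
  s <- if (inherits(genome, "plastome")) genome$seq else toupper(genome)
  cand <- character(0)
  for (i in 1:2) {
    ss <- if (i == 1) s else revcomp(s)
    q <- partition_quadripartite(ss)
    rot <- rotate_seq(ss, q$lsc[["start"]])
    q2 <- partition_quadripartite(rot)
    ss_start <- q2$ssc[["start"]]; ss_len <- q2$ssc[["len"]]
    flipped <- paste0(substr(rot, 1, ss_start),
                      revcomp(substr(rot, ss_start + 1L, ss_start + ss_len)),
                      substr(rot, ss_start + ss_len + 1L, nchar(rot)))
    cand <- c(cand, rot, flipped)
  }
  g <- as_plastome(sort(cand)[1])
  q <- partition_quadripartite(g$seq)
  g$regions <- list(lsc = c(start = 0L, len = q$sizes[["lsc"]]),
                    irb = c(start = q$irb[["start"]], len = q$sizes[["ir"]]),
                    ssc = c(start = q$ssc[["start"]], len = q$sizes[["ssc"]]),
                    ira = c(start = q$ira[["start"]], len = q$sizes[["ir"]]))
  g
}

#' Are two plastomes the same molecule?
#'
#' Equality up to rotation, strand and the SSC orientation isomer (see
#' [canonical_plastome()]).
#'
#' @param a,b `plastome` objects or sequences.
#' @return TRUE/FALSE.
#' @export
plastome_equivalent <- function(a, b) {
  identical(canonical_plastome(a)$seq, canonical_plastome(b)$seq)
}

#' Do two circular genomes match up to rotation and strand?
#'
#' @param a,b `plastome` objects or sequences.
#' @return TRUE/FALSE.
#' @export
same_circular_sequence <- function(a, b) {
  sa <- if (inherits(a, "plastome")) a$seq else toupper(a)
  sb <- if (inherits(b, "plastome")) b$seq else toupper(b)
  if (nchar(sa) != nchar(sb)) return(FALSE)
  # rotation + strand equivalence via doubled-string search
  grepl(sa, paste0(sb, sb), fixed = TRUE) ||
    grepl(sa, paste0(revcomp(sb), revcomp(sb)), fixed = TRUE)
}

#' Gene / intron / intergenic space accounting
#'
#' Labels every base of the circle as exon (gene space), intron or
#' intergenic, with precedence exon > intron > intergenic at overlaps, and
#' reports the three percentages (they sum to 100 exactly, up to float
#' formatting).
#'
#' @param genome A `plastome`.
#' @param features Feature data frame (defaults to the genome's).
#' @param include_pseudogenes Count pseudogene features as gene space?
#' @return An object of class `space_accounting`: `pct_gene`, `pct_intron`,
#'   `pct_intergenic` plus base counts.
#' @export
space_accounting <- function(genome, features = NULL,
                             include_pseudogenes = TRUE) {
  stopifnot(inherits(genome, "plastome"))
  if (is.null(features)) features <- genome$features
  n <- genome$length
  lab <- integer(n) # 0 intergenic, 1 intron, 2 exon
  for (i in seq_len(nrow(features))) {
    if (!include_pseudogenes && features$kind[i] == "pseudogene") next
    span <- circ_positions(features$start[i], features$end[i], n)
    lab[span] <- pmax(lab[span], 1L)
    ex <- features$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      p <- circ_positions(ex[j, 1], ex[j, 2], n)
      lab[p] <- 2L
    }
  }
  counts <- c(gene = sum(lab == 2L), intron = sum(lab == 1L),
              intergenic = sum(lab == 0L))
  out <- list(pct_gene = 100 * counts[["gene"]] / n,
              pct_intron = 100 * counts[["intron"]] / n,
              pct_intergenic = 100 * counts[["intergenic"]] / n,
              counts = counts, length = n)
  class(out) <- "space_accounting"
  out
}

circ_positions <- function(start, end, n) {
  # 0-based half-open, possibly wrapping the origin; returns 1-based indices
  len <- end - start
  if (len < 0) len <- len + n
  (seq.int(start, length.out = len) %% n) + 1L
}

#' @export
print.space_accounting <- function(x, ...) {
  cat(sprintf("space: gene %.2f%% | intron %.2f%% | intergenic %.2f%%\n",
              x$pct_gene, x$pct_intron, x$pct_intergenic))
  invisible(x)
}

#' Check published quadripartite size arithmetic
#'
#' For a table of per-species region sizes, verifies that
#' LSC + SSC + 2 x IR equals the reported plastome size, flagging (rather
#' than silently correcting) inconsistent rows.
#'
#' @param df Data frame with columns `species`, `plastome_size`, `lsc_size`,
#'   `ssc_size`, `ir_size`.
#' @return The input with `computed_size`, `difference` and `consistent`
#'   columns appended.
#' @export
check_quadripartite_sizes <- function(df) {
  stopifnot(all(c("species", "plastome_size", "lsc_size", "ssc_size", "ir_size")
                %in% names(df)))
  computed <- df$lsc_size + df$ssc_size + 2L * df$ir_size
  df$computed_size <- computed
  df$difference <- computed - df$plastome_size
  df$consistent <- df$difference == 0L
  df
}
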