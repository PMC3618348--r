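# Plastome assembly: recruit plastome-origin reads against a reference set,
# assemble them with a de Bruijn unitig assembler across a k sweep, pick
# the k whose additive contig length is closest to the expected plastome
# size, merge contigs on high-identity overlaps, close remaining gaps by
# recruiting against successively closer relatives, and resolve the second
# inverted-repeat copy to complete the circle.

#' Recruit plastome-origin reads
#'
#' A read pair is recruited when either mate is assigned to any reference
#' under the classifier contract (k-mer vote plus banded edit-distance
#' confirmation).
#'
#' @param reads A `read_set`.
#' @param references Named character vector of reference genomes.
#' @param k K-mer size for the vote.
#' @param min_hit_fraction Minimum hit fraction to nominate a candidate
#'   locus (kept permissive: recruitment favours recall, the edit-distance
#'   check supplies precision).
#' @param max_edit_distance Edit-distance cut-off.
#' @return List with `reads` (recruited subset), `recruited` (logical per
#'   pair) and `index` (the reference index, reusable).
#' @export
recruit_reads <- function(reads, references, k = 21L, min_hit_fraction = 0.05,
                          max_edit_distance = 5L, circular = TRUE) {
  if (length(references) == 0)
    stop_pk("no recruitment references given", class = "parameter_error")
  if (is.null(names(references)))
    names(references) <- paste0("ref", seq_along(references))
  idx <- build_panel_index(references,
                           setNames(rep("plastid", length(references)),
                                    names(references)), k, circular = circular)
  a1 <- assign_reads(reads$seq1, idx, min_hit_fraction, max_edit_distance)
  a2 <- assign_reads(reads$seq2, idx, min_hit_fraction, max_edit_distance)
  rec <- a1$ref > 0 | a2$ref > 0
  list(reads = reads[rec, , drop = FALSE], recruited = rec, index = idx)
}

#' De novo assembly of reads into unitig contigs
#'
#' Contigs are the non-branching paths of the canonical k-mer graph; with
#' `prune = TRUE`, k-mers below `min_count` are dropped first and short
#' unitigs with coverage far below the (length-weighted) median -- error
#' tips and bubble arms -- are removed iteratively.
#'
#' @param reads A `read_set` or character vector of read sequences.
#' @param k Odd k-mer size (< read length).
#' @param min_count Minimum k-mer multiplicity (`"auto"` picks 1 for clean
#'   small inputs and 2 as soon as singletons dominate the spectrum).
#' @param prune Remove weak tips/bubbles?
#' @return A data frame of contigs: `id`, `seq`, `coverage`, `k`.
#' @export
debruijn_assemble <- function(reads, k, min_count = 1L, prune = FALSE) {
  seqs <- if (inherits(reads, "read_set")) c(reads$seq1, reads$seq2)
          else as.character(reads)
  if (length(seqs) == 0)
    return(data.frame(id = character(), seq = character(), coverage = numeric(),
                      k = integer(), stringsAsFactors = FALSE))
  if (identical(min_count, "auto")) {
    ## crude spectrum heuristic: with appreciable coverage, true k-mers are
    ## seen many times and singleton k-mers are dominated by errors
    tot <- sum(nchar(seqs))
    min_count <- if (tot > 20L * 3L * k) 2L else 1L
  }
  res <- cpp_debruijn(seqs, as.integer(k), as.integer(min_count), prune, 3L)
  n <- length(res$seq)
  data.frame(id = sprintf("contig%03d", seq_len(n)), seq = res$seq,
             coverage = res$coverage,
             k = rep(as.integer(k), n), stringsAsFactors = FALSE)
}

#' Additive length of an assembly
#' @param contigs Contig data frame.
#' @return Total contig length in bases.
#' @export
additive_length <- function(contigs) sum(nchar(contigs$seq))

#' Select the assembly k by additive length
#'
#' Picks the k whose additive contig length is closest to the expected
#' plastome size; ties go to the larger k.
#'
#' @param assemblies Named list (names = k) of contig data frames, or a
#'   numeric vector of additive lengths named by k.
#' @param target_length Expected genome size in bases.
#' @return The selected k (integer).
#' @export
select_assembly <- function(assemblies, target_length) {
  if (length(assemblies) == 0)
    stop_pk("no assemblies to select from", class = "parameter_error")
  adds <- if (is.numeric(assemblies)) assemblies
          else vapply(assemblies, additive_length, numeric(1))
  ks <- as.integer(names(adds))
  stopifnot(!anyNA(ks))
  d <- abs(adds - target_length)
  cand <- which(d == min(d))
  ks[cand[which.max(ks[cand])]]
}

#' Merge contigs on high-identity overlaps
#'
#' Greedy best-overlap merging: at each step the pair (in either relative
#' orientation) with the highest-scoring suffix-prefix overlap of at least
#' `min_overlap` bases at `min_identity` is joined, until no admissible
#' overlap remains.
#'
#' @param contigs Character vector of contig sequences (or contig data
#'   frame).
#' @param min_identity Minimum overlap identity (fraction).
#' @param min_overlap Minimum overlap length in bases.
#' @return List with `contigs` (merged sequences) and `overlaps` (lengths of
#'   the accepted joins; merged length equals input length minus their sum).
#' @export
merge_contigs <- function(contigs, min_identity = 0.97, min_overlap = 50L) {
  if (is.data.frame(contigs)) contigs <- contigs$seq
  if (min_identity <= 0 || min_identity > 1 || min_overlap < 1)
    stop_pk("min_identity must be in (0,1] and min_overlap >= 1",
            class = "parameter_error")
  seqs <- as.character(contigs)
  accepted <- integer(0)
  repeat {
    n <- length(seqs)
    if (n < 2) break
    best <- NULL
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        for (flip in c(FALSE, TRUE)) {
          b <- if (flip) revcomp(seqs[j]) else seqs[j]
          ov <- cpp_best_overlap(seqs[i], b, as.integer(min_overlap), min_identity)
          if (ov$found) {
            key <- c(ov$matches, ov$len, -i, -j, -flip)
            if (is.null(best) || isTRUE(compare_keys(key, best$key) > 0)) {
              best <- list(key = key, i = i, j = j, flip = flip, len = ov$len)
            }
          }
        }
      }
    }
    if (is.null(best)) break
    b <- if (best$flip) revcomp(seqs[best$j]) else seqs[best$j]
    merged <- paste0(seqs[best$i], substr(b, best$len + 1L, nchar(b)))
    accepted <- c(accepted, best$len)
    seqs <- c(merged, seqs[-c(best$i, best$j)])
  }
  list(contigs = seqs, overlaps = accepted)
}

compare_keys <- function(a, b) {
  for (t in seq_along(a)) {
    if (a[t] > b[t]) return(1L)
    if (a[t] < b[t]) return(-1L)
  }
  0L
}

#' Order and orient contigs along a reference
#'
#' Mirrors ordering draft contigs against a pre-existing plastome
#' annotation: each contig is located on the reference by k-mer diagonal
#' voting, reverse-complemented if needed, and sorted by reference position.
#'
#' @param contigs Character vector of contigs.
#' @param reference Reference genome sequence.
#' @param k K-mer size.
#' @return Data frame `seq`, `ref_pos`, `strand`, `gap_after` (estimated
#'   distance on the reference to the next contig; NA for the last or for
#'   unplaced contigs).
#' @export
order_contigs <- function(contigs, reference, k = 21L) {
  if (is.data.frame(contigs)) contigs <- contigs$seq
  idx <- build_panel_index(c(ref = reference), c(ref = "plastid"), k)
  res <- assign_reads(contigs, idx, min_hit_fraction = 0, max_edit_distance = 0L,
                      verify = FALSE)
  strand <- ifelse(!is.na(res$strand) & res$strand == 1L, "-", "+")
  seqs <- ifelse(strand == "-", revcomp(contigs), contigs)
  placed <- res$ref > 0 & !is.na(res$pos)
  out <- data.frame(seq = seqs, ref_pos = ifelse(placed, res$pos, NA_integer_),
                    strand = strand, stringsAsFactors = FALSE)
  out <- out[order(is.na(out$ref_pos), out$ref_pos), , drop = FALSE]
  gap <- rep(NA_integer_, nrow(out))
  if (nrow(out) > 1) {
    for (i in seq_len(nrow(out) - 1L)) {
      if (!is.na(out$ref_pos[i]) && !is.na(out$ref_pos[i + 1L]))
        gap[i] <- out$ref_pos[i + 1L] - (out$ref_pos[i] + nchar(out$seq[i]))
    }
  }
  out$gap_after <- gap
  rownames(out) <- NULL
  out
}

#' Assemble recruited reads across a k sweep
#'
#' @param reads Recruited `read_set` (or sequence vector).
#' @param ks Integer vector of odd k values to try.
#' @param target_length Expected plastome size (used to select k).
#' @param min_count,prune Passed to [debruijn_assemble()].
#' @param min_identity,min_overlap Passed to [merge_contigs()].
#' @param min_contig Contigs shorter than this are dropped before merging
#'   (assembler chaff).
#' @return An `assembly_result`: list with `contigs` (character vector after
#'   merging), `k`, `additive_length` (of the selected pre-merge assembly),
#'   `sweep` (per-k additive lengths), `status` and `overlaps`.
#' @export
sweep_assemble <- function(reads, ks, target_length, min_count = 1L,
                           prune = TRUE, min_identity = 0.97, min_overlap = 50L,
                           min_contig = 200L) {
  sweeps <- lapply(ks, function(k) debruijn_assemble(reads, k, min_count, prune))
  names(sweeps) <- ks
  ksel <- select_assembly(sweeps, target_length)
  chosen <- sweeps[[as.character(ksel)]]
  chosen <- chosen[nchar(chosen$seq) >= min_contig, , drop = FALSE]
  merged <- merge_contigs(chosen, min_identity, min_overlap)
  res <- list(contigs = merged$contigs, k = ksel,
              additive_length = additive_length(chosen),
              sweep = vapply(sweeps, additive_length, numeric(1)),
              overlaps = merged$overlaps,
              status = if (length(merged$contigs) == 1L) "gapless" else "draft")
  class(res) <- "assembly_result"
  res
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("assembly_result: %d contig(s), k=%d, additive %d bp, status %s\n",
              length(x$contigs), x$k, as.integer(x$additive_length), x$status))
  invisible(x)
}

#' Iterative relative-guided gap closing
#'
#' For as long as the assembly has more than one contig, reads are
#' additionally recruited against the next most closely related genome
#' (closest first) and the pool is reassembled; iteration stops when the
#' assembly is gapless or relatives are exhausted. Remaining gaps are
#' reported with their flanking contigs (gap closure by PCR is outside this
#' tool and is represented by the report).
#'
#' @param assembly An `assembly_result`.
#' @param reads The full (quality-filtered) `read_set`.
#' @param recruited Logical vector marking pairs already recruited.
#' @param relatives Named character vector of relative genomes, ordered
#'   closest first.
#' @param reference Primary reference sequence (for ordering/gap reporting).
#' @param ks,target_length,... Passed through to [sweep_assemble()].
#' @return The updated `assembly_result`, with a `gap_report` data frame.
#' @export
iterative_gap_close <- function(assembly, reads, recruited, relatives,
                                reference, ks = NULL, target_length = NULL, ...) {
  if (is.null(ks)) ks <- assembly$k
  if (is.null(target_length)) target_length <- assembly$additive_length
  pool <- recruited
  for (rel in seq_along(relatives)) {
    if (length(assembly$contigs) <= 1L) break
    rec <- recruit_reads(reads[!pool, , drop = FALSE], relatives[rel])
    if (!any(rec$recruited)) next
    pool[!pool] <- rec$recruited
    assembly2 <- sweep_assemble(reads[pool, , drop = FALSE], ks, target_length, ...)
    assembly <- assembly2
  }
  # local splinting: recruit reads against the gap flanks, reassemble them
  # at a short k and join contigs through any bridge that overlaps both
  # flanks at the merge thresholds
  ord <- order_contigs(assembly$contigs, reference)
  if (nrow(ord) > 1) {
    contigs <- ord$seq
    for (pass in 1:5) {
      progress <- FALSE
      i <- 1L
      while (i < length(contigs)) {
        spl <- splint_gap(contigs[i], contigs[i + 1L], reads)
        if (!is.null(spl)) {
          contigs[i] <- spl
          contigs <- contigs[-(i + 1L)]
          progress <- TRUE
        } else i <- i + 1L
      }
      if (!progress) break
    }
    remerged <- merge_contigs(contigs)
    assembly$contigs <- remerged$contigs
    assembly$overlaps <- c(assembly$overlaps, remerged$overlaps)
  }
  ord <- order_contigs(assembly$contigs, reference)
  gaps <- which(!is.na(ord$gap_after) & ord$gap_after > 0)
  assembly$gap_report <- if (length(gaps)) {
    data.frame(flank_a = sprintf("contig%03d", gaps),
               flank_b = sprintf("contig%03d", gaps + 1L),
               est_gap = ord$gap_after[gaps], stringsAsFactors = FALSE)
  } else {
    data.frame(flank_a = character(), flank_b = character(),
               est_gap = integer(), stringsAsFactors = FALSE)
  }
  assembly$contigs <- ord$seq
  assembly$status <- if (length(assembly$contigs) == 1L) "gapless" else "draft"
  assembly
}

# Try to close the gap between ordered contigs A and B: recruit reads
# matching either flank, assemble them locally at a short k, and accept a
# bridge contig that overlaps the A tail and the B head at the published
# merge thresholds. Returns the joined sequence or NULL.
splint_gap <- function(a, b, reads, flank = 400L, k_local = c(51L, 41L, 31L),
                       min_overlap = 50L, min_identity = 0.97) {
  fa <- substr(a, max(1L, nchar(a) - flank + 1L), nchar(a))
  for (bb in c(b, revcomp(b))) {
    fb <- substr(bb, 1L, min(flank, nchar(bb)))
    rec <- recruit_reads(reads, c(flank_a = fa, flank_b = fb), circular = FALSE)
    if (!any(rec$recruited)) next
    for (kl in k_local) {
      local <- debruijn_assemble(rec$reads, kl, min_count = 1L, prune = TRUE)
      local <- local[nchar(local$seq) >= 2L * min_overlap, , drop = FALSE]
      for (cand in local$seq) {
        for (cc in c(cand, revcomp(cand))) {
          ov_a <- cpp_best_overlap(a, cc, as.integer(min_overlap), min_identity)
          if (!ov_a$found || ov_a$len == nchar(cc)) next
          joined <- paste0(a, substr(cc, ov_a$len + 1L, nchar(cc)))
          ov_b <- cpp_best_overlap(joined, bb, as.integer(min_overlap), min_identity)
          if (ov_b$found && ov_b$len < nchar(bb))
            return(paste0(joined, substr(bb, ov_b$len + 1L, nchar(bb))))
        }
      }
    }
  }
  NULL
}

#' Resolve the inverted repeat and complete the circle
#'
#' Takes the linear scaffold covering LSC + IRb + SSC (as produced by
#' merging a quadripartite assembly: its two ends carry short fold-back
#' fragments of the unassembled IRa copy), locates the full IR copy from
#' the reverse-complement matches between the scaffold ends and its
#' interior, and appends IRa = revcomp(IRb) to close the circle. Boundary
#' coordinates are reported for downstream verification.
#'
#' @param scaffold Character scaffold sequence, or a `plastome` (returned
#'   unchanged with a warning).
#' @param min_ir Minimum credible IR length.
#' @param seed_len Minimum fold-back fragment match length.
#' @return List with `genome` (canonically rotated `plastome`, or NULL if
#'   unresolved), `report` (boundary report with `status` in
#'   `resolved`/`already_circular`/`asymmetric`) .
#' @export
resolve_ir <- function(scaffold, min_ir = 1000L, seed_len = 20L) {
  if (inherits(scaffold, "plastome")) {
    warning("scaffold is already a circular plastome; returning unchanged")
    return(list(genome = scaffold,
                report = list(status = "already_circular")))
  }
  s <- toupper(scaffold)
  n <- nchar(s)
  m <- cpp_revcomp_selfmatches(s, 15L, as.integer(seed_len), FALSE)
  if (nrow(m) == 0)
    stop_pk("no inverted-repeat evidence found in scaffold (try the structure module)",
            class = "no_ir_error")
  full <- m[m[, "len"] >= min_ir, , drop = FALSE]
  if (nrow(full) > 0) {
    warning("scaffold already contains two inverted-repeat copies; treating as circular")
    g <- canonical_plastome(as_plastome(s))
    return(list(genome = g, report = list(status = "already_circular")))
  }
  pref <- m[m[, "start1"] <= 2L & m[, "start2"] > m[, "len"], , drop = FALSE]
  suff <- m[m[, "start2"] + m[, "len"] >= n - 2L &
              m[, "start1"] + m[, "len"] < n - 2L, , drop = FALSE]
  have_pref <- nrow(pref) > 0
  have_suff <- nrow(suff) > 0
  if (!have_pref || !have_suff) {
    return(list(genome = NULL,
                report = list(status = "asymmetric",
                              prefix_anchor = have_pref,
                              suffix_anchor = have_suff,
                              matches = m)))
  }
  p <- pref[1, ]; q <- suff[1, ]
  irb_start <- p[["start2"]]
  irb_end <- q[["start1"]] + q[["len"]]
  if (irb_end - irb_start < min_ir || irb_start <= p[["len"]] ||
      n - q[["len"]] <= irb_end) {
    return(list(genome = NULL,
                report = list(status = "asymmetric", irb = c(irb_start, irb_end),
                              matches = m)))
  }
  irb <- substr(s, irb_start + 1L, irb_end)
  core <- substr(s, p[["len"]] + 1L, n - q[["len"]]) # LSC + IRb + SSC
  circle <- paste0(core, revcomp(irb))
  g <- canonical_plastome(as_plastome(circle), min_ir = min_ir)
  list(genome = g,
       report = list(status = "resolved",
                     irb = c(start = unname(irb_start), end = unname(irb_end)),
                     prefix_fragment = unname(p[["len"]]),
                     suffix_fragment = unname(q[["len"]])))
}

#' Full assembly pipeline for one sample
#'
#' recruit -> k sweep -> merge -> (optional) iterative gap closing ->
#' IR resolution.
#'
#' @param reads A quality-filtered `read_set`.
#' @param references Named character vector of recruitment references.
#' @param ks K sweep values.
#' @param target_length Expected plastome size.
#' @param relatives Optional ordered relatives for gap closing.
#' @param ... Passed to [sweep_assemble()].
#' @return List with `genome`, `assembly`, `ir_report`.
#' @export
assemble_plastome <- function(reads, references, ks = c(41L, 51L, 61L),
                              target_length, relatives = NULL, ...) {
  rec <- recruit_reads(reads, references)
  assembly <- sweep_assemble(rec$reads, ks, target_length, ...)
  if (length(assembly$contigs) > 1L) {
    assembly <- iterative_gap_close(assembly, reads, rec$recruited,
                                    relatives %||% character(0),
                                    references[[1]], ks = ks,
                                    target_length = target_length, ...)
  }
  if (length(assembly$contigs) != 1L) {
    return(list(genome = NULL, assembly = assembly,
                ir_report = list(status = "unresolved_gaps")))
  }
  ir <- resolve_ir(assembly$contigs[[1]])
  list(genome = ir$genome, assembly = assembly, ir_report = ir$report)
}
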