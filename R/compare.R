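# Whole-plastome pairwise comparison: anchor-based global alignment,
# VISTA-like sliding-window identity tracks on reference coordinates, and
# the catalogue of large deletions within a named region.

#' Anchor-based pairwise whole-genome alignment
#'
#' Anchors are maximal runs of k-mers occurring exactly once in each
#' sequence; they are chained colinearly (longest increasing subsequence on
#' query position) and the inter-anchor segments are filled with an affine
#' Needleman-Wunsch alignment, giving an end-to-end alignment. Query-gap
#' runs are normalised to their leftmost equivalent placement so deletion
#' breakpoints are reproducible.
#'
#' @param reference,query Sequences (character or `plastome`), canonically
#'   rotated/stranded beforehand (see [canonical_plastome()]).
#' @param k Anchor k-mer size.
#' @param ref_id,query_id Names recorded in the alignment.
#' @return Object of class `pairwise_alignment`: run-length encoded columns
#'   (`runs` with ops M match, X mismatch, D query gap, I query insertion),
#'   plus the two sequences.
#' @export
align_pair <- function(reference, query, k = 21L, ref_id = "reference",
                       query_id = "query") {
  r <- if (inherits(reference, "plastome")) reference$seq else toupper(reference)
  q <- if (inherits(query, "plastome")) query$seq else toupper(query)
  anc <- cpp_shared_unique_anchors(r, q, as.integer(k))
  if (nrow(anc) == 0)
    stop_pk("alignment failure: no unique shared anchors between %s and %s",
            ref_id, query_id, class = "alignment_failure")
  # chain colinearly: anchors sorted by ref start; LIS on query start
  keep <- lis_indices(anc[, "query_start"])
  anc <- anc[keep, , drop = FALSE]
  # trim overlaps between consecutive anchors
  if (nrow(anc) > 1) {
    for (i in 2:nrow(anc)) {
      ov <- max(anc[i - 1, "ref_start"] + anc[i - 1, "len"] - anc[i, "ref_start"],
                anc[i - 1, "query_start"] + anc[i - 1, "len"] - anc[i, "query_start"],
                0L)
      anc[i, "ref_start"] <- anc[i, "ref_start"] + ov
      anc[i, "query_start"] <- anc[i, "query_start"] + ov
      anc[i, "len"] <- anc[i, "len"] - ov
    }
    anc <- anc[anc[, "len"] > 0, , drop = FALSE]
  }
  pieces <- vector("list", 2L * nrow(anc) + 1L)
  pi <- 0L
  add_piece <- function(v) { pi <<- pi + 1L; pieces[[pi]] <<- v }
  nw_fill <- function(rseg, qseg) {
    nr <- nchar(rseg); nq <- nchar(qseg)
    if (nr == 0 && nq == 0) return()
    if (nr == 0) { add_piece(rep("I", nq)); return() }
    if (nq == 0) { add_piece(rep("D", nr)); return() }
    if (nr == nq) {
      # anchored equal-length segment: the parsimonious fill is ungapped
      rc <- strsplit(rseg, "", fixed = TRUE)[[1]]
      qc <- strsplit(qseg, "", fixed = TRUE)[[1]]
      add_piece(ifelse(rc == qc, "M", "X"))
      return()
    }
    sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    aln <- Biostrings::pairwiseAlignment(qseg, rseg, type = "global",
                                         substitutionMatrix = sub_mat,
                                         gapOpening = 4, gapExtension = 0.5)
    pc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sc <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    v <- character(length(pc))
    v[sc == "-"] <- "I"
    v[sc != "-" & pc == "-"] <- "D"
    v[sc != "-" & pc != "-" & pc == sc] <- "M"
    v[v == ""] <- "X"
    add_piece(v)
  }
  rpos <- 0L; qpos <- 0L
  for (i in seq_len(nrow(anc))) {
    rs <- anc[i, "ref_start"]; qs <- anc[i, "query_start"]; L <- anc[i, "len"]
    nw_fill(substr(r, rpos + 1L, rs), substr(q, qpos + 1L, qs))
    add_piece(rep("M", L))
    rpos <- rs + L; qpos <- qs + L
  }
  nw_fill(substr(r, rpos + 1L, nchar(r)), substr(q, qpos + 1L, nchar(q)))
  colv <- unlist(pieces[seq_len(pi)])
  rl <- rle(colv)
  runs <- data.frame(op = rl$values, len = rl$lengths, stringsAsFactors = FALSE)
  runs <- normalize_gaps(runs, r, q)
  out <- list(ref_id = ref_id, query_id = query_id, runs = runs,
              ref_len = nchar(r), query_len = nchar(q), ref = r, query = q)
  stopifnot(sum(runs$len[runs$op %in% c("M", "X", "D")]) == nchar(r),
            sum(runs$len[runs$op %in% c("M", "X", "I")]) == nchar(q))
  class(out) <- "pairwise_alignment"
  out
}

lis_indices <- function(x) {
  # longest strictly increasing subsequence; returns indices
  n <- length(x)
  if (n == 0) return(integer(0))
  tails <- integer(0)   # values
  tidx <- integer(0)    # index of tail element
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(x[i] - 1L, tails) # rightmost tail < x[i]
    prev[i] <- if (j > 0) tidx[j] else 0L
    if (j == length(tails)) { tails <- c(tails, x[i]); tidx <- c(tidx, i) }
    else { tails[j + 1L] <- x[i]; tidx[j + 1L] <- i }
  }
  out <- integer(0)
  cur <- tidx[length(tidx)]
  while (cur > 0) { out <- c(cur, out); cur <- prev[cur] }
  out
}

# shift D runs (and I runs) to their leftmost equivalent placement
normalize_gaps <- function(runs, r, q) {
  rch <- strsplit(r, "", fixed = TRUE)[[1]]
  qch <- strsplit(q, "", fixed = TRUE)[[1]]
  repeat {
    changed <- FALSE
    rpos <- 0L; qpos <- 0L
    i <- 1L
    while (i <= nrow(runs)) {
      op <- runs$op[i]; len <- runs$len[i]
      if ((op == "D" || op == "I") && i > 1 && runs$op[i - 1] == "M" &&
          runs$len[i - 1] > 0) {
        shifted <- 0L
        if (op == "D") {
          s <- rpos; e <- rpos + len
          while (runs$len[i - 1] - shifted > 0 && s - shifted > 0 &&
                 rch[s - shifted] == rch[e - shifted] &&
                 qch[qpos - shifted] == rch[e - shifted]) shifted <- shifted + 1L
        } else {
          s <- qpos; e <- qpos + len
          while (runs$len[i - 1] - shifted > 0 && s - shifted > 0 &&
                 qch[s - shifted] == qch[e - shifted] &&
                 rch[rpos - shifted] == qch[e - shifted]) shifted <- shifted + 1L
        }
        if (shifted > 0) {
          changed <- TRUE
          runs$len[i - 1] <- runs$len[i - 1] - shifted
          # columns shifted past the gap become M columns after it
          if (i < nrow(runs) && runs$op[i + 1] == "M") {
            runs$len[i + 1] <- runs$len[i + 1] + shifted
          } else {
            runs <- rbind(runs[seq_len(i), , drop = FALSE],
                          data.frame(op = "M", len = shifted,
                                     stringsAsFactors = FALSE),
                          if (i < nrow(runs)) runs[(i + 1):nrow(runs), , drop = FALSE])
          }
          if (runs$len[i - 1] == 0) {
            runs <- runs[-(i - 1), , drop = FALSE]
            i <- i - 1L
          }
          rpos <- rpos - shifted
          qpos <- qpos - shifted
        }
      }
      if (op %in% c("M", "X", "D")) rpos <- rpos + len
      if (op %in% c("M", "X", "I")) qpos <- qpos + len
      i <- i + 1L
    }
    if (!changed) break
  }
  rownames(runs) <- NULL
  runs
}

#' Left-normalise a deletion interval on a reference
#'
#' Shifts a deletion `[start, start+len)` to its leftmost equivalent
#' placement (the same convention [align_pair()] applies to query gaps), so
#' planted event coordinates can be compared with catalogued ones.
#'
#' @param ref Reference sequence.
#' @param start 0-based deletion start.
#' @param len Deletion length.
#' @return The normalised 0-based start.
#' @export
normalize_deletion_left <- function(ref, start, len) {
  ch <- strsplit(ref, "", fixed = TRUE)[[1]]
  while (start > 0 && ch[start] == ch[start + len]) start <- start - 1L
  start
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: %s vs %s | identity %.2f%% | %d runs\n",
              x$ref_id, x$query_id, alignment_identity(x), nrow(x$runs)))
  invisible(x)
}

#' Overall alignment identity
#'
#' Matches over all alignment columns (gap columns count against identity),
#' as a percentage.
#'
#' @param aln A `pairwise_alignment`.
#' @return Numeric percentage.
#' @export
alignment_identity <- function(aln) {
  100 * sum(aln$runs$len[aln$runs$op == "M"]) / sum(aln$runs$len)
}

#' Sliding-window identity track
#'
#' Per window of reference columns: matches / window length x 100, with
#' query-gap columns counting as mismatch (insertions in the query carry no
#' reference coordinate and are not represented).
#'
#' @param aln A `pairwise_alignment`.
#' @param window,step Window size and step in reference bases.
#' @return Data frame `start`, `end` (0-based half-open), `identity`.
#' @export
window_identity <- function(aln, window = 100L, step = 25L) {
  if (window < step || window > aln$ref_len)
    stop_pk("need step <= window <= reference length", class = "parameter_error")
  consume <- aln$runs$op %in% c("M", "X", "D")
  match_vec <- rep(aln$runs$op == "M", aln$runs$len * consume)
  stopifnot(length(match_vec) == aln$ref_len)
  cs <- c(0, cumsum(match_vec))
  starts <- seq(0L, aln$ref_len - window, by = step)
  data.frame(start = starts, end = starts + window,
             identity = 100 * (cs[starts + window + 1L] - cs[starts + 1L]) / window)
}

#' Catalogue large deletions within a region
#'
#' Extracts maximal query-gap runs from each alignment, merges runs
#' separated by fewer than `merge_gap` reference columns (alignment jitter
#' can split one biological deletion), clips them to the region and keeps
#' events strictly longer than `min_len`.
#'
#' @param alignments Named list of `pairwise_alignment`s against one common
#'   reference.
#' @param region `c(start, end)`, 0-based half-open on the reference.
#' @param min_len Only deletions with length > `min_len` are recorded.
#' @param merge_gap Merge gap runs separated by fewer than this many
#'   reference columns.
#' @return Object of class `deletion_catalog`: data frame `species`,
#'   `start`, `end`, `length` (reference coordinates).
#' @export
catalog_deletions <- function(alignments, region, min_len = 40L, merge_gap = 5L) {
  if (length(region) != 2 || region[2] <= region[1])
    stop_pk("region must be c(start, end) with end > start", class = "parameter_error")
  rows <- list()
  for (sp in names(alignments)) {
    aln <- alignments[[sp]]
    if (region[2] > aln$ref_len)
      stop_pk("region exceeds reference length", class = "parameter_error")
    runs <- aln$runs
    rstart <- cumsum(c(0L, ifelse(runs$op %in% c("M", "X", "D"), runs$len, 0L)))
    dsel <- which(runs$op == "D")
    if (!length(dsel)) next
    ev <- data.frame(start = rstart[dsel], end = rstart[dsel] + runs$len[dsel],
                     gaplen = runs$len[dsel])
    # merge across small matched stretches
    merged <- ev[1, , drop = FALSE]
    if (nrow(ev) > 1) {
      for (i in 2:nrow(ev)) {
        last <- nrow(merged)
        if (ev$start[i] - merged$end[last] < merge_gap) {
          merged$end[last] <- ev$end[i]
          merged$gaplen[last] <- merged$gaplen[last] + ev$gaplen[i]
        } else merged <- rbind(merged, ev[i, ])
      }
    }
    # clip to region
    s <- pmax(merged$start, region[1]); e <- pmin(merged$end, region[2])
    lens <- pmin(merged$gaplen, e - s)
    keep <- e > s & lens > min_len
    if (any(keep)) {
      rows[[sp]] <- data.frame(species = sp, start = s[keep], end = e[keep],
                               length = lens[keep], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(species = character(), start = integer(),
                         end = integer(), length = integer(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "region") <- region
  attr(out, "min_len") <- min_len
  class(out) <- c("deletion_catalog", "data.frame")
  out
}
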