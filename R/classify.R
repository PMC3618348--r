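# Read-origin estimation against a labelled reference panel (plastid vs
# bacterial). The aligner stand-in assigns each read to the reference
# sharing the most canonical k-mers, confirms the candidate locus with a
# banded edit distance, and otherwise leaves the read unassigned. Ties are
# broken by category priority (plastid first) and then by lexical
# reference id, so the decision is deterministic.

#' Build a k-mer index over a labelled reference panel
#'
#' @param references Named character vector of reference sequences.
#' @param categories Character vector (same length/names) with values
#'   `"plastid"` or `"bacterial"`.
#' @param k Odd k-mer size between 15 and 31.
#' @param circular Logical (recycled): treat these references as circles, so
#'   reads crossing the origin still match (the index is extended by the
#'   first 300 bases of the sequence).
#' @return An object of class `panel_index`.
#' @export
build_panel_index <- function(references, categories, k = 21L,
                              circular = FALSE) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 15L || k > 31L)
    stop_pk("k must be odd and within [15, 31]", class = "parameter_error")
  if (length(references) == 0)
    stop_pk("reference panel is empty", class = "parameter_error")
  ids <- names(references)
  if (is.null(ids) || anyDuplicated(ids))
    stop_pk("references must carry unique ids", class = "parameter_error")
  categories <- unname(categories[ids])
  if (anyNA(categories) || !all(categories %in% c("plastid", "bacterial")))
    stop_pk("each reference needs a category: plastid or bacterial",
            class = "parameter_error")
  refs <- data.frame(id = ids, length = nchar(references),
                     category = categories, stringsAsFactors = FALSE)
  # priority: plastid before bacterial, then lexical id
  pr <- order(match(refs$category, c("plastid", "bacterial")), refs$id)
  priority <- integer(nrow(refs))
  priority[pr] <- seq_len(nrow(refs))
  circular <- rep_len(circular, length(references))
  idx_seqs <- ifelse(circular,
                     paste0(references, substr(references, 1L, 300L)),
                     references)
  out <- list(ptr = cpp_panel_build(unname(idx_seqs), k), k = k, refs = refs,
              priority = priority)
  class(out) <- "panel_index"
  out
}

#' @export
print.panel_index <- function(x, ...) {
  cat(sprintf("panel_index: k=%d, %d references (%d plastid, %d bacterial), %d k-mers\n",
              x$k, nrow(x$refs), sum(x$refs$category == "plastid"),
              sum(x$refs$category == "bacterial"), cpp_panel_n_kmers(x$ptr)))
  invisible(x)
}

#' Test canonical k-mer membership in a panel index
#'
#' @param index A `panel_index`.
#' @param kmers Character vector of k-mers.
#' @return Logical vector.
#' @export
panel_has_kmer <- function(index, kmers) {
  cpp_panel_has(index$ptr, kmers)
}

# low-level: assign a vector of sequences; returns integer ref index (0 =
# unassigned) plus diagnostics
assign_reads <- function(seqs, index, min_hit_fraction, max_edit_distance,
                         verify = TRUE) {
  cpp_classify(index$ptr, seqs, min_hit_fraction, as.integer(max_edit_distance),
               index$priority, verify)
}

#' Classify reads by origin against a reference panel
#'
#' Reproduces the read-origin screening used to compare tissue sources:
#' each read is assigned to a plastid or bacterial panel reference or left
#' unassigned, and the per-category proportions are reported.
#'
#' @param reads A `read_set`, or a character vector of read sequences.
#' @param index A `panel_index`.
#' @param min_hit_fraction Minimum fraction of a read's k-mers that must hit
#'   the winning reference.
#' @param max_edit_distance Banded edit-distance cut-off for locus
#'   confirmation.
#' @param subsample If the input exceeds this many reads, a seeded subsample
#'   of this size is classified.
#' @param seed Seed for the subsample draw.
#' @return An object of class `origin_report` with per-category counts and
#'   proportions, per-reference counts and the unassigned tally.
#' @export
classify_reads <- function(reads, index, min_hit_fraction = 0.5,
                           max_edit_distance = 5L, subsample = 1e5, seed = 1L) {
  seqs <- if (inherits(reads, "read_set")) c(reads$seq1, reads$seq2)
          else as.character(reads)
  if (length(seqs) > subsample) {
    with_seed(seed, idx <- sort(sample.int(length(seqs), subsample)))
    seqs <- seqs[idx]
  }
  res <- assign_reads(seqs, index, min_hit_fraction, max_edit_distance)
  n <- length(seqs)
  ref_id <- ifelse(res$ref > 0, index$refs$id[pmax(res$ref, 1L)], NA_character_)
  cat_of <- ifelse(res$ref > 0, index$refs$category[pmax(res$ref, 1L)], "unassigned")
  counts <- c(plastid = sum(cat_of == "plastid"),
              bacterial = sum(cat_of == "bacterial"),
              unassigned = sum(cat_of == "unassigned"))
  per_ref <- table(factor(ref_id, levels = index$refs$id))
  out <- list(n = n, counts = counts,
              proportions = counts / max(n, 1L),
              per_reference = as.data.frame(per_ref, responseName = "reads",
                                            stringsAsFactors = FALSE))
  names(out$per_reference)[1] <- "id"
  class(out) <- "origin_report"
  out
}

#' @export
print.origin_report <- function(x, ...) {
  cat(sprintf("origin_report: %d reads | plastid %.1f%% | bacterial %.1f%% | unassigned %.1f%%\n",
              x$n, 100 * x$proportions[["plastid"]],
              100 * x$proportions[["bacterial"]],
              100 * x$proportions[["unassigned"]]))
  invisible(x)
}

#' Origin report as a data frame (stacked-bar plot data)
#'
#' @param x An `origin_report`.
#' @param ... Unused.
#' @return Data frame with `category`, `reads`, `proportion`.
#' @export
as.data.frame.origin_report <- function(x, ...) {
  data.frame(category = names(x$counts), reads = as.integer(x$counts),
             proportion = as.numeric(x$proportions), stringsAsFactors = FALSE)
}
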