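# Read quality control. A read is flagged when (i) it contains a run of
# more than three consecutive N calls, (ii) more than three bases have a
# PHRED score of 20 or below, or (iii) its median PHRED score (lower middle
# value for even lengths) is below 20. Flagged reads are trimmed from the
# 3' end to the longest prefix on which no criterion fires; reads shorter
# than `min_len` (25 by default), before or after trimming, are discarded.

#' Assess a single read against the quality-control rules
#'
#' @param bases Read sequence (may contain N).
#' @param quals Integer PHRED scores, one per base (0-60).
#' @param min_len Minimum acceptable read length.
#' @return A list of class `qc_decision`: `action` (`"pass"`, `"trim"` or
#'   `"discard"`), `trim_to` (prefix length kept, `NA` unless trimming) and
#'   `reasons` (subset of `consecutive_N`, `low_qual_count`, `low_median`,
#'   `too_short`).
#' @export
assess_read <- function(bases, quals, min_len = 25L) {
  n <- nchar(bases)
  if (length(quals) != n)
    stop_pk("quality vector length (%d) != read length (%d)", length(quals), n,
            class = "format_error")
  if (any(quals < 0 | quals > 60))
    stop_pk("PHRED scores must lie in [0, 60]", class = "format_error")
  if (n == 0)
    return(qc_decision("discard", NA_integer_, "too_short"))
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  isN <- ch == "N"
  # run length of Ns ending at each position, and its running maximum
  run <- integer(n)
  r <- 0L
  for (i in seq_len(n)) { r <- if (isN[i]) r + 1L else 0L; run[i] <- r }
  maxrun <- cummax(run)
  cnt_le20 <- cumsum(quals <= 20)
  cnt_lt20 <- cumsum(quals < 20)
  Ls <- seq_len(n)
  ok_nrun <- maxrun <= 3L
  ok_lowq <- cnt_le20 <= 3L
  # lower-middle median of the first L values is < 20 iff at least
  # floor((L+1)/2) of them are < 20
  ok_median <- cnt_lt20 < (Ls + 1L) %/% 2L
  ok <- ok_nrun & ok_lowq & ok_median

  reasons <- character(0)
  if (!ok_nrun[n]) reasons <- c(reasons, "consecutive_N")
  if (!ok_lowq[n]) reasons <- c(reasons, "low_qual_count")
  if (!ok_median[n]) reasons <- c(reasons, "low_median")
  if (n < min_len) {
    return(qc_decision("discard", NA_integer_, unique(c(reasons, "too_short"))))
  }
  if (ok[n]) return(qc_decision("pass", NA_integer_, character(0)))
  good <- which(ok & Ls >= min_len)
  if (length(good) == 0)
    return(qc_decision("discard", NA_integer_, unique(c(reasons, "too_short"))))
  qc_decision("trim", max(good), reasons)
}

qc_decision <- function(action, trim_to, reasons) {
  structure(list(action = action, trim_to = trim_to, reasons = reasons),
            class = "qc_decision")
}

#' @export
print.qc_decision <- function(x, ...) {
  cat("qc_decision:", x$action,
      if (!is.na(x$trim_to)) sprintf("(keep %d bp)", x$trim_to) else "",
      if (length(x$reasons)) paste0("[", paste(x$reasons, collapse = ","), "]") else "",
      "\n")
  invisible(x)
}

new_qc_stats <- function() {
  list(input = 0L, passed = 0L, trimmed = 0L, discarded = 0L,
       pair_dropped = 0L,
       reasons = c(consecutive_N = 0L, low_qual_count = 0L,
                   low_median = 0L, too_short = 0L))
}

#' Filter a paired read set
#'
#' Applies [assess_read()] to every mate; trimmed reads keep their longest
#' clean prefix. Under the default pair policy (`"both"`) a pair is dropped
#' whenever either mate is discarded, which keeps mates synchronised for
#' assembly; `"independent"` keeps surviving mates.
#'
#' @param reads A `read_set` (see [simulate_reads()]).
#' @param min_len Minimum read length.
#' @param pair_policy `"both"` or `"independent"`.
#' @return List with `reads` (filtered `read_set`) and `stats` (counts:
#'   `input`, `passed`, `trimmed`, `discarded`, `pair_dropped`, per-reason
#'   tallies; `passed + trimmed + discarded == input`).
#' @export
filter_reads <- function(reads, min_len = 25L, pair_policy = c("both", "independent")) {
  pair_policy <- match.arg(pair_policy)
  stats <- new_qc_stats()
  n <- nrow(reads)
  stats$input <- 2L * n
  if (n == 0) return(list(reads = reads, stats = stats))
  q1 <- decode_quals(reads$qual1)
  q2 <- decode_quals(reads$qual2)
  d1 <- vector("list", n)
  d2 <- vector("list", n)
  for (i in seq_len(n)) {
    d1[[i]] <- assess_read(reads$seq1[i], q1[[i]], min_len)
    d2[[i]] <- assess_read(reads$seq2[i], q2[[i]], min_len)
  }
  act1 <- vapply(d1, `[[`, character(1), "action")
  act2 <- vapply(d2, `[[`, character(1), "action")
  for (d in c(d1, d2)) {
    for (rs in d$reasons) stats$reasons[[rs]] <- stats$reasons[[rs]] + 1L
  }
  stats$passed <- sum(act1 == "pass") + sum(act2 == "pass")
  stats$trimmed <- sum(act1 == "trim") + sum(act2 == "trim")
  stats$discarded <- sum(act1 == "discard") + sum(act2 == "discard")
  keep <- if (pair_policy == "both") act1 != "discard" & act2 != "discard"
          else act1 != "discard" | act2 != "discard"
  stats$pair_dropped <- sum(act1 == "discard" | act2 == "discard") -
    sum(act1 == "discard" & act2 == "discard")
  out <- reads[keep, , drop = FALSE]
  # apply trims
  tr1 <- vapply(d1, `[[`, integer(1), "trim_to")[keep]
  tr2 <- vapply(d2, `[[`, integer(1), "trim_to")[keep]
  do_trim <- function(seqs, quals, tr) {
    idx <- which(!is.na(tr))
    if (length(idx)) {
      seqs[idx] <- substring(seqs[idx], 1L, tr[idx])
      quals[idx] <- substring(quals[idx], 1L, tr[idx])
    }
    list(seqs, quals)
  }
  t1 <- do_trim(out$seq1, out$qual1, tr1)
  t2 <- do_trim(out$seq2, out$qual2, tr2)
  out$seq1 <- t1[[1]]; out$qual1 <- t1[[2]]
  out$seq2 <- t2[[1]]; out$qual2 <- t2[[2]]
  rownames(out) <- NULL
  list(reads = out, stats = stats)
}

#' Quality-filter FASTQ files
#'
#' File-level wrapper around [filter_reads()] for one or two (paired) FASTQ
#' streams; paired inputs are validated mate-by-mate.
#'
#' @param in1,in2 Input FASTQ paths (`in2 = NULL` for single-end).
#' @param out1,out2 Output FASTQ paths.
#' @param min_len Minimum read length.
#' @param pair_policy See [filter_reads()].
#' @param quality_encoding `"phred33"` or `"phred64"`.
#' @return The QC stats list, invisibly written next to nothing; also
#'   returned visibly.
#' @export
filter_fastq <- function(in1, out1, in2 = NULL, out2 = NULL, min_len = 25L,
                         pair_policy = "both",
                         quality_encoding = "phred33") {
  f1 <- read_fastq(in1, quality_encoding)
  if (!is.null(in2)) {
    f2 <- read_fastq(in2, quality_encoding)
    if (nrow(f1) != nrow(f2))
      stop_pk("mate files differ in record count (%d vs %d)", nrow(f1), nrow(f2),
              class = "format_error")
    base1 <- sub("/[12]$", "", f1$id)
    base2 <- sub("/[12]$", "", f2$id)
    bad <- which(base1 != base2)
    if (length(bad))
      stop_pk("mate desynchronisation at record %d (%s vs %s)",
              bad[1], f1$id[bad[1]], f2$id[bad[1]], class = "format_error")
    rs <- data.frame(id = base1, seq1 = f1$seq, seq2 = f2$seq,
                     qual1 = f1$qual, qual2 = f2$qual, stringsAsFactors = FALSE)
    class(rs) <- c("read_set", "data.frame")
    res <- filter_reads(rs, min_len, pair_policy)
    write_fastq(paste0(res$reads$id, "/1"), res$reads$seq1, res$reads$qual1, out1)
    if (!is.null(out2))
      write_fastq(paste0(res$reads$id, "/2"), res$reads$seq2, res$reads$qual2, out2)
    return(res$stats)
  }
  # single-end: reuse the pair machinery with a dummy clean mate
  n <- nrow(f1)
  stats <- new_qc_stats()
  stats$input <- n
  if (n == 0) { write_fastq(character(0), character(0), character(0), out1); return(stats) }
  quals <- decode_quals(f1$qual)
  keep <- logical(n)
  trim <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    d <- assess_read(f1$seq[i], quals[[i]], min_len)
    for (rs in d$reasons) stats$reasons[[rs]] <- stats$reasons[[rs]] + 1L
    if (d$action == "pass") { stats$passed <- stats$passed + 1L; keep[i] <- TRUE }
    else if (d$action == "trim") {
      stats$trimmed <- stats$trimmed + 1L; keep[i] <- TRUE; trim[i] <- d$trim_to
    } else stats$discarded <- stats$discarded + 1L
  }
  sq <- f1$seq; ql <- f1$qual
  idx <- which(!is.na(trim))
  sq[idx] <- substring(sq[idx], 1, trim[idx])
  ql[idx] <- substring(ql[idx], 1, trim[idx])
  write_fastq(f1$id[keep], sq[keep], ql[keep], out1)
  stats
}
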