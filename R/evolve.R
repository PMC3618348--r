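# Descendant genome simulation. Every change to the parent sequence is an
# event (snp, small_indel, deletion, pseudogene_ablation) with coordinates
# on the PARENT genome; replaying the ordered log on the parent reproduces
# the child byte-for-byte, which serves as the definitional oracle for
# conservation arithmetic and feature lift-over.

#' Replay an event log on a parent sequence
#'
#' Events carry parent coordinates (0-based half-open) and are applied in
#' descending `start` order so that earlier coordinates stay valid.
#'
#' @param seq Parent sequence (character scalar).
#' @param events Event data frame with columns `kind`, `start`, `end`,
#'   `payload` (replacement base for `snp`, inserted sequence for
#'   insertions, empty otherwise).
#' @return The child sequence.
#' @export
replay_events <- function(seq, events) {
  if (is.null(events) || nrow(events) == 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  ord <- order(events$start, decreasing = TRUE)
  for (i in ord) {
    e <- events[i, ]
    if (e$kind == "snp") {
      x[e$start + 1L] <- e$payload
    } else if (e$kind %in% c("deletion", "pseudogene_ablation") ||
               (e$kind == "small_indel" && e$end > e$start)) {
      x <- x[-((e$start + 1L):e$end)]
    } else if (e$kind == "small_indel" && e$end == e$start) {
      # insertion of payload before parent position `start`
      x <- append(x, strsplit(e$payload, "", fixed = TRUE)[[1]], after = e$start)
    } else {
      stop_pk("unknown event kind '%s'", e$kind, class = "event_error")
    }
  }
  paste(x, collapse = "")
}

empty_event_log <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             payload = character(), stringsAsFactors = FALSE)
}

#' Evolve a descendant genome from an annotated parent
#'
#' Structured events (typically the large intergenic deletions and
#' pseudogene-ablating deletions that characterise plastome hot-spots) are
#' applied first, in list order; stochastic substitutions and small indels
#' are then drawn at the given per-base rates, avoiding positions removed by
#' structured deletions. Feature coordinates are lifted over through all
#' events: a deletion fully covering a feature removes it, a partial overlap
#' truncates and flags it.
#'
#' @param parent A `plastome` object.
#' @param rates List with per-base rates `sub` and `indel`, both in
#'   `[0, 0.2]`.
#' @param structured_events List of events, each a list with `kind`
#'   (`"deletion"`, `"pseudogene_ablation"` or `"snp"`), `start`, `end`
#'   (0-based half-open parent coordinates) and, for `snp`, `payload`.
#' @param seed Integer seed.
#' @return A list with `genome` (child `plastome`, regions unset), `log`
#'   (event data frame in ascending coordinate order) and `removed`
#'   (names of features deleted outright).
#' @export
evolve_genome <- function(parent, rates = list(sub = 0.01, indel = 1e-4),
                          structured_events = list(), seed = 1L) {
  stopifnot(inherits(parent, "plastome"))
  sub_rate <- if (is.null(rates$sub)) 0 else rates$sub
  indel_rate <- if (is.null(rates$indel)) 0 else rates$indel
  if (sub_rate < 0 || sub_rate > 0.2 || indel_rate < 0 || indel_rate > 0.2)
    stop_pk("rates must lie in [0, 0.2]", class = "parameter_error")
  L <- parent$length

  ev <- empty_event_log()
  for (e in structured_events) {
    kind <- e$kind
    if (!kind %in% c("deletion", "pseudogene_ablation", "snp", "small_indel"))
      stop_pk("unknown structured event kind '%s'", kind, class = "event_error")
    start <- as.integer(e$start)
    end <- as.integer(if (is.null(e$end)) start + 1L else e$end)
    if (start < 0 || end > L || (kind != "small_indel" && end <= start && kind != "snp"))
      stop_pk("structured event outside parent coordinates [0, %d)", L,
              class = "event_error")
    payload <- if (is.null(e$payload)) "" else e$payload
    ev <- rbind(ev, data.frame(kind = kind, start = start, end = end,
                               payload = payload, stringsAsFactors = FALSE))
  }
  # reject overlapping structured deletions with a conflict report
  dels <- ev[ev$kind %in% c("deletion", "pseudogene_ablation", "small_indel") &
               ev$end > ev$start, , drop = FALSE]
  if (nrow(dels) > 1) {
    o <- order(dels$start)
    s <- dels$start[o]; e2 <- dels$end[o]
    ovl <- which(s[-1] < e2[-length(e2)])
    if (length(ovl))
      stop_pk("overlapping structured deletions: [%d,%d) and [%d,%d)",
              s[ovl[1]], e2[ovl[1]], s[ovl[1] + 1L], e2[ovl[1] + 1L],
              class = "event_conflict")
  }
  in_deleted <- function(p) { # vectorised: is parent position inside any deletion?
    if (nrow(dels) == 0) return(rep(FALSE, length(p)))
    out <- rep(FALSE, length(p))
    for (i in seq_len(nrow(dels))) out <- out | (p >= dels$start[i] & p < dels$end[i])
    out
  }

  with_seed(seed, {
    # stochastic substitutions
    n_sub <- rbinom(1L, L, sub_rate)
    if (n_sub > 0) {
      pos <- sample.int(L, n_sub) - 1L
      pos <- pos[!in_deleted(pos)]
      if (length(pos)) {
        old <- strsplit(substring(parent$seq, pos + 1L, pos + 1L), "")
        old <- unlist(old)
        new <- vapply(old, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                      character(1), USE.NAMES = FALSE)
        ev <- rbind(ev, data.frame(kind = "snp", start = pos, end = pos + 1L,
                                   payload = new, stringsAsFactors = FALSE))
      }
    }
    # stochastic small indels (1-10 bp), non-overlapping
    n_ind <- rbinom(1L, L, indel_rate)
    if (n_ind > 0) {
      pos <- sort(sample.int(L, n_ind) - 1L)
      lens <- sample(1:10, n_ind, replace = TRUE)
      is_ins <- runif(n_ind) < 0.5
      keep <- !logical(n_ind)
      last_end <- -1L
      for (i in seq_len(n_ind)) {
        span_end <- if (is_ins[i]) pos[i] else pos[i] + lens[i]
        if (pos[i] <= last_end || span_end > L ||
            any(in_deleted(seq.int(pos[i], max(pos[i], span_end - 1L))))) {
          keep[i] <- FALSE
        } else last_end <- span_end
      }
      for (i in which(keep)) {
        if (is_ins[i]) {
          ev <- rbind(ev, data.frame(kind = "small_indel", start = pos[i],
                                     end = pos[i], payload = random_dna(lens[i]),
                                     stringsAsFactors = FALSE))
        } else {
          ev <- rbind(ev, data.frame(kind = "small_indel", start = pos[i],
                                     end = pos[i] + lens[i], payload = "",
                                     stringsAsFactors = FALSE))
        }
      }
    }
  })
  ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL

  child_seq <- replay_events(parent$seq, ev)
  lifted <- liftover_features(parent$features, ev)
  child <- as_plastome(child_seq, lifted$features, circular = parent$circular)
  list(genome = child, log = ev, removed = lifted$removed)
}

# Lift features through an event log (parent coordinates).
liftover_features <- function(features, events) {
  if (nrow(features) == 0)
    return(list(features = features, removed = character(0)))
  dels <- events[events$end > events$start &
                   events$kind %in% c("deletion", "pseudogene_ablation", "small_indel"), ,
                 drop = FALSE]
  ins <- events[events$kind == "small_indel" & events$end == events$start, ,
                drop = FALSE]
  ins_len <- nchar(ins$payload)
  # shift of a parent point p: insertions strictly before p add, deleted
  # bases before p subtract
  shift_point <- function(p) {
    d <- 0L
    if (nrow(dels)) d <- d - sum(pmax(0L, pmin(p, dels$end) - dels$start))
    if (nrow(ins)) d <- d + sum(ins_len[ins$start <= p])
    p + d
  }
  removed <- character(0)
  keep <- logical(nrow(features))
  out <- features
  for (i in seq_len(nrow(features))) {
    ex <- features$exons[[i]]
    trunc <- isTRUE(features$truncated[i])
    new_ex <- NULL
    for (j in seq_len(nrow(ex))) {
      s <- ex[j, 1]; e <- ex[j, 2]
      if (nrow(dels)) {
        for (k in seq_len(nrow(dels))) {
          ds <- dels$start[k]; de <- dels$end[k]
          if (de <= s || ds >= e) next
          if (ds <= s && de >= e) { s <- e <- NA_integer_; trunc <- TRUE; break }
          trunc <- TRUE
          if (ds <= s) s <- de
          else if (de >= e) e <- ds
          else { e <- ds } # internal deletion: keep 5' piece, flag truncated
        }
      }
      if (is.na(s)) next
      new_ex <- rbind(new_ex, c(shift_point(s), shift_point(e)))
    }
    if (is.null(new_ex)) {
      removed <- c(removed, features$name[i])
      keep[i] <- FALSE
      next
    }
    keep[i] <- TRUE
    out$exons[[i]] <- new_ex
    out$start[i] <- min(new_ex[, 1])
    out$end[i] <- max(new_ex[, 2])
    out$truncated[i] <- trunc
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(features = out, removed = removed)
}

#' Simulate paired-end reads from a (circular) genome
#'
#' Fragments are sampled uniformly on the circle (reads may wrap the
#' origin); mate 1 is the first `read_len` bases of the fragment and mate 2
#' the reverse complement of the last `read_len` bases. Substitution errors
#' are applied at `error_rate` per base, and PHRED qualities follow a
#' position-dependent model whose mean decays linearly 3'-ward. Contaminant
#' genomes contribute read pairs at the given fractions; every pair carries
#' a truth label naming its source.
#'
#' @param genome A `plastome` object or character sequence.
#' @param n_pairs Number of read pairs.
#' @param insert_mean,insert_sd Fragment-size model in bases (mean must be
#'   at least `read_len`).
#' @param read_len Read length in bases.
#' @param error_rate Per-base substitution error rate.
#' @param contaminants List of `list(name=, seq=, fraction=)`; fractions
#'   must sum (with the focal genome's share) to 1.
#' @param seed Integer seed.
#' @param circular Sample fragments across the origin (set `FALSE` for a
#'   linear template).
#' @param qual_model List with `q_start`, `q_end`, `sd` for the linear
#'   quality decay (discrete PHRED 2-40).
#' @return An object of class `read_set`: a data frame with `id`, `seq1`,
#'   `seq2`, `qual1`, `qual2` (PHRED+33 strings), `source`, `start`
#'   (0-based fragment start on the source), `insert` and `strand`.
#' @export
simulate_reads <- function(genome, n_pairs, insert_mean = 200L, insert_sd = 20,
                           read_len = 100L, error_rate = 0,
                           contaminants = list(), seed = 1L, circular = TRUE,
                           qual_model = list(q_start = 38, q_end = 28, sd = 3)) {
  seqs <- c(plastid = if (inherits(genome, "plastome")) genome$seq else toupper(genome))
  fracs <- c(plastid = 1)
  for (ct in contaminants) {
    nm <- ct$name
    seqs[nm] <- if (inherits(ct$seq, "plastome")) ct$seq$seq else toupper(ct$seq)
    fracs[nm] <- ct$fraction
    fracs["plastid"] <- fracs["plastid"] - ct$fraction
  }
  if (any(fracs < -1e-9) || any(fracs > 1 + 1e-9))
    stop_pk("contaminant fractions must lie in [0,1] and sum to at most 1",
            class = "parameter_error")
  if (insert_mean < read_len)
    stop_pk("insert_mean (%d) must be >= read_len (%d)", insert_mean, read_len,
            class = "parameter_error")
  with_seed(seed, {
    src <- sample(names(seqs), n_pairs, replace = TRUE, prob = pmax(fracs, 0))
    lens <- pmax(read_len, pmin(round(rnorm(n_pairs, insert_mean, insert_sd)),
                                nchar(seqs)[src] - !circular))
    Lsrc <- nchar(seqs)[src]
    start <- if (circular) floor(runif(n_pairs) * Lsrc)
             else floor(runif(n_pairs) * (Lsrc - lens + 1))
    strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
    doubled <- vapply(seqs, function(s) paste0(s, s), character(1))
    frag <- substring(doubled[src], start + 1, start + lens)
    neg <- strand == "-"
    frag[neg] <- revcomp(frag[neg])
    m1 <- substring(frag, 1, read_len)
    m2 <- revcomp(substring(frag, lens - read_len + 1, lens))
    reads <- c(m1, m2)
    if (error_rate > 0) {
      total <- 2L * n_pairs * read_len
      n_err <- rbinom(1L, total, error_rate)
      if (n_err > 0) {
        at <- sample.int(total, n_err)
        ridx <- (at - 1L) %/% read_len + 1L
        rpos <- (at - 1L) %% read_len + 1L
        old <- substring(reads[ridx], rpos, rpos)
        alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                      nrow = 4, byrow = TRUE,
                      dimnames = list(c("A", "C", "G", "T"), NULL))
        new <- alt[cbind(match(old, rownames(alt)), sample.int(3L, n_err, replace = TRUE))]
        reads <- cpp_apply_subs(reads, ridx, rpos, new)
      }
    }
    qmean <- seq(qual_model$q_start, qual_model$q_end, length.out = read_len)
    qm <- matrix(rnorm(2L * n_pairs * read_len, mean = rep(qmean, each = 2L * n_pairs),
                       sd = qual_model$sd), nrow = 2L * n_pairs)
    qm[] <- pmax(2L, pmin(40L, round(qm)))
    storage.mode(qm) <- "integer"
    qstr <- cpp_encode_phred_mat(qm, 33L)
    out <- data.frame(
      id = sprintf("read%06d", seq_len(n_pairs)),
      seq1 = reads[seq_len(n_pairs)],
      seq2 = reads[n_pairs + seq_len(n_pairs)],
      qual1 = qstr[seq_len(n_pairs)],
      qual2 = qstr[n_pairs + seq_len(n_pairs)],
      source = src,
      start = as.integer(start),
      insert = as.integer(lens),
      strand = strand,
      stringsAsFactors = FALSE)
  })
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  attr(out, "read_len") <- as.integer(read_len)
  out
}

#' Write a read set as paired FASTQ plus a truth-label sidecar
#'
#' @param reads A `read_set`.
#' @param prefix Output prefix; writes `<prefix>_1.fastq`,
#'   `<prefix>_2.fastq` and `<prefix>_truth.tsv`.
#' @export
write_read_set <- function(reads, prefix) {
  write_fastq(paste0(reads$id, "/1"), reads$seq1, reads$qual1,
              paste0(prefix, "_1.fastq"))
  write_fastq(paste0(reads$id, "/2"), reads$seq2, reads$qual2,
              paste0(prefix, "_2.fastq"))
  write_tsv_report(reads[, c("id", "source", "start", "insert", "strand")],
                   paste0(prefix, "_truth.tsv"))
  invisible(prefix)
}
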