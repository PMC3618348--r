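# Readers and writers for the standard formats used throughout the pipeline.
# FASTA goes through Biostrings; FASTQ is a fixed 4-line record format that
# we parse directly so that mate synchronisation, quality-encoding and
# truncation errors can be reported with record indices; GFF3 conversion is
# done against the internal 0-based half-open convention at this boundary
# only; Newick goes through ape.

#' Read a FASTA file
#'
#' Sequences are normalised to upper case. A `[circular]` tag in a header is
#' stripped from the name and returned in the `circular` attribute.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences with a logical `circular`
#'   attribute (one flag per record).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- names(x)
  circ <- grepl("\\[circular\\]", ids)
  ids <- trimws(sub("\\s*\\[circular\\]", "", ids))
  ids <- sub("\\s.*$", "", ids) # first token is the id
  if (anyDuplicated(ids))
    stop_pk("duplicate sequence ids in %s: %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            class = "format_error")
  out <- toupper(as.character(x))
  names(out) <- ids
  attr(out, "circular") <- circ
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param circular Logical vector; records flagged `TRUE` get a
#'   `[circular]` header tag.
#' @export
write_fasta <- function(seqs, path, circular = FALSE) {
  circular <- rep_len(circular, length(seqs))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  ids <- ifelse(circular, paste(ids, "[circular]"), ids)
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- ids
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @param quality_encoding `"phred33"` (Sanger) or `"phred64"`.
#' @return A data frame with columns `id`, `seq` and `qual` (quality kept as
#'   the encoded string; decode with [decode_quals()]).
#' @export
read_fastq <- function(path, quality_encoding = c("phred33", "phred64")) {
  quality_encoding <- match.arg(quality_encoding)
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop_pk("truncated FASTQ record %d in %s", length(lines) %/% 4 + 1, path,
            class = "format_error")
  n <- length(lines) %/% 4
  if (n == 0)
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  id <- lines[seq(1, by = 4, length.out = n)]
  seqs <- toupper(lines[seq(2, by = 4, length.out = n)])
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(id, "@"))
  if (length(bad))
    stop_pk("malformed FASTQ header at record %d", bad[1], class = "format_error")
  mism <- which(nchar(seqs) != nchar(qual))
  if (length(mism))
    stop_pk("base/quality length mismatch at record %d", mism[1],
            class = "format_error")
  id <- sub("^@", "", id)
  offset <- if (quality_encoding == "phred33") 33L else 64L
  qmin <- if (n > 0) min(utf8ToInt(paste(qual, collapse = ""))) else NA
  if (!is.na(qmin) && qmin - offset < 0)
    warning("implausible quality scores: encoding offset ", offset,
            " yields negative PHRED values; check --quality-encoding")
  out <- data.frame(id = id, seq = seqs, qual = qual, stringsAsFactors = FALSE)
  attr(out, "offset") <- offset
  out
}

#' Decode quality strings into integer PHRED scores
#'
#' @param qual Character vector of encoded quality strings.
#' @param offset Encoding offset (33 for Sanger).
#' @return List of integer vectors.
#' @export
decode_quals <- function(qual, offset = 33L) {
  cpp_decode_phred(qual, as.integer(offset))
}

#' Encode integer PHRED scores
#'
#' @param quals List of integer vectors.
#' @param offset Encoding offset.
#' @return Character vector of encoded quality strings.
#' @export
encode_quals <- function(quals, offset = 33L) {
  cpp_encode_phred(quals, as.integer(offset))
}

#' Write a FASTQ file
#'
#' @param id,seq,qual Parallel vectors: read ids, bases and *encoded*
#'   quality strings.
#' @param path Output path.
#' @export
write_fastq <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(id))
    writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), con)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Converts the 1-based inclusive GFF3 coordinates to the internal 0-based
#' half-open convention. Rows of type `gene`, `pseudogene`, `tRNA` and
#' `rRNA` become features; `exon` rows are attached to their `Parent`.
#'
#' @param path Path to a GFF3 file.
#' @param genome_length Optional; if given, features out of bounds raise an
#'   error listing the offenders.
#' @return A feature data frame (see [generate_plastome()] for the layout).
#' @export
read_gff3 <- function(path, genome_length = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(empty_features())
  f <- read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("seqid", "source", "type", "start", "end",
                                "score", "strand", "phase", "attr"))
  get_attr <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
    ifelse(lengths(regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))) > 0,
           sub(paste0("^.*", key, "="), "", m), NA_character_)
  }
  ids <- vapply(f$attr, function(a) {
    m <- regmatches(a, regexpr("(^|;)ID=[^;]*", a))
    if (length(m)) sub("^.*ID=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  parents <- vapply(f$attr, function(a) {
    m <- regmatches(a, regexpr("(^|;)Parent=[^;]*", a))
    if (length(m)) sub("^.*Parent=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  names_ <- vapply(f$attr, function(a) {
    m <- regmatches(a, regexpr("(^|;)Name=[^;]*", a))
    if (length(m)) sub("^.*Name=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  is_feat <- f$type %in% c("gene", "pseudogene", "tRNA", "rRNA", "ORF")
  feats <- f[is_feat, , drop = FALSE]
  fids <- ids[is_feat]
  kind_map <- c(gene = "protein", pseudogene = "pseudogene",
                tRNA = "tRNA", rRNA = "rRNA", ORF = "orf")
  out <- data.frame(
    name = ifelse(is.na(names_[is_feat]), fids, names_[is_feat]),
    kind = unname(kind_map[feats$type]),
    strand = feats$strand,
    start = feats$start - 1L,
    end = feats$end,
    stringsAsFactors = FALSE
  )
  exons <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    ex <- which(f$type == "exon" & parents == fids[i])
    if (length(ex)) {
      m <- cbind(f$start[ex] - 1L, f$end[ex])
      exons[[i]] <- m[order(m[, 1]), , drop = FALSE]
    } else {
      exons[[i]] <- cbind(out$start[i], out$end[i])
    }
  }
  out$exons <- exons
  if (!is.null(genome_length)) {
    bad <- which(out$start < 0 | out$end > genome_length)
    if (length(bad))
      stop_pk("features out of bounds: %s", paste(out$name[bad], collapse = ", "),
              class = "format_error")
  }
  out
}

#' Write gene features as GFF3
#'
#' @param features Feature data frame (0-based half-open internally).
#' @param path Output path.
#' @param seqid Sequence id for column 1.
#' @export
write_gff3 <- function(features, path, seqid = "genome") {
  type_map <- c(protein = "gene", pseudogene = "pseudogene",
                tRNA = "tRNA", rRNA = "rRNA", orf = "ORF")
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(features))) {
    fid <- sprintf("feat%04d", i)
    writeLines(sprintf("%s\tplastomekit\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       seqid, type_map[[features$kind[i]]],
                       features$start[i] + 1L, features$end[i],
                       features$strand[i], fid, features$name[i]), con)
    ex <- features$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\tplastomekit\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         seqid, ex[j, 1] + 1L, ex[j, 2],
                         features$strand[i], fid), con)
    }
  }
  invisible(path)
}

#' Write a tree in Newick format
#'
#' @param tree An `ape::phylo` object (node labels carry bootstrap support).
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a tab-separated report
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv_report <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

empty_features <- function() {
  data.frame(name = character(), kind = character(), strand = character(),
             start = integer(), end = integer(),
             exons = I(list()), stringsAsFactors = FALSE)
}
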