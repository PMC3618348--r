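# Internal helpers shared across modules.

# Evaluate `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Uniform random DNA string
#'
#' Draws an i.i.d. uniform A/C/G/T sequence using the current RNG stream.
#'
#' @param n Length in bases.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  if (length(x) > 50) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  } else {
    vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
  }
}

# 0-based half-open substring on a circular sequence (may wrap the origin).
substr_circular <- function(seq, start, len) {
  n <- nchar(seq)
  stopifnot(len <= n)
  s <- start %% n
  if (s + len <= n) {
    substr(seq, s + 1, s + len)
  } else {
    paste0(substr(seq, s + 1, n), substr(seq, 1, s + len - n))
  }
}

# Rotate a circular sequence so that 0-based position `origin` becomes 0.
rotate_seq <- function(seq, origin) {
  substr_circular(seq, origin, nchar(seq))
}

stop_pk <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "plastomekit_error")))
}
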