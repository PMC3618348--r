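# Maximum-parsimony phylogenomics from reference-projected whole-plastome
# alignments: build a gap-free character matrix, score trees with the Fitch
# algorithm, search tree space exhaustively or by branch-and-bound, and
# attach bootstrap supports.

#' Build a gap-free character matrix from pairwise alignments
#'
#' Each query is projected onto the columns of the common reference; any
#' reference column with a gap (or missing state) in any taxon is dropped,
#' matching the rule of excluding sites with gaps or missing data.
#'
#' @param alignments Named list of `pairwise_alignment`s sharing one
#'   reference.
#' @param ref_name Taxon name for the reference itself.
#' @return Object of class `character_matrix`: `taxa`, `mat` (character
#'   matrix taxa x columns), `ref_columns` (0-based reference coordinates
#'   of the retained columns).
#' @export
build_character_matrix <- function(alignments, ref_name = "reference") {
  if (length(alignments) < 2)
    stop_pk("need at least 3 taxa (reference + 2 queries)", class = "parameter_error")
  ref <- alignments[[1]]$ref
  ref_len <- alignments[[1]]$ref_len
  for (a in alignments) stopifnot(a$ref_len == ref_len)
  taxa <- c(ref_name, names(alignments))
  mat <- matrix(NA_character_, nrow = length(taxa), ncol = ref_len,
                dimnames = list(taxa, NULL))
  mat[1, ] <- strsplit(ref, "", fixed = TRUE)[[1]]
  for (s in seq_along(alignments)) {
    aln <- alignments[[s]]
    qch <- strsplit(aln$query, "", fixed = TRUE)[[1]]
    states <- rep(NA_character_, ref_len)
    rpos <- 0L; qpos <- 0L
    for (i in seq_len(nrow(aln$runs))) {
      op <- aln$runs$op[i]; len <- aln$runs$len[i]
      if (op %in% c("M", "X")) {
        states[(rpos + 1L):(rpos + len)] <- qch[(qpos + 1L):(qpos + len)]
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "D") {
        rpos <- rpos + len
      } else {
        qpos <- qpos + len
      }
    }
    mat[s + 1L, ] <- states
  }
  keep <- which(colSums(is.na(mat)) == 0 &
                  colSums(matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))) ==
                  nrow(mat))
  out <- list(taxa = taxa, mat = mat[, keep, drop = FALSE],
              ref_columns = keep - 1L)
  class(out) <- "character_matrix"
  out
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d gap-free columns\n",
              length(x$taxa), ncol(x$mat)))
  invisible(x)
}

# compress columns to site patterns; returns bit-coded states and weights
compress_patterns <- function(cm, drop_constant = FALSE) {
  m4 <- matrix(match(cm$mat, c("A", "C", "G", "T")) - 1L, nrow = nrow(cm$mat))
  key <- as.vector(crossprod(m4 + 1, 5^(seq_len(nrow(m4)) - 1)))
  first <- !duplicated(key)
  weights <- as.integer(table(factor(key, levels = key[first])))
  states <- matrix(bitwShiftL(1L, m4[, first, drop = FALSE]), nrow = nrow(m4))
  if (drop_constant) {
    cons <- apply(states, 2, function(col) all(col == col[1]))
    states <- states[, !cons, drop = FALSE]
    weights <- weights[!cons]
  }
  list(states = states, weights = weights, n_col = ncol(cm$mat))
}

#' Fitch parsimony score of a tree
#'
#' Minimum number of state changes the matrix requires on the given tree
#' (unordered states, unrooted trees; invariant columns contribute zero).
#'
#' @param tree An `ape::phylo` whose tip labels match the matrix taxa.
#' @param cm A `character_matrix`.
#' @return Integer score.
#' @export
parsimony_score <- function(tree, cm) {
  if (!setequal(tree$tip.label, cm$taxa))
    stop_pk("tree leaves do not match matrix taxa", class = "parameter_error")
  cp <- compress_patterns(cm)
  ord <- match(tree$tip.label, cm$taxa)
  states <- cp$states[ord, , drop = FALSE]
  tr <- stats::reorder(tree, "postorder")
  score <- cpp_fitch_score(states, cp$weights, tr$edge,
                           max(tr$edge), length(tree$tip.label) + 1L)
  as.integer(score)
}

#' Maximum-parsimony tree search
#'
#' Stepwise-addition enumeration of unrooted binary topologies, either
#' exhaustive (all (2n-5)!! trees) or with branch-and-bound pruning; all
#' equally most-parsimonious trees are returned.
#'
#' @param cm A `character_matrix`.
#' @param strategy `"branch_and_bound"` or `"exhaustive"`.
#' @param max_trees Cap on stored co-optimal trees.
#' @return List with `trees` (`ape::multiPhylo`), `score`, `splits` (one
#'   integer bip-mask vector per tree) and `n_topologies` (topologies
#'   scored; for the exhaustive strategy this is the full count).
#' @export
search_mp <- function(cm, strategy = c("branch_and_bound", "exhaustive"),
                      max_trees = 1000L) {
  strategy <- match.arg(strategy)
  n <- length(cm$taxa)
  if (n < 4) stop_pk("need at least 4 taxa", class = "strategy_error")
  if (strategy == "exhaustive" && n > 12)
    stop_pk("exhaustive search is limited to 12 taxa", class = "strategy_error")
  if (n > 20)
    stop_pk("branch-and-bound search is limited to 20 taxa", class = "strategy_error")
  cp <- compress_patterns(cm, drop_constant = TRUE)
  res <- cpp_mp_search(cp$states, cp$weights, strategy == "exhaustive",
                       as.integer(max_trees), Inf)
  trees <- lapply(res$trees, function(nw) {
    tr <- ape::read.tree(text = nw)
    tr$tip.label <- cm$taxa[as.integer(tr$tip.label) + 1L]
    tr
  })
  class(trees) <- "multiPhylo"
  list(trees = trees, score = as.integer(res$score), splits = res$splits,
       n_topologies = res$n_scored)
}

#' Bootstrap supports for the maximum-parsimony tree
#'
#' Columns are resampled with replacement (per replicate) and the search is
#' repeated; the support of an internal edge is the percentage of
#' replicates whose optimal trees all contain that bipartition. Replicate
#' draws come from a single seeded generator, so results are reproducible.
#'
#' @param cm A `character_matrix`.
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param strategy Search strategy per replicate.
#' @return List with `tree` (a most-parsimonious tree with node labels set
#'   to supports), `supports` (data frame: bipartition mask, member taxa,
#'   support), `score`, `trees` (all co-optimal trees on the original
#'   matrix).
#' @export
bootstrap_mp <- function(cm, replicates = 1000L, seed = 1L,
                         strategy = "branch_and_bound") {
  main <- search_mp(cm, strategy)
  cp <- compress_patterns(cm, drop_constant = FALSE)
  counts <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      w <- as.integer(rmultinom(1L, cp$n_col, cp$weights / sum(cp$weights))[, 1])
      sel <- w > 0L
      # constant patterns never change scores; drop for speed
      st <- cp$states[, sel, drop = FALSE]
      ww <- w[sel]
      cons <- apply(st, 2, function(col) all(col == col[1]))
      res <- cpp_mp_search(st[, !cons, drop = FALSE], ww[!cons],
                           FALSE, 64L, Inf)
      splits <- Reduce(intersect, res$splits)
      for (m in splits) {
        key <- as.character(m)
        counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      }
    }
  })
  support_of <- function(mask) {
    key <- as.character(mask)
    cnt <- counts[[key]]
    if (is.null(cnt)) 0 else 100 * cnt / replicates
  }
  best <- main$trees[[1]]
  masks <- main$splits[[1]]
  supports <- vapply(masks, support_of, numeric(1))
  sup_df <- data.frame(
    mask = unlist(masks),
    taxa = vapply(masks, function(m) paste(cm$taxa[mask_bits(m, length(cm$taxa))],
                                           collapse = ","), character(1)),
    support = supports, stringsAsFactors = FALSE)
  best <- annotate_supports(best, cm$taxa, sup_df)
  list(tree = best, supports = sup_df, score = main$score, trees = main$trees,
       replicates = replicates)
}

mask_bits <- function(mask, n) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0)
}

# canonical bipartition mask of the tips below each internal node
phylo_splits <- function(tree, taxa) {
  n <- length(tree$tip.label)
  tipbit <- bitwShiftL(1L, match(tree$tip.label, taxa) - 1L)
  nnode <- tree$Nnode
  masks <- integer(n + nnode)
  tr <- stats::reorder(tree, "postorder")
  masks[seq_len(n)] <- tipbit
  for (e in seq_len(nrow(tr$edge))) {
    pa <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    masks[pa] <- bitwOr(masks[pa], masks[ch])
  }
  full <- bitwShiftL(1L, length(taxa)) - 1L
  canon <- function(m) if (bitwAnd(m, 1L) == 1L) bitwAnd(bitwNot(m), full) else m
  root <- n + 1L
  internal <- setdiff((n + 1L):(n + nnode), root)
  list(nodes = internal, masks = vapply(masks[internal], canon, integer(1)))
}

annotate_supports <- function(tree, taxa, sup_df) {
  sp <- phylo_splits(tree, taxa)
  labs <- rep("", tree$Nnode)
  for (i in seq_along(sp$nodes)) {
    hit <- match(sp$masks[i], sup_df$mask)
    if (!is.na(hit))
      labs[sp$nodes[i] - length(tree$tip.label)] <-
        sprintf("%.0f", sup_df$support[hit])
  }
  tree$node.label <- labs
  tree
}
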