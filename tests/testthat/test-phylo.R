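test_that("character matrix: identical taxa keep every column", {
  g <- mini_plastome(seed = 71)
  alns <- list(a = align_pair(g$seq, g$seq), b = align_pair(g$seq, g$seq),
               c = align_pair(g$seq, g$seq))
  cm <- build_character_matrix(alns, ref_name = "ref")
  expect_equal(ncol(cm$mat), g$length)
  expect_true(all(cm$mat == cm$mat[rep(1, 4), ]))
})

test_that("a planted deletion drops exactly its columns", {
  g <- mini_plastome(seed = 72)
  del <- list(kind = "deletion", start = 3000L, end = 3100L)
  child <- evolve_genome(g, rates = list(sub = 0, indel = 0),
                         structured_events = list(del), seed = 1)$genome
  alns <- list(a = align_pair(g$seq, child$seq), b = align_pair(g$seq, g$seq))
  cm <- build_character_matrix(alns)
  expect_equal(ncol(cm$mat), g$length - 100L)
  dropped <- setdiff(0:(g$length - 1), cm$ref_columns)
  ns <- normalize_deletion_left(g$seq, 3000L, 100L)
  expect_equal(sort(dropped), ns:(ns + 99L))
})

test_that("matrix projection agrees with a column-by-column oracle", {
  set.seed(70)
  ref <- random_dna(300)
  q1 <- paste0(substr(ref, 1, 100), substr(ref, 121, 300))  # 20-base deletion
  q2 <- ref                                                 # sparse substitutions
  for (p in seq(10, 290, by = 40)) {
    substr(q2, p, p) <- setdiff(c("A", "C", "G", "T"), substr(ref, p, p))[1]
  }
  alns <- list(q1 = align_pair(ref, q1, k = 11), q2 = align_pair(ref, q2, k = 11))
  cm <- build_character_matrix(alns)
  expect_equal(nrow(cm$mat), 3L)
  expect_equal(ncol(cm$mat), 280L)
  rch <- strsplit(ref, "")[[1]]
  expect_equal(unname(cm$mat["reference", ]), rch[cm$ref_columns + 1])
  # naive projection oracle for the substitution-only taxon: reference
  # column i simply carries the query base at the same position
  q2ch <- strsplit(q2, "")[[1]]
  expect_equal(unname(cm$mat["q2", ]), q2ch[cm$ref_columns + 1])
})

test_that("Fitch score: worked 4-taxon example and brute-force oracle", {
  mk_cm <- function(mat) {
    structure(list(taxa = rownames(mat), mat = mat,
                   ref_columns = seq_len(ncol(mat)) - 1L),
              class = "character_matrix")
  }
  m <- matrix(c("A", "A", "C", "C"), ncol = 1,
              dimnames = list(c("A1", "A2", "B1", "B2"), NULL))
  t_ab <- ape::read.tree(text = "((A1,A2),(B1,B2));")
  t_ax <- ape::read.tree(text = "((A1,B1),(A2,B2));")
  expect_equal(parsimony_score(t_ab, mk_cm(m)), 1L)
  expect_equal(parsimony_score(t_ax, mk_cm(m)), 2L)
  # invariant columns contribute zero
  m0 <- matrix("G", nrow = 4, ncol = 7, dimnames = dimnames(m[, rep(1, 7)]))
  expect_equal(parsimony_score(t_ab, mk_cm(m0)), 0L)
  # random 6-taxon matrices vs exhaustive assignment enumeration
  set.seed(73)
  for (rep in 1:5) {
    mat <- matrix(sample(c("A", "C", "G", "T"), 6 * 12, replace = TRUE),
                  nrow = 6, dimnames = list(paste0("t", 1:6), NULL))
    tree <- ape::rtree(6, rooted = FALSE, tip.label = paste0("t", 1:6))
    expect_equal(parsimony_score(tree, mk_cm(mat)), fitch_oracle(tree, mat))
  }
  # score is invariant under taxon relabelling / column permutation
  mat <- matrix(sample(c("A", "C", "G", "T"), 6 * 30, replace = TRUE),
                nrow = 6, dimnames = list(paste0("t", 1:6), NULL))
  tree <- ape::rtree(6, rooted = FALSE, tip.label = paste0("t", 1:6))
  s1 <- parsimony_score(tree, mk_cm(mat))
  expect_equal(parsimony_score(tree, mk_cm(mat[, sample(30)])), s1)
  perm <- sample(6)
  mat2 <- mat[perm, , drop = FALSE]
  expect_equal(parsimony_score(tree, mk_cm(mat2)), s1)
})

test_that("exhaustive search enumerates all topologies; 5 taxa -> 15", {
  set.seed(74)
  mat <- matrix(sample(c("A", "C", "G", "T"), 5 * 40, replace = TRUE),
                nrow = 5, dimnames = list(paste0("t", 1:5), NULL))
  cm <- structure(list(taxa = rownames(mat), mat = mat,
                       ref_columns = seq_len(40) - 1L),
                  class = "character_matrix")
  res <- search_mp(cm, "exhaustive")
  expect_equal(res$n_topologies, 15)
  expect_error(search_mp(cm, "exhaustive", max_trees = 1)$score, NA)
})

test_that("branch-and-bound equals exhaustive search on 7 taxa", {
  set.seed(75)
  for (rep in 1:3) {
    mat <- matrix(sample(c("A", "C", "G", "T"), 7 * 60, replace = TRUE),
                  nrow = 7, dimnames = list(paste0("t", 1:7), NULL))
    cm <- structure(list(taxa = rownames(mat), mat = mat,
                         ref_columns = seq_len(60) - 1L),
                    class = "character_matrix")
    ex <- search_mp(cm, "exhaustive")
    bb <- search_mp(cm, "branch_and_bound")
    expect_equal(bb$score, ex$score)
    expect_setequal(vapply(bb$splits, function(s) paste(sort(s), collapse = ","),
                           character(1)),
                    vapply(ex$splits, function(s) paste(sort(s), collapse = ","),
                           character(1)))
    # n_topologies counts score() calls; branch-and-bound also scores
    # partial trees, so only positivity is meaningful here
    expect_gt(bb$n_topologies, 0)
  }
})

test_that("the MP tree of a synthetic clade recovers the generating topology", {
  anc <- mini_plastome(seed = 76)
  br <- function(parent, seed, rate = 0.004)
    evolve_genome(parent, rates = list(sub = rate, indel = 0), seed = seed)$genome
  nAB <- br(anc, 10); A <- br(nAB, 11); B <- br(nAB, 12)
  nCD <- br(anc, 13); C <- br(nCD, 14); D <- br(nCD, 15)
  alns <- lapply(list(B = B, C = C, D = D), function(x) align_pair(A$seq, x$seq))
  cm <- build_character_matrix(alns, ref_name = "A")
  res <- search_mp(cm, "exhaustive")
  expect_equal(length(res$trees), 1L)
  truth <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(res$trees[[1]]),
                                         ape::unroot(truth))), 0)
})

test_that("bootstrap: certain splits score 100, seeds reproduce, stability", {
  # a strongly supported split (t1,t2 | rest) backed by 50 synapomorphic
  # columns, plus compatible resolving patterns for the remaining edges
  mat <- cbind(matrix(rep(c("A", "A", "C", "C", "C", "C"), 50), nrow = 6),
               matrix(rep(c("A", "A", "A", "C", "C", "C"), 20), nrow = 6),
               matrix(rep(c("A", "A", "A", "A", "C", "C"), 20), nrow = 6))
  rownames(mat) <- paste0("t", 1:6)
  cm <- structure(list(taxa = rownames(mat), mat = mat,
                       ref_columns = seq_len(ncol(mat)) - 1L),
                  class = "character_matrix")
  bs <- bootstrap_mp(cm, replicates = 50, seed = 3)
  strong <- bs$supports[bs$supports$taxa == "t3,t4,t5,t6", ] # = {t1,t2}
  expect_equal(strong$support, 100)
  bs2 <- bootstrap_mp(cm, replicates = 50, seed = 3)
  expect_equal(bs$supports, bs2$supports)
  expect_true(all(bs$supports$support >= 0 & bs$supports$support <= 100))
})
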