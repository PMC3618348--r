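test_that("panel index construction and membership", {
  set.seed(10)
  ref <- random_dna(100)
  idx <- build_panel_index(c(a = ref), c(a = "plastid"), k = 21)
  # a 100-bp reference has exactly 80 k-mer positions
  expect_equal(idx$refs$length, 100L)
  kmers <- substring(ref, 1:80, 21:100)
  expect_true(all(panel_has_kmer(idx, kmers)))
  # canonicalisation: the reverse complement indexes to the same keys
  idx_rc <- build_panel_index(c(a = revcomp(ref)), c(a = "plastid"), k = 21)
  expect_true(all(panel_has_kmer(idx_rc, kmers)))
  expect_error(build_panel_index(c(a = ref, a = ref),
                                 c(a = "plastid"), k = 21),
               class = "parameter_error")
  expect_error(build_panel_index(c(a = ref), c(a = "plastid"), k = 20),
               class = "parameter_error")
})

test_that("sampled k-mer membership agrees with a naive scan oracle", {
  set.seed(11)
  refs <- c(a = random_dna(400), b = random_dna(300), c = random_dna(500))
  idx <- build_panel_index(refs, c(a = "plastid", b = "bacterial", c = "bacterial"),
                           k = 15)
  for (i in 1:1000) {
    if (i %% 3 == 0) {
      km <- random_dna(15)
    } else {
      r <- refs[[sample(3, 1)]]
      s <- sample(nchar(r) - 14, 1)
      km <- substr(r, s, s + 14)
      if (i %% 2 == 0) km <- revcomp(km)
    }
    expect_equal(panel_has_kmer(idx, km), kmer_in_panel_oracle(km, refs),
                 info = km)
  }
})

test_that("error-free reads from a panel genome are fully assigned to it", {
  set.seed(12)
  g <- mini_plastome(seed = 4)
  bact <- random_dna(15000)
  idx <- build_panel_index(c(cp = g$seq, bac = bact),
                           c(cp = "plastid", bac = "bacterial"),
                           circular = TRUE)
  reads <- simulate_reads(g, 500, seed = 2)
  rep <- classify_reads(reads, idx)
  expect_equal(unname(rep$counts[["plastid"]]), 1000L)
  expect_equal(unname(rep$counts[["unassigned"]]), 0L)
  expect_equal(sum(rep$counts), rep$n)
  expect_equal(sum(rep$proportions), 1, tolerance = 1e-9)
})

test_that("mixture proportions are recovered within 3 binomial SD", {
  set.seed(13)
  g <- mini_plastome(seed = 4)
  b1 <- random_dna(20000); b2 <- random_dna(15000); foreign <- random_dna(20000)
  n_pairs <- 3000
  reads <- simulate_reads(g, n_pairs, contaminants = list(
    list(name = "b1", seq = b1, fraction = 0.2),
    list(name = "b2", seq = b2, fraction = 0.1),
    list(name = "foreign", seq = foreign, fraction = 0.1)), seed = 3)
  idx <- build_panel_index(c(cp = g$seq, b1 = b1, b2 = b2),
                           c(cp = "plastid", b1 = "bacterial", b2 = "bacterial"),
                           circular = TRUE)
  rep <- classify_reads(reads, idx)
  n <- rep$n
  truth <- c(plastid = mean(reads$source == "plastid"),
             bacterial = mean(reads$source %in% c("b1", "b2")))
  for (cat in names(truth)) {
    sd3 <- 3 * sqrt(truth[[cat]] * (1 - truth[[cat]]) / n)
    expect_lt(abs(rep$proportions[[cat]] - truth[[cat]]), sd3 + 1e-3)
  }
})

test_that("classification is invariant to read order and ties are deterministic", {
  set.seed(14)
  shared <- random_dna(300)
  refA <- paste0(shared, random_dna(200))
  refB <- paste0(shared, random_dna(200))
  idx <- build_panel_index(c(zeb = refA, ant = refB),
                           c(zeb = "bacterial", ant = "bacterial"))
  read <- substr(shared, 10, 109) # equal k-mer support for both references
  r1 <- plastomekit:::assign_reads(read, idx, 0.5, 5L)
  r2 <- plastomekit:::assign_reads(read, idx, 0.5, 5L)
  expect_equal(r1$ref, r2$ref)
  # lexical tie-break within the same category: "ant" wins
  expect_equal(idx$refs$id[r1$ref], "ant")
  # permutation invariance of the aggregate report
  reads <- vapply(1:200, function(i) {
    r <- if (i %% 2) refA else refB
    s <- sample(nchar(r) - 99, 1)
    substr(r, s, s + 99)
  }, character(1))
  repA <- classify_reads(reads, idx)
  repB <- classify_reads(rev(reads), idx)
  expect_equal(repA$counts, repB$counts)
})

test_that("leaf vs root template scenario reproduces the expected ordering", {
  set.seed(15)
  g <- mini_plastome(seed = 4)
  bact <- random_dna(25000)
  idx <- build_panel_index(c(cp = g$seq, soil = bact),
                           c(cp = "plastid", soil = "bacterial"),
                           circular = TRUE)
  leaf <- simulate_reads(g, 1500, contaminants = list(
    list(name = "soil", seq = bact, fraction = 0.05)), seed = 5)
  root <- simulate_reads(g, 1500, contaminants = list(
    list(name = "soil", seq = bact, fraction = 0.55)), seed = 6)
  rep_leaf <- classify_reads(leaf, idx)
  rep_root <- classify_reads(root, idx)
  expect_gt(rep_leaf$proportions[["plastid"]], rep_root$proportions[["plastid"]])
  expect_gt(rep_root$proportions[["bacterial"]], rep_leaf$proportions[["bacterial"]])
})

test_that("subsampling is seeded and bounded", {
  set.seed(16)
  g <- mini_plastome(seed = 4)
  reads <- simulate_reads(g, 600, seed = 2)
  idx <- build_panel_index(c(cp = g$seq), c(cp = "plastid"))
  r1 <- classify_reads(reads, idx, subsample = 200, seed = 7)
  r2 <- classify_reads(reads, idx, subsample = 200, seed = 7)
  expect_equal(r1$counts, r2$counts)
  expect_equal(r1$n, 200L)
})
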