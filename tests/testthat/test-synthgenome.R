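test_that("plastome geometry, placement and determinism", {
  g <- mini_plastome(seed = 5)
  expect_equal(g$length, 8000 + 2400 + 2 * 1500)
  inv <- mini_inventory()
  expect_equal(nrow(g$features), nrow(inv) + sum(inv$region == "IR")) # IR x2
  # IRa is the exact reverse complement of IRb (string-compare oracle)
  irb <- substr(g$seq, g$regions$irb[["start"]] + 1,
                g$regions$irb[["start"]] + g$regions$irb[["len"]])
  ira <- substr(g$seq, g$regions$ira[["start"]] + 1,
                g$regions$ira[["start"]] + g$regions$ira[["len"]])
  expect_identical(ira, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(irb))))
  # every placed feature spells its declared length
  f <- g$features
  expect_true(all(f$end - f$start >= 1))
  # same (spec, seed) -> identical bytes out
  expect_identical(g$seq, mini_plastome(seed = 5)$seq)
  expect_false(identical(g$seq, mini_plastome(seed = 6)$seq))
})

test_that("default inventory reproduces the published-scale genome", {
  g <- generate_plastome(plastome_spec(seed = 2))
  expect_equal(g$length, 135282)
  expect_equal(g$regions$lsc[["len"]], 79972)
  expect_equal(g$regions$ssc[["len"]], 12428)
  expect_equal(g$regions$irb[["len"]], 21441)
})

test_that("empty inventory gives featureless genome of correct length", {
  spec <- plastome_spec(5000, 1500, 1200,
                        gene_inventory = default_gene_inventory()[0, ], seed = 1)
  g <- generate_plastome(spec)
  expect_equal(g$length, 5000 + 1500 + 2400)
  expect_equal(nrow(g$features), 0L)
})

test_that("unpackable inventory raises a packing error naming the region", {
  inv <- mini_inventory()
  spec <- plastome_spec(2000, 1500, 1200, gene_inventory = inv, seed = 1)
  expect_error(generate_plastome(spec), "LSC", class = "packing_error")
})

test_that("spec invariants are enforced", {
  expect_error(plastome_spec(ir_len = 999), class = "spec_error")
  expect_error(plastome_spec(lsc_len = 1000, ssc_len = 2000), class = "spec_error")
})

test_that("evolution replay reproduces the child byte-for-byte", {
  g <- mini_plastome(seed = 11)
  for (seed in 1:4) {
    ev <- evolve_genome(g, rates = list(sub = 0.01, indel = 5e-4), seed = seed)
    expect_identical(replay_events(g$seq, ev$log), ev$genome$seq)
    dels <- ev$log[ev$log$end > ev$log$start &
                     ev$log$kind %in% c("deletion", "small_indel",
                                        "pseudogene_ablation"), ]
    ins <- ev$log[ev$log$kind == "small_indel" & ev$log$end == ev$log$start, ]
    expect_equal(ev$genome$length,
                 g$length - sum(dels$end - dels$start) + sum(nchar(ins$payload)))
  }
})

test_that("empty event list and zero rates give an identical child", {
  g <- mini_plastome(seed = 3)
  ev <- evolve_genome(g, rates = list(sub = 0, indel = 0), seed = 1)
  expect_identical(ev$genome$seq, g$seq)
  expect_equal(nrow(ev$log), 0L)
})

test_that("a deletion covering a feature removes it; partial overlap truncates", {
  g <- mini_plastome(seed = 7)
  accd <- g$features[g$features$name == "accD", ]
  del <- list(kind = "pseudogene_ablation",
              start = accd$start - 8L, end = accd$start + 309L)
  ev <- evolve_genome(g, rates = list(sub = 0, indel = 0),
                      structured_events = list(del), seed = 1)
  expect_true("accD" %in% ev$removed)
  expect_false("accD" %in% ev$genome$features$name)
  expect_equal(ev$genome$length, g$length - 317L)
  # partial overlap
  rbcl <- g$features[g$features$name == "rbcL", ]
  del2 <- list(kind = "deletion", start = rbcl$end - 30L, end = rbcl$end + 30L)
  ev2 <- evolve_genome(g, rates = list(sub = 0, indel = 0),
                       structured_events = list(del2), seed = 1)
  child_rbcl <- ev2$genome$features[ev2$genome$features$name == "rbcL", ]
  expect_true(child_rbcl$truncated)
  expect_equal(child_rbcl$end - child_rbcl$start, rbcl$end - rbcl$start - 30L)
})

test_that("overlapping structured deletions are rejected with a conflict", {
  g <- mini_plastome(seed = 7)
  evs <- list(list(kind = "deletion", start = 100L, end = 300L),
              list(kind = "deletion", start = 250L, end = 400L))
  expect_error(evolve_genome(g, structured_events = evs, seed = 1),
               class = "event_conflict")
})

test_that("structured events outside parent coordinates are rejected", {
  g <- mini_plastome(seed = 7)
  expect_error(evolve_genome(g, structured_events = list(
    list(kind = "deletion", start = g$length - 10L, end = g$length + 10L)),
    seed = 1), class = "event_error")
  expect_error(evolve_genome(g, rates = list(sub = 0.5, indel = 0), seed = 1),
               class = "parameter_error")
})

test_that("error-free reads are exact substrings of the doubled circle", {
  g <- mini_plastome(seed = 9)
  reads <- simulate_reads(g, 300, seed = 4)
  doubled <- paste0(g$seq, g$seq)
  for (i in sample.int(nrow(reads), 50)) {
    frag <- substr(doubled, reads$start[i] + 1, reads$start[i] + reads$insert[i])
    if (reads$strand[i] == "-") frag <- revcomp(frag)
    expect_identical(reads$seq1[i], substr(frag, 1, 100))
    expect_identical(reads$seq2[i],
                     revcomp(substr(frag, reads$insert[i] - 99, reads$insert[i])))
  }
})

test_that("empirical substitution error rate matches the model", {
  g <- mini_plastome(seed = 9)
  n_pairs <- 10000
  reads <- simulate_reads(g, n_pairs, error_rate = 0.01, seed = 5)
  clean <- simulate_reads(g, n_pairs, error_rate = 0, seed = 5)
  mism <- sum(mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                     c(reads$seq1, reads$seq2), c(clean$seq1, clean$seq2)))
  total <- 2 * n_pairs * 100
  p_hat <- mism / total
  sd3 <- 3 * sqrt(0.01 * 0.99 / total)
  expect_lt(abs(p_hat - 0.01), sd3)
})

test_that("contaminant fractions are respected and labelled", {
  g <- mini_plastome(seed = 9)
  set.seed(1)
  bact <- random_dna(20000)
  reads <- simulate_reads(g, 5000, contaminants = list(
    list(name = "soil_bact", seq = bact, fraction = 0.3)), seed = 6)
  frac <- mean(reads$source == "soil_bact")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
})

test_that("read simulation parameter errors and determinism", {
  g <- mini_plastome(seed = 9)
  expect_error(simulate_reads(g, 10, insert_mean = 50, read_len = 100),
               class = "parameter_error")
  r1 <- simulate_reads(g, 100, error_rate = 0.02, seed = 3)
  r2 <- simulate_reads(g, 100, error_rate = 0.02, seed = 3)
  expect_identical(r1, r2)
})
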