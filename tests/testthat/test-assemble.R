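test_that("de Bruijn assembly reconstructs simple inputs", {
  # a single read -> one contig equal to that read (up to strand)
  r <- "ACGTACGGTTACGATTACCGGATCGATCGTTAGGCA"
  ctg <- debruijn_assemble(r, k = 15)
  expect_equal(nrow(ctg), 1L)
  expect_true(ctg$seq == r || ctg$seq == revcomp(r))
  # error-free 50x tiling reads over a 10-kb non-repetitive sequence
  set.seed(20)
  src <- random_dna(10000)
  starts <- seq(1, 9901, by = 2)
  reads <- substring(src, starts, starts + 99)
  ctg <- debruijn_assemble(reads, k = 31)
  expect_equal(nrow(ctg), 1L)
  expect_true(ctg$seq == src || ctg$seq == revcomp(src))
  # no reads -> empty result
  expect_equal(nrow(debruijn_assemble(character(0), k = 31)), 0L)
})

test_that("an exact long repeat breaks the assembly at its boundaries", {
  set.seed(21)
  rep2k <- random_dna(2000)
  src <- paste0(random_dna(3000), rep2k, random_dna(2500), rep2k, random_dna(2800))
  reads <- simulate_reads(src, 4000, seed = 3, circular = FALSE)
  ctg <- debruijn_assemble(reads, k = 31)
  expect_gte(nrow(ctg), 3L)
  # the repeat collapses to one unitig whose sequence contains it
  expect_true(any(vapply(ctg$seq, function(s)
    grepl(rep2k, s, fixed = TRUE) || grepl(revcomp(rep2k), s, fixed = TRUE),
    logical(1))))
})

test_that("k selection minimises distance to the target length", {
  adds <- c(`51` = 140000, `71` = 135300, `91` = 120000)
  expect_equal(select_assembly(adds, 135282), 71L)
  expect_equal(select_assembly(c(`31` = 10000), 135282), 31L)
  # equidistant candidates go to the larger k, reproducibly
  for (i in 1:5)
    expect_equal(select_assembly(c(`41` = 99000, `61` = 101000), 1e5), 61L)
  expect_error(select_assembly(numeric(0), 1), class = "parameter_error")
})

test_that("contig merging honours the 97% / 50 bp contract", {
  set.seed(22)
  a <- random_dna(400)
  b <- paste0(substr(a, 341, 400), random_dna(300)) # perfect 60-bp overlap
  m <- merge_contigs(c(a, b))
  expect_equal(length(m$contigs), 1L)
  expect_equal(nchar(m$contigs), 400 + 360 - 60)
  expect_equal(m$overlaps, 60L)
  # a 49-bp overlap at 100% identity is refused
  b49 <- paste0(substr(a, 352, 400), random_dna(300))
  m49 <- merge_contigs(c(a, b49))
  expect_equal(length(m49$contigs), 2L)
  # random fragmentation reassembles to the source
  src <- random_dna(3000)
  cuts <- sort(sample(200:2800, 19))
  starts <- c(1, pmax(1, cuts - 80))
  ends <- c(cuts + 80, 3000)
  pieces <- substring(src, starts, ends)
  flip <- seq_along(pieces) %% 2 == 0
  pieces[flip] <- revcomp(pieces[flip])
  mm <- merge_contigs(sample(pieces))
  expect_equal(length(mm$contigs), 1L)
  expect_true(mm$contigs == src || mm$contigs == revcomp(src))
  # additive length conservation
  expect_equal(nchar(mm$contigs), sum(nchar(pieces)) - sum(mm$overlaps))
})

test_that("read recruitment: recall and contaminant rejection", {
  g <- mini_plastome(seed = 30)
  reads <- simulate_reads(g, 800, seed = 4)
  rec <- recruit_reads(reads, c(self = g$seq))
  expect_true(all(rec$recruited)) # error-free same-species reads: 100% recall
  # reads from a ~2%-diverged relative are still recruited
  rel <- evolve_genome(g, rates = list(sub = 0.02, indel = 1e-4), seed = 5)$genome
  reads_rel <- simulate_reads(rel, 1000, seed = 6)
  rec_rel <- recruit_reads(reads_rel, c(anc = g$seq))
  expect_gte(mean(rec_rel$recruited), 0.95)
  # bacterial reads recruited at most 0.1%
  set.seed(23)
  bact <- random_dna(30000)
  reads_b <- simulate_reads(bact, 1000, seed = 7)
  rec_b <- recruit_reads(reads_b, c(anc = g$seq))
  expect_lte(mean(rec_b$recruited), 0.001)
})

test_that("mini end-to-end: sweep, merge and IR resolution recover the circle", {
  g <- mini_plastome(seed = 31)
  reads <- simulate_reads(g, round(60 * g$length / 200), seed = 8)
  res <- assemble_plastome(reads, c(self = g$seq), ks = c(41L, 51L),
                           target_length = g$length)
  expect_equal(res$ir_report$status, "resolved")
  expect_true(plastome_equivalent(res$genome, g))
  expect_equal(res$genome$length, g$length)
})

test_that("resolve_ir handles generator scaffolds and degenerate cases", {
  g <- mini_plastome(seed = 32)
  ira0 <- g$regions$ira[["start"]]; irlen <- g$regions$ira[["len"]]
  ira <- substr(g$seq, ira0 + 1, ira0 + irlen)
  core <- substr(g$seq, 1, ira0) # LSC + IRb + SSC
  scaffold <- paste0(substr(ira, irlen - 59, irlen), core, substr(ira, 1, 60))
  out <- resolve_ir(scaffold)
  expect_equal(out$report$status, "resolved")
  expect_true(plastome_equivalent(out$genome, g))
  # already-circular input is a no-op with a warning
  expect_warning(out2 <- resolve_ir(g), "unchanged")
  expect_identical(out2$genome$seq, g$seq)
  # truncated fold-back at one end is flagged asymmetric
  trunc <- paste0(substr(ira, irlen - 59, irlen), core)
  out3 <- resolve_ir(trunc)
  expect_equal(out3$report$status, "asymmetric")
  expect_false(isTRUE(out3$report$suffix_anchor))
  expect_null(out3$genome)
})

test_that("gaps from divergent references close via a closer relative", {
  g <- mini_plastome(seed = 33)
  # reference with a 600-bp region replaced: reads from there are unrecruited
  set.seed(24)
  hole_start <- 4000L
  ref_holed <- paste0(substr(g$seq, 1, hole_start),
                      random_dna(600),
                      substr(g$seq, hole_start + 601, g$length))
  reads <- simulate_reads(g, round(60 * g$length / 200), seed = 9)
  res1 <- assemble_plastome(reads, c(holed = ref_holed), ks = c(41L, 51L),
                            target_length = g$length,
                            relatives = c(close = g$seq))
  expect_true(plastome_equivalent(res1$genome, g))
  expect_equal(res1$ir_report$status, "resolved")
  # without support the gap persists and is reported with its flanks
  reads_gone <- reads[!(reads$start > hole_start - 250 &
                          reads$start < hole_start + 600), , drop = FALSE]
  res2 <- assemble_plastome(reads_gone, c(holed = ref_holed), ks = c(41L, 51L),
                            target_length = g$length)
  expect_gt(length(res2$assembly$contigs), 1L)
  expect_gt(nrow(res2$assembly$gap_report), 0L)
})
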