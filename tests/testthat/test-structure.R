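test_that("the planted IR is detected at its exact coordinates", {
  g <- mini_plastome(seed = 40)
  ir <- detect_inverted_repeat(g)
  expect_equal(ir$start1, unname(g$regions$irb[["start"]]))
  expect_equal(ir$start2, unname(g$regions$ira[["start"]]))
  expect_equal(ir$len, unname(g$regions$irb[["len"]]))
  # strand invariance: detection on the reverse complement mirrors coordinates
  ir_rc <- detect_inverted_repeat(revcomp(g$seq))
  expect_equal(ir_rc$len, ir$len)
  n <- g$length
  expect_setequal(c(ir_rc$start1, ir_rc$start2) %% n,
                  c((n - (ir$start1 + ir$len)) %% n,
                    (n - (ir$start2 + ir$len)) %% n))
})

test_that("a random sequence has no kilobase inverted repeat", {
  set.seed(41)
  expect_error(detect_inverted_repeat(random_dna(50000), min_len = 1000),
               class = "no_ir_error")
  expect_error(detect_inverted_repeat(random_dna(1500), min_len = 1000),
               class = "parameter_error")
})

test_that("quadripartite partition: sizes, rotation invariance, arithmetic", {
  g <- mini_plastome(seed = 42)
  q <- partition_quadripartite(g)
  expect_equal(q$sizes[["lsc"]], 8000)
  expect_equal(q$sizes[["ssc"]], 2400)
  expect_equal(q$sizes[["ir"]], 1500)
  expect_equal(q$sizes[["lsc"]] + q$sizes[["ssc"]] + 2 * q$sizes[["ir"]],
               q$sizes[["total"]])
  # arbitrary rotation yields the same partition sizes
  for (off in c(3000L, 9000L, 12000L)) {
    qr <- partition_quadripartite(plastomekit:::rotate_seq(g$seq, off))
    expect_equal(qr$sizes, q$sizes)
  }
})

test_that("partition arithmetic holds across many random geometries", {
  set.seed(43)
  empty <- default_gene_inventory()[0, ]
  for (i in 1:25) {
    lsc <- sample(3000:6000, 1)
    ssc <- sample(800:2000, 1)
    ir <- sample(1000:1600, 1)
    g <- generate_plastome(plastome_spec(lsc, ssc, ir, gene_inventory = empty,
                                         seed = i))
    q <- partition_quadripartite(g)
    expect_equal(q$sizes[["lsc"]] + q$sizes[["ssc"]] + 2 * q$sizes[["ir"]],
                 lsc + ssc + 2 * ir)
    expect_equal(q$sizes[["lsc"]], lsc)
  }
})

test_that("detect -> partition -> reassemble reproduces the input circle", {
  g <- mini_plastome(seed = 44)
  q <- partition_quadripartite(g)
  seg <- function(iv) plastomekit:::substr_circular(g$seq, iv[["start"]], iv[["len"]])
  rebuilt <- paste0(seg(q$lsc), seg(q$irb), seg(q$ssc), seg(q$ira))
  expect_true(same_circular_sequence(rebuilt, g$seq))
})

test_that("space accounting matches the per-base oracle and sums to 100", {
  g <- mini_plastome(seed = 45)
  sa <- space_accounting(g)
  want <- space_oracle(g)
  expect_equal(unname(sa$counts), unname(want))
  expect_equal(sa$pct_gene + sa$pct_intron + sa$pct_intergenic, 100,
               tolerance = 1e-9)
  # one gene covering the whole circle
  whole <- as_plastome(paste0("ATG", strrep("AAC", 30), "TAA"))
  whole$features <- data.frame(name = "g", kind = "protein", strand = "+",
                               start = 0L, end = whole$length,
                               exons = I(list(cbind(0L, whole$length))),
                               stringsAsFactors = FALSE)
  sa2 <- space_accounting(whole)
  expect_equal(c(sa2$pct_gene, sa2$pct_intron, sa2$pct_intergenic),
               c(100, 0, 0))
  # pseudogene flag moves remnant bases between gene and intergenic space
  sa3 <- space_accounting(g, include_pseudogenes = FALSE)
  expect_lt(sa3$pct_gene, sa$pct_gene)
})

test_that("the default generator hits the published space proportions", {
  g <- generate_plastome(plastome_spec(seed = 46))
  sa <- space_accounting(g)
  expect_equal(sa$pct_gene, 54.34, tolerance = 0.01)
  expect_equal(sa$pct_intron, 11.91, tolerance = 0.01)
  expect_equal(sa$pct_intergenic, 33.75, tolerance = 0.01)
})

test_that("published size arithmetic flags exactly the inconsistent row", {
  tab <- load_published_geometry()
  chk <- check_quadripartite_sizes(tab)
  expect_equal(sum(!chk$consistent), 1L)
  expect_match(chk$species[!chk$consistent], "arundinacea")
  expect_equal(chk$difference[!chk$consistent], 137060L - 136048L)
})

test_that("canonical form unifies rotation, strand and SSC orientation", {
  g <- mini_plastome(seed = 47)
  rot <- plastomekit:::rotate_seq(g$seq, 5000L)
  expect_true(plastome_equivalent(rot, g))
  expect_true(plastome_equivalent(revcomp(g$seq), g))
  # SSC-flipped isomer
  q <- partition_quadripartite(g)
  s0 <- q$ssc[["start"]]; sl <- q$ssc[["len"]]
  flip <- paste0(substr(g$seq, 1, s0), revcomp(substr(g$seq, s0 + 1, s0 + sl)),
                 substr(g$seq, s0 + sl + 1, g$length))
  expect_true(plastome_equivalent(flip, g))
  expect_false(plastome_equivalent(mini_plastome(seed = 48), g))
})
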