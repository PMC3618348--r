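test_that("transferring a reference onto itself is the identity", {
  g <- mini_plastome(seed = 50)
  tr <- transfer_annotation(g, g)
  expect_equal(length(tr$missing), 0L)
  expect_equal(nrow(tr$features), nrow(g$features))
  expect_equal(tr$features$start, g$features$start)
  expect_equal(tr$features$end, g$features$end)
  expect_equal(tr$features$strand, g$features$strand)
  expect_false(any(tr$features$truncated))
})

test_that("an in-frame deletion shortens the transferred gene by 3 codons", {
  g <- mini_plastome(seed = 51)
  atpa <- g$features[g$features$name == "atpA", ]
  del <- list(kind = "deletion", start = atpa$start + 30L, end = atpa$start + 39L)
  child <- evolve_genome(g, rates = list(sub = 0, indel = 0),
                         structured_events = list(del), seed = 1)$genome
  tr <- transfer_annotation(child, g)
  a2 <- tr$features[tr$features$name == "atpA", ]
  expect_equal(feature_codons(child$seq, a2), feature_codons(g$seq, atpa) - 3)
  expect_false(a2$truncated)
})

test_that("a fully deleted gene lands on the missing list", {
  g <- mini_plastome(seed = 52)
  tgt <- g$features[g$features$name == "psbA", ]
  del <- list(kind = "deletion", start = tgt$start - 20L, end = tgt$end + 20L)
  child <- evolve_genome(g, rates = list(sub = 0, indel = 0),
                         structured_events = list(del), seed = 1)$genome
  tr <- transfer_annotation(child, g)
  expect_true("psbA" %in% tr$missing)
  expect_false("psbA" %in% tr$features$name)
})

test_that("gene length table reproduces published size differences", {
  tab <- load_published_gene_lengths()
  mat <- as.matrix(tab[, 2:7])
  rownames(mat) <- tab$gene
  d <- gene_length_differences(mat)
  expect_equal(unname(d), tab$size_difference)
  # spot checks against the printed column
  expect_equal(unname(d["rpoC2"]), 38)
  expect_equal(unname(d["rps18"]), 21)
  expect_equal(unname(d["ycf68"]), 18)
  expect_equal(unname(d["ndhH"]), 7)
})

test_that("gene_length_table on synthetic species recovers planted deltas", {
  g <- mini_plastome(seed = 53)
  atpa <- g$features[g$features$name == "atpA", ]
  rbcl <- g$features[g$features$name == "rbcL", ]
  mk_child <- function(dels, seed) {
    evolve_genome(g, rates = list(sub = 0, indel = 0),
                  structured_events = dels, seed = seed)$genome
  }
  c1 <- mk_child(list(list(kind = "deletion", start = atpa$start + 12L,
                           end = atpa$start + 21L)), 1)  # atpA -3 codons
  c2 <- mk_child(list(list(kind = "deletion", start = rbcl$start + 30L,
                           end = rbcl$start + 60L)), 2)  # rbcL -10 codons
  ann <- list(spA = transfer_annotation(g, g)$features,
              spB = transfer_annotation(c1, g)$features,
              spC = transfer_annotation(c2, g)$features)
  tab <- gene_length_table(ann)
  expect_setequal(tab$gene, c("atpA", "rbcL"))
  expect_equal(tab$difference[tab$gene == "atpA"], 3)
  expect_equal(tab$difference[tab$gene == "rbcL"], 10)
  # all-identical annotations -> empty variable-gene table
  expect_equal(nrow(gene_length_table(list(a = g, b = g))), 0L)
})

test_that("grass feature calls follow the region and reading-frame rules", {
  g <- mini_plastome(seed = 54)
  fr <- call_grass_features(g)
  expect_equal(fr$rbcl_psai_len, 600) # 80 + 55 + 100 + 200 + 165 by design
  expect_equal(fr$rpl23_remnant, "present")
  expect_equal(fr$accd, "pseudo") # random remnant is not a clean frame
  expect_false(orf_complete_oracle(plastomekit:::spliced_seq(
    g$seq, g$features$exons[[which(g$features$name == "accD")]], "+")))
  # planting an intact ORF in place of the remnant makes the call "present"
  accd <- g$features[g$features$name == "accD", ]
  orf <- plastomekit:::random_orf(200 %/% 3)
  g2 <- g
  substr(g2$seq, accd$start + 1L, accd$start + nchar(orf)) <- orf
  f2 <- g2$features
  f2$end[f2$name == "accD"] <- accd$start + nchar(orf)
  f2$exons[[which(f2$name == "accD")]] <- cbind(accd$start, accd$start + nchar(orf))
  g2$features <- f2
  fr2 <- call_grass_features(g2)
  expect_equal(fr2$accd, "present")
  expect_true(orf_complete_oracle(plastomekit:::spliced_seq(
    g2$seq, f2$exons[[which(f2$name == "accD")]], "+")))
  # a planted internal stop flips it to pseudo, confirmed by the ORF oracle
  g3 <- g2
  substr(g3$seq, accd$start + 31L, accd$start + 33L) <- "TAA"
  fr3 <- call_grass_features(g3)
  expect_equal(fr3$accd, "pseudo")
  expect_false(orf_complete_oracle(plastomekit:::spliced_seq(
    g3$seq, f2$exons[[which(f2$name == "accD")]], "+")))
})

test_that("the 317-bp ablation removes the accD remnant entirely", {
  g <- mini_plastome(seed = 55)
  accd <- g$features[g$features$name == "accD", ]
  del <- list(kind = "pseudogene_ablation", start = accd$start - 8L,
              end = accd$start + 309L)
  child <- evolve_genome(g, rates = list(sub = 0, indel = 0),
                         structured_events = list(del), seed = 1)$genome
  fr <- call_grass_features(child)
  expect_equal(fr$accd, "absent")
  expect_equal(fr$rbcl_psai_len, 600 - 317)
})

test_that("rbcL-psaI length is strand independent; missing genes error", {
  g <- mini_plastome(seed = 56)
  fwd <- call_grass_features(g)
  rc <- as_plastome(revcomp(g$seq))
  n <- g$length
  f <- g$features
  f$exons <- I(lapply(f$exons, function(m)
    cbind(n - m[, 2], n - m[, 1])[rev(seq_len(nrow(m))), , drop = FALSE]))
  tmp <- f$start
  f$start <- n - f$end
  f$end <- n - tmp
  f$strand <- ifelse(f$strand == "+", "-", "+")
  rc$features <- f
  bwd <- call_grass_features(rc)
  expect_equal(bwd$rbcl_psai_len, fwd$rbcl_psai_len)
  noanno <- g
  noanno$features <- g$features[g$features$name != "rbcL", ]
  expect_error(call_grass_features(noanno), class = "region_undefined")
})

test_that("rpoC2 insertion length is measured between flank anchors", {
  set.seed(57)
  left <- random_dna(60); right <- random_dna(60)
  insertion <- random_dna(341)
  g <- mini_plastome(seed = 57)
  g2 <- as_plastome(paste0(substr(g$seq, 1, 500), left, insertion, right,
                           substr(g$seq, 501, g$length)))
  g2$features <- g$features # rbcL/psaI coordinates unaffected upstream? shift!
  # rebuild features by transfer to keep coordinates honest
  g2$features <- transfer_annotation(g2, g)$features
  fr <- call_grass_features(g2, flank_library = list(left = left, right = right))
  expect_equal(fr$rpoc2_insertion_len, 341L)
  fr_na <- call_grass_features(g2)
  expect_true(is.na(fr_na$rpoc2_insertion_len))
  expect_match(fr_na$rpoc2_reason, "no flank")
})
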