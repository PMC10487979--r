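# Seeded local search, hit chaining and block classification.

test_that("a verbatim copy is found with identity and coverage 1", {
  set.seed(61)
  exon <- random_dna_fix(150)
  subject <- paste0(random_dna_fix(400), exon, random_dna_fix(400))
  hits <- seeded_local_search(exon, subject)
  expect_identical(nrow(hits), 1L)
  expect_equal(hits$identity, 1)
  expect_equal(hits$coverage, 1)
  expect_identical(hits$start, 400L)
  expect_identical(hits$end, 550L)
  expect_identical(hits$strand, "+")
})

test_that("inverted copies are found on the minus strand", {
  set.seed(62)
  exon <- random_dna_fix(120)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(exon)))
  subject <- paste0(random_dna_fix(300), rc, random_dna_fix(300))
  hits <- seeded_local_search(exon, subject)
  expect_identical(hits$strand, "-")
  expect_identical(hits$start, 300L)
})

test_that("subjects without seeds yield no hits; short queries warn", {
  expect_identical(nrow(seeded_local_search(strrep("A", 60), strrep("C", 500))),
                   0L)
  expect_warning(h <- seeded_local_search("ACGTACGT", strrep("A", 100)),
                 "shorter than seed")
  expect_identical(nrow(h), 0L)
})

test_that("self-locations are excluded", {
  set.seed(63)
  exon <- random_dna_fix(150)
  subject <- paste0(random_dna_fix(100), exon, random_dna_fix(100))
  hits <- seeded_local_search(exon, subject, exclude = c(100L, 250L))
  expect_identical(nrow(hits), 0L)
})

test_that("mutated copies stay above threshold and match the SW oracle", {
  set.seed(64)
  for (i in 1:10) {
    exon <- random_dna_fix(sample(60:120, 1))
    copy <- strsplit(exon, "")[[1]]
    nmut <- round(0.1 * length(copy))
    at <- sample(length(copy), nmut)
    for (p in at) copy[p] <- sample(setdiff(c("A", "C", "G", "T"), copy[p]), 1)
    subject <- paste0(random_dna_fix(150), paste(copy, collapse = ""),
                      random_dna_fix(150))
    hits <- seeded_local_search(exon, subject)
    expect_gte(nrow(hits), 1L)
    expect_gte(max(hits$identity), 0.80)
    # window-refined score never exceeds (and here equals) the full SW score
    expect_lte(max(hits$score), sw_oracle(exon, subject))
  }
})

test_that("colinear hits chain into blocks and isolated hits stay apart", {
  hits <- data.frame(
    start = c(1000L, 1300L, 1700L, 150000L),
    end = c(1200L, 1600L, 1900L, 150200L),
    strand = "+", identity = 0.95, coverage = 1, score = 100,
    exon_index = c(4L, 5L, 6L, 2L))
  b <- chain_hits_to_blocks(hits)
  expect_identical(nrow(b), 2L)
  expect_identical(b$exon_from[1], 4L)
  expect_identical(b$exon_to[1], 6L)
  expect_identical(b$n_exons[1], 3L)
  # non-colinear exon order breaks the chain
  hits2 <- hits[1:3, ]; hits2$exon_index <- c(4L, 3L, 5L)
  expect_gt(nrow(chain_hits_to_blocks(hits2)), 1L)
  # inverted chains need strictly decreasing exon indices
  hits3 <- hits[1:3, ]; hits3$strand <- "-"; hits3$exon_index <- c(9L, 8L, 7L)
  expect_identical(nrow(chain_hits_to_blocks(hits3)), 1L)
})

test_that("block locations classify as internal / upstream / downstream", {
  set.seed(65)
  cds <- random_cds_fix(120)
  m0 <- make_coding_model("tx", cds, c(90L, 180L, 270L))
  # give the model generous flanks to place blocks in
  m <- gene_model("tx", "g1", m0$exons, m0$gene_seq,
                  flank_seq = paste0(random_dna_fix(5000), m0$gene_seq,
                                     random_dna_fix(5000)),
                  flank_offset = 5000L)
  introns <- m$introns + 5000L
  blk <- function(s, e, from = 2L, to = 3L)
    data.frame(start = s, end = e, exon_from = from, exon_to = to)
  loc <- classify_block_location(blk(introns[2, 1] + 2L, introns[2, 2] - 2L), m)
  expect_identical(loc$location, "internal")
  expect_identical(loc$intron_index, 2L)
  expect_false(loc$straddle)
  loc2 <- classify_block_location(blk(1000L, 4659L), m)
  expect_identical(loc2$location, "upstream")
  expect_identical(loc2$distance, 341L)
  gend <- 5000L + nchar(m$gene_seq)
  loc3 <- classify_block_location(blk(gend + 1L, gend + 200L), m)
  expect_identical(loc3$location, "downstream")
  expect_identical(loc3$distance, 1L)
  # a block overlapping its own source exons is a self-hit leak
  ex2 <- m$exons[2, ] + 5000L
  expect_error(
    classify_block_location(blk(ex2[1] - 5L, ex2[2] + 5L, 2L, 2L), m),
    "self-hit")
})

test_that("planted duplications are recovered with exact spans", {
  cfg <- sim_config(seed = 71, n_leaves = 2, tree = "(a,b);", te_rate = 0,
    duplications = list(
      list(taxon = "a", exon_from = 4, exon_to = 9,
           target = list(type = "intron", index = 14), divergence = 0),
      list(taxon = "b", exon_from = 2, exon_to = 6,
           target = list(type = "downstream", distance = 5000),
           divergence = 0)))
  sim <- simulate_family(cfg)
  ba <- suppressWarnings(scan_duplications(sim$models$a))
  ia <- ba[ba$location == "internal" & !is.na(ba$intron_index), ]
  expect_true(any(ia$exon_from == 4 & ia$exon_to == 9 & ia$intron_index == 14))
  bb <- suppressWarnings(scan_duplications(sim$models$b))
  db <- bb[bb$location == "downstream", ]
  # exon 2 of this family is only 14 nt, below the score cutoff for a
  # significant hit, so the recoverable span starts at exon 3
  expect_true(any(db$exon_from <= 3 & db$exon_to == 6))
  expect_true(all(ba$completeness == "partial"))
})
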