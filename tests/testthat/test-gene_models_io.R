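# Parsing, validation and writing of the external formats.

write_fixture_genome <- function(dir, scaffold, seq) {
  fa <- file.path(dir, paste0(scaffold, ".fa"))
  writeLines(c(paste0(">", scaffold), seq), fa)
  fa
}

test_that("GFF3 coordinates convert to 0-based half-open and introns derive", {
  dir <- withr::local_tempdir()
  seq <- strrep("ACGTACGTAC", 10)  # 100 nt
  fa <- write_fixture_genome(dir, "sc1", seq)
  gff <- file.path(dir, "one.gff3")
  writeLines(c("##gff-version 3",
               "sc1\tsrc\tgene\t1\t9\t.\t+\t.\tID=g1",
               "sc1\tsrc\tmRNA\t1\t9\t.\t+\t.\tID=m1;Parent=g1",
               "sc1\tsrc\texon\t1\t9\t.\t+\t.\tParent=m1"), gff)
  models <- parse_gff3(gff, fa, taxon = "tx")
  expect_length(models, 1)
  m <- models[[1]]
  expect_identical(m$span, c(0L, 9L))
  expect_identical(nchar(m$gene_seq), 9L)
  expect_identical(nrow(m$introns), 0L)
})

test_that("minus-strand genes are normalized to transcription order", {
  dir <- withr::local_tempdir()
  set.seed(5)
  seq <- random_dna_fix(200)
  fa <- write_fixture_genome(dir, "sc1", seq)
  gff <- file.path(dir, "rev.gff3")
  # genomic exons 21..50 and 101..140 on '-': exon 1 of the model is the
  # rightmost genomic exon
  writeLines(c("##gff-version 3",
               "sc1\tsrc\tgene\t21\t140\t.\t-\t.\tID=g1",
               "sc1\tsrc\tmRNA\t21\t140\t.\t-\t.\tID=m1;Parent=g1",
               "sc1\tsrc\tCDS\t21\t50\t.\t-\t.\tParent=m1",
               "sc1\tsrc\tCDS\t101\t140\t.\t-\t.\tParent=m1"), gff)
  m <- parse_gff3(gff, fa, taxon = "tx")[[1]]
  expect_identical(nrow(m$exons), 2L)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_identical(exon_seqs(m)[1], rc(substring(seq, 101, 140)))
  expect_identical(m$cds_seq,
                   rc(paste0(substring(seq, 21, 50), substring(seq, 101, 140))))
})

test_that("opposite-strand encodings of one gene give identical cds_seq", {
  dir <- withr::local_tempdir()
  set.seed(6)
  seq <- random_dna_fix(300)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  fa1 <- write_fixture_genome(dir, "fwd", seq)
  fa2 <- write_fixture_genome(dir, "rev", rc)
  gff1 <- file.path(dir, "f.gff3"); gff2 <- file.path(dir, "r.gff3")
  writeLines(c("##gff-version 3",
               "fwd\tsrc\tgene\t51\t250\t.\t+\t.\tID=g1",
               "fwd\tsrc\tmRNA\t51\t250\t.\t+\t.\tID=m1;Parent=g1",
               "fwd\tsrc\tCDS\t51\t110\t.\t+\t.\tParent=m1",
               "fwd\tsrc\tCDS\t181\t250\t.\t+\t.\tParent=m1"), gff1)
  # same intervals mirrored onto the reverse complement: x -> 301 - x
  writeLines(c("##gff-version 3",
               "rev\tsrc\tgene\t51\t250\t.\t-\t.\tID=g1",
               "rev\tsrc\tmRNA\t51\t250\t.\t-\t.\tID=m1;Parent=g1",
               "rev\tsrc\tCDS\t191\t250\t.\t-\t.\tParent=m1",
               "rev\tsrc\tCDS\t51\t120\t.\t-\t.\tParent=m1"), gff2)
  m1 <- parse_gff3(gff1, fa1, taxon = "a")[[1]]
  m2 <- parse_gff3(gff2, fa2, taxon = "a")[[1]]
  expect_identical(m1$cds_seq, m2$cds_seq)
  expect_identical(unname(m1$exons), unname(m2$exons))
})

test_that("errors: missing scaffold, overlapping exons", {
  dir <- withr::local_tempdir()
  fa <- write_fixture_genome(dir, "sc1", strrep("A", 50))
  gff <- file.path(dir, "bad.gff3")
  writeLines(c("##gff-version 3",
               "scX\tsrc\tgene\t1\t9\t.\t+\t.\tID=g1",
               "scX\tsrc\tmRNA\t1\t9\t.\t+\t.\tID=m1;Parent=g1",
               "scX\tsrc\texon\t1\t9\t.\t+\t.\tParent=m1"), gff)
  expect_error(parse_gff3(gff, fa), "scaffold 'scX'")
  writeLines(c("##gff-version 3",
               "sc1\tsrc\tgene\t1\t30\t.\t+\t.\tID=g1",
               "sc1\tsrc\tmRNA\t1\t30\t.\t+\t.\tID=m1;Parent=g1",
               "sc1\tsrc\texon\t1\t20\t.\t+\t.\tParent=m1",
               "sc1\tsrc\texon\t15\t30\t.\t+\t.\tParent=m1"), gff)
  expect_error(parse_gff3(gff, fa), "overlapping exons.*m1")
})

test_that("a 22-exon record yields a 21-intron model and round-trips", {
  sim <- simulate_family(sim_config(seed = 3, n_leaves = 2, tree = "(a,b);",
                                    root_exons = 22, gain_rate = 0,
                                    loss_rate = 0, te_rate = 0))
  d <- withr::local_tempdir()
  p <- emit_files(sim$models, sim$truth, d)
  m <- parse_gff3(p$gff3[["a"]], p$fasta[["a"]], taxon = "a")[[1]]
  expect_identical(nrow(m$exons), 22L)
  expect_identical(nrow(m$introns), 21L)
  # round-trip: write back and re-parse
  gff2 <- file.path(d, "rt.gff3")
  write_gene_gff3(list(m), gff2)
  m2 <- parse_gff3(gff2, p$fasta[["a"]], taxon = "a")[[1]]
  expect_identical(m2$exons, m$exons)
  expect_identical(m2$cds_seq, m$cds_seq)
  expect_identical(m2$gene_seq, m$gene_seq)
})

test_that("exon/intron concatenation reproduces cds and gene sequence", {
  sim <- simulate_family(sim_config(seed = 9, n_leaves = 4, te_rate = 1))
  for (m in sim$models) {
    expect_identical(paste(exon_seqs(m), collapse = ""), m$cds_seq)
    inter <- character(0)
    for (i in seq_len(nrow(m$exons))) {
      inter <- c(inter, exon_seqs(m)[i])
      if (i <= nrow(m$introns)) inter <- c(inter, intron_seqs(m)[i])
    }
    expect_identical(paste(inter, collapse = ""), m$gene_seq)
  }
})

test_that("parse_newick validates rootedness and labels internal nodes", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_identical(ape::Ntip(tr), 4L)
  expect_identical(tr$Nnode, 3L)
  expect_true(all(nzchar(tr$node.label)))
  expect_error(parse_newick("(A,B,C);"), "root")
  # deterministic labels: same input, same labels
  expect_identical(parse_newick("((A,B),(C,D));")$node.label, tr$node.label)
})

test_that("RepeatMasker .out parsing maps the four-way class vocabulary", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "te.out")
  hdr <- c("   SW   perc ...", "score  div. ...", "")
  rec <- function(cf, name) sprintf(
    " 1000   10.0  0.0  0.0  sc1   101   600 (400) + %s  %s  1  500 (0)  1",
    name, cf)
  writeLines(c(hdr, rec("LTR/Gypsy", "gyp1"), rec("LTR/Copia", "cop1"),
               rec("DNA/hAT", "hat1"), rec("RC/Helitron", "hel1"),
               rec("Unknown", "unk1")), out)
  ann <- parse_repeatmasker_out(out)
  expect_identical(nrow(ann), 5L)
  expect_identical(ann$te_class,
                   c("retrotransposon", "retrotransposon", "DNA_transposon",
                     "helitron", "unclassified"))
  expect_identical(ann$superfamily[1:2], c("Gypsy", "Copia"))
  expect_identical(ann$start[1], 100L)  # 1-based 101 -> 0-based 100
  expect_identical(ann$end[1], 600L)

  writeLines(hdr, out)
  expect_identical(nrow(parse_repeatmasker_out(out)), 0L)

  writeLines(c(hdr, rec("LTR/Gypsy", "gyp1"), "garbage line here"), out)
  expect_warning(ann2 <- parse_repeatmasker_out(out), "1 malformed")
  expect_identical(nrow(ann2), 1L)
})

test_that("report tables render percentages to two decimals", {
  dir <- withr::local_tempdir()
  types <- c(rep("GT-AG", 1391), rep("GG-CA", 23), rep("AT-AC", 65))
  census <- splice_site_census(list(make_splice_model(types)))
  write_report_tables(list(splice_census = census), dir)
  tab <- read.delim(file.path(dir, "splice_census.tsv"),
                    colClasses = "character")
  expect_identical(tab$percent[tab$site_type == "GT-AG"], "94.05")

  # empty duplication result: header-only TSV
  empty <- scan_duplications(make_splice_model("GT-AG"))
  write_report_tables(list(duplications = empty), dir)
  lines <- readLines(file.path(dir, "duplication_blocks.tsv"))
  expect_length(lines, 1L)

  # matrix shape: 4 taxa x 3 sites -> 4 data rows, taxon + 3 site columns
  m <- matrix(1L, 4, 3, dimnames = list(paste0("t", 1:4), c("1", "2", "3")))
  write_report_tables(list(presence_matrix = m), dir)
  pm <- read.delim(file.path(dir, "presence_matrix.tsv"), check.names = FALSE)
  expect_identical(dim(pm), c(4L, 4L))
})
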