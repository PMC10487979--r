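# Protein star alignment, intron projection and site clustering.

test_that("star alignment of identical sequences has no gaps", {
  prots <- c(a = "MKLVNNPQRST", b = "MKLVNNPQRST", c = "MKLVNNPQRST")
  msa <- align_proteins(prots)
  expect_false(any(grepl("-", msa, fixed = TRUE)))
  expect_identical(unname(nchar(msa)), rep(11L, 3))
})

test_that("an insertion in one sequence gaps all the others", {
  base <- "MKLVNNPQRSTWYHEDA"
  ins <- paste0(substring(base, 1, 8), "GGG", substring(base, 9))
  prots <- c(a = base, b = ins, c = base)
  msa <- align_proteins(prots)
  expect_identical(unique(nchar(unclass(msa))), 20L)
  expect_identical(lengths(regmatches(msa, gregexpr("-", msa)))[["a"]], 3L)
  expect_identical(lengths(regmatches(msa, gregexpr("-", msa)))[["b"]], 0L)
  expect_identical(gsub("-", "", msa[["a"]]), base)
})

test_that("alignment input validation", {
  expect_error(align_proteins(c(a = "MKL")), "two")
  expect_error(align_proteins(c(a = "MKL", b = "")), "empty")
  m <- make_coding_model("a", random_cds_fix(20), 30L)
  expect_error(map_introns_to_alignment(m, c(a = "MK-", b = "MKLV")),
               "ragged")
})

test_that("intron projection computes codon index, phase and column", {
  set.seed(13)
  cds <- random_cds_fix(200)  # 600 nt
  m <- make_coding_model("a", cds, c(300L, 301L, 500L))
  prot <- substr(as.character(Biostrings::translate(
    Biostrings::DNAString(cds))), 1, 199)
  msa <- c(a = prot)
  pos <- map_introns_to_alignment(m, msa)
  expect_identical(pos$codon_index, c(100L, 100L, 166L))
  expect_identical(pos$phase, c(0L, 1L, 2L))
  # ungapped row: column equals codon index
  expect_identical(pos$alignment_column, pos$codon_index)
  # mismatching protein is an error naming the taxon
  expect_error(map_introns_to_alignment(m, c(a = paste0(prot, "W"))), "'a'")
})

test_that("identical proteins put homologous introns in one column", {
  set.seed(14)
  cds <- random_cds_fix(150)
  m1 <- make_coding_model("a", cds, 300L)
  m2 <- make_coding_model("b", cds, 300L)
  msa <- align_proteins(c(a = translate_cds_fix(cds), b = translate_cds_fix(cds)))
  p1 <- map_introns_to_alignment(m1, msa)
  p2 <- map_introns_to_alignment(m2, msa)
  expect_identical(p1$alignment_column, p2$alignment_column)
})

test_that("presence matrix recovers a shared 21-site inventory", {
  set.seed(15)
  cds <- random_cds_fix(400)
  offs <- sort(sample(seq(3, 1197, by = 3), 21))
  models <- lapply(c("a", "b"), make_coding_model, cds = cds, offsets = offs)
  msa <- c(a = translate_cds_fix(cds), b = translate_cds_fix(cds))
  pos <- do.call(rbind, lapply(models, map_introns_to_alignment, msa = msa))
  mat <- build_presence_matrix(pos)
  expect_identical(dim(mat), c(2L, 21L))
  expect_true(all(mat == 1L))
  # conservation: total mapped introns = sum of matrix entries
  expect_identical(sum(mat), nrow(pos))
  # a taxon lacking one site gets a 0 cell
  models2 <- list(make_coding_model("a", cds, offs),
                  make_coding_model("b", cds, offs[-10]))
  pos2 <- do.call(rbind, lapply(models2, map_introns_to_alignment, msa = msa))
  mat2 <- build_presence_matrix(pos2)
  expect_identical(sum(mat2["b", ]), 20L)
  expect_identical(sum(mat2[, 10] == 0), 1L)
})

test_that("site count is non-increasing as column tolerance grows", {
  set.seed(16)
  cds <- random_cds_fix(300)
  pos <- do.call(rbind, lapply(1:4, function(i) {
    offs <- sort(sample(seq(3, 897, by = 3), 8))
    map_introns_to_alignment(
      make_coding_model(paste0("t", i), cds, offs),
      stats::setNames(rep(translate_cds_fix(cds), 4), paste0("t", 1:4)))
  }))
  counts <- vapply(c(0, 1, 2, 5, 10), function(tol)
    ncol(suppressWarnings(tryCatch(
      build_presence_matrix(pos, column_tolerance = tol),
      error = function(e) matrix(nrow = 0, ncol = 0)))), integer(1))
  counts <- counts[counts > 0]
  expect_true(all(diff(counts) <= 0))
})

test_that("over-loose tolerance raises an ambiguity error naming the taxon", {
  set.seed(17)
  cds <- random_cds_fix(100)
  m1 <- make_coding_model("a", cds, c(30L, 33L))  # adjacent phase-0 introns
  m2 <- make_coding_model("b", cds, 30L)
  msa <- c(a = translate_cds_fix(cds), b = translate_cds_fix(cds))
  pos <- rbind(map_introns_to_alignment(m1, msa),
               map_introns_to_alignment(m2, msa))
  expect_error(build_presence_matrix(pos, column_tolerance = 5),
               "multiple introns")
  expect_silent(build_presence_matrix(pos, column_tolerance = 0))
})

test_that("novel sites get prime labels against a reference complement", {
  mat <- matrix(c(1, 1, 1, 0,
                  1, 1, 1, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("ref", "other"), NULL))
  colnames(mat) <- as.character(1:4)
  lab <- label_intron_sites(mat, "ref")
  expect_identical(colnames(lab), c("1", "2", "3", "3'"))
  # reference as logical vector, novel site in the middle
  lab2 <- label_intron_sites(mat, c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(colnames(lab2), c("1", "1'", "2", "3"))
})

test_that("unmutated simulated families are recovered exactly", {
  sim <- simulate_family(sim_config(seed = 22, n_leaves = 8, subst_rate = 0,
                                    gain_rate = 0.2, loss_rate = 0.4))
  pos <- do.call(rbind, lapply(sim$models, map_introns_to_alignment,
                               msa = sim$truth$msa))
  mat <- build_presence_matrix(pos)
  tm <- sim$truth$matrix
  expect_identical(dim(mat), dim(tm))
  expect_identical(unname(mat[rownames(tm), ]), unname(tm))
})
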