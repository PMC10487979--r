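# Internal helpers shared across modules. All genomic intervals inside the
# package are 0-based half-open; conversions to/from 1-based inclusive are
# confined to the format parsers/writers.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Substitute bases at a fixed per-site probability
#' @noRd
mutate_dna <- function(seq, divergence) {
  if (divergence <= 0 || nchar(seq) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < divergence)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' @noRd
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a CDS, dropping a terminal stop if present
#' @noRd
translate_cds <- function(cds_seq) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq),
                                           if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}

#' Interval matrix helper: validate an n x 2 matrix of half-open intervals
#' @noRd
as_interval_matrix <- function(x) {
  if (is.null(x)) return(matrix(integer(0), ncol = 2L,
                                dimnames = list(NULL, c("start", "end"))))
  m <- matrix(as.integer(x), ncol = 2L)
  colnames(m) <- c("start", "end")
  if (any(m[, 2L] < m[, 1L])) stop("interval with end < start")
  m
}

#' Sum of interval widths
#' @noRd
interval_widths <- function(m) m[, 2L] - m[, 1L]

#' Format a proportion (0-100) with two decimals, the report convention
#' @noRd
fmt_pct <- function(x) sprintf("%.2f", x)

#' Run code with a private RNG stream seeded from `seed`
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}
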