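#' GC content of a nucleotide sequence
#'
#' Percent G+C over unambiguous bases only: IUPAC ambiguity codes (including
#' N) are excluded from both numerator and denominator, so N-rich draft
#' sequence does not deflate the estimate.
#'
#' @param seq nucleotide string (case-insensitive, IUPAC allowed).
#' @return percent in `[0, 100]`, or `NA_real_` if the sequence contains no
#'   unambiguous base.
#' @export
gc_content <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n_gc <- sum(chars %in% c("G", "C"))
  n_at <- sum(chars %in% c("A", "T"))
  denom <- n_gc + n_at
  if (denom == 0L) return(NA_real_)
  100 * n_gc / denom
}

#' GC content by codon position
#'
#' GC1/GC2/GC3: percent G+C over the first, second and third positions of
#' each complete codon of a coding sequence. A trailing partial codon is
#' dropped with a warning.
#'
#' @param cds_seq coding sequence, length >= 3.
#' @return named numeric vector `c(gc1=, gc2=, gc3=)`.
#' @export
gc_by_codon_position <- function(cds_seq) {
  n <- nchar(cds_seq)
  if (n < 3L) stop("cds_seq shorter than one codon")
  if (n %% 3L != 0L) {
    warning("dropping trailing partial codon")
    n <- n - n %% 3L
    cds_seq <- substring(cds_seq, 1L, n)
  }
  chars <- strsplit(toupper(cds_seq), "", fixed = TRUE)[[1L]]
  pos <- rep(1:3, n / 3L)
  vapply(1:3, function(p) {
    cc <- chars[pos == p]
    gc <- sum(cc %in% c("G", "C")); at <- sum(cc %in% c("A", "T"))
    if (gc + at == 0L) NA_real_ else 100 * gc / (gc + at)
  }, numeric(1)) -> v
  names(v) <- c("gc1", "gc2", "gc3")
  v
}

#' Full GC profile of a gene model
#'
#' @param model a [gene_model()].
#' @return list with `gc_gene`, `gc_cds`, `gc1`, `gc2`, `gc3` and
#'   `gc_introns` (per-intron percents).
#' @export
gc_profile <- function(model) {
  pos <- gc_by_codon_position(model$cds_seq)
  list(gc_gene = gc_content(model$gene_seq),
       gc_cds = gc_content(model$cds_seq),
       gc1 = unname(pos[1L]), gc2 = unname(pos[2L]), gc3 = unname(pos[3L]),
       gc_introns = vapply(intron_seqs(model), gc_content, numeric(1),
                           USE.NAMES = FALSE))
}

#' Splice-site census
#'
#' Records the terminal dinucleotides of every intron (on the normalized
#' transcription strand) across a set of gene models and summarizes site
#' types. An intron is canonical iff its type is GT-AG. Introns shorter
#' than 4 nt are flagged invalid and excluded from the totals. The census
#' counts per sequence (gene copy), not per species.
#'
#' @param models list of [gene_model()].
#' @return object of class `splice_census`: list with `records` (one row per
#'   intron: taxon, gene_id, intron_index, donor, acceptor, site_type,
#'   canonical, valid) and `summary` (site_type, count, percent over valid
#'   sites), plus `canonical_percent` / `noncanonical_percent`.
#' @export
splice_site_census <- function(models) {
  rows <- lapply(models, function(m) {
    seqs <- intron_seqs(m)
    if (length(seqs) == 0L) return(NULL)
    donor <- toupper(substring(seqs, 1L, 2L))
    acceptor <- toupper(substring(seqs, nchar(seqs) - 1L, nchar(seqs)))
    data.frame(taxon = m$taxon, gene_id = m$gene_id,
               intron_index = seq_along(seqs),
               donor = donor, acceptor = acceptor,
               site_type = paste(donor, acceptor, sep = "-"),
               canonical = donor == "GT" & acceptor == "AG",
               valid = nchar(seqs) >= 4L,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(records))
    records <- data.frame(taxon = character(0), gene_id = character(0),
                          intron_index = integer(0), donor = character(0),
                          acceptor = character(0), site_type = character(0),
                          canonical = logical(0), valid = logical(0))
  ok <- records[records$valid, , drop = FALSE]
  total <- nrow(ok)
  counts <- if (total > 0L) sort(table(ok$site_type), decreasing = TRUE)
            else table(character(0))
  summary <- data.frame(site_type = names(counts),
                        count = as.integer(counts),
                        percent = if (total > 0L) 100 * as.integer(counts) / total
                                  else numeric(0),
                        stringsAsFactors = FALSE)
  structure(list(
    records = records, summary = summary, total = total,
    canonical_percent = if (total > 0L) 100 * sum(ok$canonical) / total else NA_real_,
    noncanonical_percent = if (total > 0L) 100 * sum(!ok$canonical) / total else NA_real_
  ), class = "splice_census")
}

#' @export
print.splice_census <- function(x, ...) {
  cat(sprintf("<splice_census> %d valid sites: %s%% canonical (GT-AG), %s%% non-canonical\n",
              x$total, fmt_pct(x$canonical_percent),
              fmt_pct(x$noncanonical_percent)))
  invisible(x)
}

#' Intron length bins
#'
#' Counts introns per length bin per taxon. Bin edges are strict lower
#' bounds: with the default `edges = c(5000, 10000)` the bins are
#' `<=5000`, `(5000, 10000]` and `>10000`, so "larger than 5 kb" means
#' strictly greater than 5000 nt.
#'
#' @param models list of [gene_model()].
#' @param edges increasing numeric vector of bin edges.
#' @return data.frame: taxon, gene_id, one count column per bin, plus a
#'   `TOTAL` row block attribute via `attr(, "totals")`.
#' @export
intron_length_bins <- function(models, edges = c(5000, 10000)) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  breaks <- c(-Inf, edges, Inf)
  labels <- c(sprintf("<=%d", edges[1L]),
              if (length(edges) > 1L)
                sprintf("(%d,%d]", edges[-length(edges)], edges[-1L]),
              sprintf(">%d", edges[length(edges)]))
  per <- lapply(models, function(m) {
    w <- interval_widths(m$introns)
    cnt <- table(cut(w, breaks = breaks, labels = labels, right = TRUE))
    cbind(data.frame(taxon = m$taxon, gene_id = m$gene_id,
                     n_introns = length(w), stringsAsFactors = FALSE),
          as.data.frame(rbind(as.integer(cnt)),
                        col.names = labels))
  })
  out <- do.call(rbind, per)
  names(out)[-(1:3)] <- labels
  totals <- colSums(out[, labels, drop = FALSE])
  attr(out, "totals") <- totals
  out
}

#' Per-gene length summary
#'
#' Gene length, CDS length, intron count and intron fraction
#' (1 - CDS/gene) per gene model, joined with genome sizes where supplied.
#'
#' @param models list of [gene_model()].
#' @param genome_sizes optional data.frame with columns `taxon` and
#'   `genome_size` (duplicate taxa are an error), or a named numeric vector.
#' @return data.frame, one row per model.
#' @export
length_summary <- function(models, genome_sizes = NULL) {
  if (!is.null(genome_sizes) && !is.data.frame(genome_sizes))
    genome_sizes <- data.frame(taxon = names(genome_sizes),
                               genome_size = as.numeric(genome_sizes))
  if (!is.null(genome_sizes) && anyDuplicated(genome_sizes$taxon))
    stop("duplicate taxon keys in genome-size table")
  df <- do.call(rbind, lapply(models, function(m) {
    glen <- nchar(m$gene_seq); clen <- nchar(m$cds_seq)
    data.frame(taxon = m$taxon, gene_id = m$gene_id,
               gene_length = glen, cds_length = clen,
               n_introns = nrow(m$introns),
               intron_fraction = 1 - clen / glen,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(genome_sizes)) {
    df$genome_size <- genome_sizes$genome_size[match(df$taxon,
                                                     genome_sizes$taxon)]
  }
  df
}
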