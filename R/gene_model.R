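#' Construct a gene model
#'
#' A `gene_model` is the package's normalized representation of one taxon's
#' copy of the gene: ordered exons and introns on the transcription strand,
#' with the spliced (CDS) and unspliced sequences attached. All coordinates
#' are 0-based half-open. `exons` are given in *gene-local* coordinates on
#' the normalized (transcription) strand, so exon 1 always starts the gene
#' regardless of genomic strand; introns are derived as the gaps between
#' consecutive exons.
#'
#' @param taxon taxon identifier.
#' @param gene_id gene identifier.
#' @param exons integer matrix (n x 2) of gene-local exon intervals in
#'   transcription order, 0-based half-open.
#' @param gene_seq unspliced gene sequence on the transcription strand.
#' @param scaffold scaffold identifier (optional).
#' @param span genomic interval `c(start, end)` of the gene on the scaffold,
#'   0-based half-open (optional).
#' @param strand `"+"` or `"-"`; the strand the gene was annotated on.
#' @param flank_seq scanned-frame sequence (gene plus flanks) on the
#'   transcription strand, used by the duplication scan; `NULL` to default
#'   to the gene sequence itself.
#' @param flank_offset 0-based position of the gene start within
#'   `flank_seq`.
#' @param transcripts optional named list of exon matrices (gene-local
#'   coordinates) for alternative transcripts; the constitutive model is
#'   not required to be among them.
#'
#' @return an object of class `gene_model` with derived fields `introns`
#'   (interval matrix) and `cds_seq` (spliced exon sequence).
#' @export
gene_model <- function(taxon, gene_id, exons, gene_seq,
                       scaffold = NA_character_, span = NULL,
                       strand = "+", flank_seq = NULL, flank_offset = 0L,
                       transcripts = NULL) {
  exons <- as_interval_matrix(exons)
  n <- nrow(exons)
  if (n < 1L) stop("gene model needs at least one exon")
  if (is.unsorted(exons[, 1L], strictly = TRUE) && n > 1L)
    stop("exons must be sorted in transcription order")
  if (n > 1L && any(exons[-1L, 1L] < exons[-n, 2L]))
    stop(sprintf("overlapping exons in gene '%s'", gene_id))
  if (exons[1L, 1L] != 0L || exons[n, 2L] != nchar(gene_seq))
    stop(sprintf("gene '%s': exons must span the gene sequence exactly", gene_id))
  introns <- if (n > 1L) {
    cbind(start = exons[-n, 2L], end = exons[-1L, 1L])
  } else {
    as_interval_matrix(NULL)
  }
  cds_seq <- paste(substring(gene_seq, exons[, 1L] + 1L, exons[, 2L]),
                   collapse = "")
  m <- structure(list(
    taxon = taxon, gene_id = gene_id, scaffold = scaffold,
    span = if (is.null(span)) c(0L, nchar(gene_seq)) else as.integer(span),
    strand = strand,
    exons = exons, introns = introns,
    cds_seq = cds_seq, gene_seq = gene_seq,
    flank_seq = flank_seq %||% gene_seq,
    flank_offset = as.integer(if (is.null(flank_seq)) 0L else flank_offset),
    transcripts = transcripts
  ), class = "gene_model")
  validate_gene_model(m)
  m
}

#' @noRd
validate_gene_model <- function(m) {
  stopifnot(nrow(m$introns) == nrow(m$exons) - 1L)
  if (sum(interval_widths(m$exons)) != nchar(m$cds_seq))
    stop("cds_seq length must equal total exon length")
  if (nchar(m$gene_seq) != m$span[2L] - m$span[1L])
    stop("gene_seq length must equal span length")
  glen <- nchar(m$gene_seq)
  off <- m$flank_offset
  if (off < 0L || off + glen > nchar(m$flank_seq))
    stop("flank_offset does not place the gene inside flank_seq")
  if (substring(m$flank_seq, off + 1L, off + glen) != m$gene_seq)
    stop("flank_seq does not contain gene_seq at flank_offset")
  invisible(m)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s / %s: %d bp, %d exons, %d introns (%s strand)\n",
              x$taxon, x$gene_id, nchar(x$gene_seq), nrow(x$exons),
              nrow(x$introns), x$strand))
  invisible(x)
}

#' Exon or intron sequences of a gene model
#'
#' @param model a [gene_model()].
#' @return character vector of sequences in transcription order.
#' @export
exon_seqs <- function(model) {
  substring(model$gene_seq, model$exons[, 1L] + 1L, model$exons[, 2L])
}

#' @rdname exon_seqs
#' @export
intron_seqs <- function(model) {
  if (nrow(model$introns) == 0L) return(character(0))
  substring(model$gene_seq, model$introns[, 1L] + 1L, model$introns[, 2L])
}

#' CDS offsets of intron positions
#'
#' Offset (in spliced CDS nucleotides) at which each intron interrupts the
#' coding sequence; intron i falls after `offset[i]` CDS nucleotides.
#'
#' @param model a [gene_model()].
#' @return integer vector, one entry per intron.
#' @export
intron_cds_offsets <- function(model) {
  w <- interval_widths(model$exons)
  if (length(w) < 2L) return(integer(0))
  cumsum(w)[-length(w)]
}
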