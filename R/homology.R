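# Homologizing intron positions across taxa: introns are projected into
# protein-alignment coordinates (codon index + phase) and clustered into
# sites, yielding the taxa x sites presence/absence matrix that feeds the
# parsimony reconstruction.

#' Star multiple alignment of proteins
#'
#' Deterministic star alignment: every sequence is globally aligned to the
#' longest sequence (BLOSUM62, gap open 10, gap extend 1) and the pairwise
#' alignments are merged under the once-a-gap-always-a-gap rule. Adequate
#' for well-conserved coding regions; supply a real MSA for divergent data
#' (any function accepting an MSA takes a named character vector of equal
#' lengths).
#'
#' @param proteins named character vector of >= 2 ungapped protein
#'   sequences.
#' @return named character vector of aligned rows (equal lengths), class
#'   `protein_msa`.
#' @export
align_proteins <- function(proteins) {
  if (length(proteins) < 2L) stop("need at least two sequences")
  if (any(!nzchar(proteins))) stop("empty protein sequence")
  if (is.null(names(proteins))) stop("proteins must be named")
  center_i <- which.max(nchar(proteins))
  center <- proteins[[center_i]]
  nc <- nchar(center)
  others <- proteins[-center_i]

  data("BLOSUM62", package = "Biostrings", envir = environment())
  alns <- lapply(others, function(s)
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(center), Biostrings::AAString(s),
      type = "global", substitutionMatrix = get("BLOSUM62"),
      gapOpening = 10, gapExtension = 1))

  # insertion counts relative to the center: slot j = gaps before center
  # residue j (slot nc + 1 = trailing)
  ins_of <- function(c_gapped) {
    chars <- strsplit(c_gapped, "", fixed = TRUE)[[1L]]
    ins <- integer(nc + 1L); j <- 1L
    for (ch in chars) {
      if (ch == "-") ins[j] <- ins[j] + 1L else j <- j + 1L
    }
    ins
  }
  c_gapped <- vapply(alns, function(a)
    as.character(Biostrings::alignedPattern(a)), character(1))
  s_gapped <- vapply(alns, function(a)
    as.character(Biostrings::alignedSubject(a)), character(1))
  ins_all <- lapply(c_gapped, ins_of)
  master <- Reduce(pmax, ins_all, integer(nc + 1L))

  merge_row <- function(cg, sg) {
    cc <- strsplit(cg, "", fixed = TRUE)[[1L]]
    sc <- strsplit(sg, "", fixed = TRUE)[[1L]]
    out <- character(0); buf <- character(0); j <- 1L
    flush <- function(buf, slot) c(buf, rep("-", master[slot] - length(buf)))
    for (k in seq_along(cc)) {
      if (cc[k] == "-") {
        buf <- c(buf, sc[k])
      } else {
        out <- c(out, flush(buf, j), sc[k]); buf <- character(0); j <- j + 1L
      }
    }
    out <- c(out, flush(buf, nc + 1L))
    paste(out, collapse = "")
  }
  rows <- mapply(merge_row, c_gapped, s_gapped)
  center_row <- merge_row(center, center)
  msa <- c(stats::setNames(center_row, names(proteins)[center_i]), rows)
  msa <- msa[names(proteins)]
  class(msa) <- "protein_msa"
  msa
}

#' @noRd
check_msa <- function(msa) {
  if (length(unique(nchar(msa))) != 1L)
    stop("MSA rows have unequal (ragged) lengths")
  invisible(msa)
}

#' Project intron positions into alignment coordinates
#'
#' Each intron of a gene model is assigned its codon index
#' (`floor(cds_offset / 3)`, 0-based) and phase (`cds_offset mod 3`), then
#' the codon index is mapped through the taxon's gap pattern to a 0-based
#' alignment column. The model's translated CDS must equal the taxon's MSA
#' row with gaps removed. An intron interrupting the terminal stop codon is
#' mapped to the last residue column.
#'
#' @param model a [gene_model()].
#' @param msa named character vector of aligned proteins (names = taxa).
#' @return data.frame with `taxon`, `gene_id`, `intron_index`,
#'   `codon_index`, `phase`, `alignment_column`.
#' @export
map_introns_to_alignment <- function(model, msa) {
  check_msa(msa)
  key <- if (model$taxon %in% names(msa)) model$taxon else model$gene_id
  if (!key %in% names(msa))
    stop(sprintf("taxon '%s' not found in MSA", model$taxon))
  row <- msa[[key]]
  prot <- translate_cds(model$cds_seq)
  if (gsub("-", "", row, fixed = TRUE) != prot)
    stop(sprintf("CDS of taxon '%s' does not translate to its MSA row",
                 model$taxon))
  offs <- intron_cds_offsets(model)
  if (length(offs) == 0L) {
    return(data.frame(taxon = character(0), gene_id = character(0),
                      intron_index = integer(0), codon_index = integer(0),
                      phase = integer(0), alignment_column = integer(0)))
  }
  codon <- offs %/% 3L
  phase <- offs %% 3L
  cols0 <- which(strsplit(row, "", fixed = TRUE)[[1L]] != "-") - 1L
  plen <- length(cols0)
  codon_mapped <- pmin(codon, plen - 1L)
  data.frame(taxon = model$taxon, gene_id = model$gene_id,
             intron_index = seq_along(offs),
             codon_index = codon, phase = phase,
             alignment_column = cols0[codon_mapped + 1L],
             stringsAsFactors = FALSE)
}

#' Cluster intron positions into homologous sites
#'
#' Single-linkage clustering of intron positions sharing a phase (when
#' `phase_strict`) with alignment columns within `column_tolerance` of each
#' other. Each cluster is one homologous site; sites are ordered by
#' alignment column. Two introns of one gene falling in one cluster signal
#' an over-loose tolerance and raise an error.
#'
#' @param positions data.frame as returned by
#'   [map_introns_to_alignment()], row-bound over >= 2 taxa.
#' @param column_tolerance non-negative integer; maximum column gap joined
#'   by single linkage (0 = identical columns only).
#' @param phase_strict if `TRUE` (default) positions of different phase are
#'   never merged.
#' @return binary matrix taxa x sites with `attr(, "site_info")` giving per
#'   site label, representative alignment column and phase.
#' @export
build_presence_matrix <- function(positions, column_tolerance = 0,
                                  phase_strict = TRUE) {
  if (length(unique(positions$taxon)) < 2L)
    stop("need intron positions from at least two taxa")
  key <- if (phase_strict) positions$phase else rep(0L, nrow(positions))
  positions$cluster <- NA_integer_
  cl_id <- 0L
  info <- list()
  for (ph in sort(unique(key))) {
    sel <- which(key == ph)
    ord <- sel[order(positions$alignment_column[sel])]
    cols <- positions$alignment_column[ord]
    newc <- c(TRUE, diff(cols) > column_tolerance)
    ids <- cl_id + cumsum(newc)
    positions$cluster[ord] <- ids
    cl_id <- max(ids)
    for (ci in unique(ids)) {
      rows <- ord[ids == ci]
      info[[ci]] <- data.frame(
        cluster = ci, column = min(positions$alignment_column[rows]),
        phase = as.integer(names(which.max(table(positions$phase[rows])))))
    }
  }
  info <- do.call(rbind, info)

  dup <- stats::aggregate(intron_index ~ taxon + gene_id + cluster,
                          data = positions, FUN = length)
  bad <- dup[dup$intron_index > 1L, , drop = FALSE]
  if (nrow(bad) > 0L)
    stop("ambiguous clustering (tolerance too loose): multiple introns of ",
         paste(unique(bad$taxon), collapse = ", "),
         " fall in one site cluster")

  info <- info[order(info$column, info$phase), , drop = FALSE]
  info$label <- as.character(seq_len(nrow(info)))
  taxa <- unique(positions$taxon)
  mat <- matrix(0L, nrow = length(taxa), ncol = nrow(info),
                dimnames = list(taxa, info$label))
  for (r in seq_len(nrow(positions))) {
    j <- match(positions$cluster[r], info$cluster)
    mat[positions$taxon[r], j] <- 1L
  }
  rownames(info) <- NULL
  attr(mat, "site_info") <- info[, c("label", "column", "phase")]
  attr(mat, "positions") <- positions
  mat
}

#' Relabel sites against a reference complement
#'
#' Sites present in the reference keep sequential numbers 1..k in column
#' order; a site absent from the reference is a novel site and is labeled
#' with the number of the nearest preceding reference site plus a prime
#' (e.g. `21'`; further novel sites after the same reference site append
#' additional primes).
#'
#' @param mat presence matrix from [build_presence_matrix()].
#' @param reference either a taxon name (row of `mat`) or a logical/0-1
#'   vector over sites (e.g. the root states of a reconstruction).
#' @return `mat` with updated column names and `site_info` labels.
#' @export
label_intron_sites <- function(mat, reference) {
  if (is.character(reference) && length(reference) == 1L) {
    if (!reference %in% rownames(mat))
      stop(sprintf("reference taxon '%s' not in matrix", reference))
    ref <- mat[reference, ] == 1
  } else {
    if (length(reference) != ncol(mat))
      stop("reference vector length must equal number of sites")
    ref <- as.logical(reference)
  }
  labels <- character(ncol(mat))
  num <- 0L; primes <- 0L
  for (j in seq_len(ncol(mat))) {
    if (ref[j]) {
      num <- num + 1L; primes <- 0L
      labels[j] <- as.character(num)
    } else {
      primes <- primes + 1L
      labels[j] <- paste0(num, strrep("'", primes))
    }
  }
  colnames(mat) <- labels
  si <- attr(mat, "site_info")
  if (!is.null(si)) { si$label <- labels; attr(mat, "site_info") <- si }
  mat
}
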