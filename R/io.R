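#' Parse gene models from GFF3 + FASTA
#'
#' Reads a GFF3 annotation (gene/mRNA/exon or CDS features) together with the
#' genome FASTA slice it refers to and assembles normalized [gene_model()]
#' objects. GFF3 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention, and minus-strand genes are
#' reverse-complemented so that exon 1 is always the first transcribed exon.
#' When both CDS and exon features are present, CDS features define the
#' model. For multi-transcript genes the longest transcript (by summed exon
#' length) becomes the constitutive model; all transcripts are retained in
#' `$transcripts` for isoform analysis.
#'
#' @param path GFF3 file.
#' @param fasta_path FASTA file containing every scaffold referenced.
#' @param taxon taxon identifier to stamp on the models; defaults to the
#'   GFF3 file base name.
#' @return list of [gene_model()] objects.
#' @export
parse_gff3 <- function(path, fasta_path, taxon = NULL) {
  taxon <- taxon %||% sub("\\.gff3?$", "", basename(path))
  gr <- rtracklayer::import(path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*", "", names(genome))

  type <- as.character(gr$type)
  first_parent <- function(x) vapply(x, function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  parent <- if (!is.null(gr$Parent)) first_parent(gr$Parent) else
    rep(NA_character_, length(gr))
  id <- if (!is.null(gr$ID)) gr$ID else rep(NA_character_, length(gr))

  genes <- which(type == "gene")
  models <- list()
  for (gi in genes) {
    gene_id <- id[gi]
    scaffold <- as.character(GenomicRanges::seqnames(gr)[gi])
    if (!scaffold %in% names(genome))
      stop(sprintf("scaffold '%s' referenced by gene '%s' missing from FASTA",
                   scaffold, gene_id))
    strand <- as.character(GenomicRanges::strand(gr)[gi])
    if (!strand %in% c("+", "-")) strand <- "+"

    tx_idx <- which(type %in% c("mRNA", "transcript") & parent == gene_id)
    tx_ids <- id[tx_idx]
    if (length(tx_idx) == 0L) {  # exons attached directly to the gene
      tx_ids <- gene_id
    }
    tx_exons <- lapply(tx_ids, function(tid) {
      kids <- which(parent == tid & type %in% c("CDS", "exon"))
      use_type <- if (any(type[kids] == "CDS")) "CDS" else "exon"
      kids <- kids[type[kids] == use_type]
      if (length(kids) == 0L) return(NULL)
      iv <- cbind(start = GenomicRanges::start(gr)[kids] - 1L,
                  end = GenomicRanges::end(gr)[kids])
      iv <- iv[order(iv[, 1L]), , drop = FALSE]
      if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
        stop(sprintf("overlapping exons in transcript '%s'", tid))
      iv
    })
    names(tx_exons) <- tx_ids
    tx_exons <- Filter(Negate(is.null), tx_exons)
    if (length(tx_exons) == 0L) next

    lens <- vapply(tx_exons, function(m) sum(interval_widths(m)), numeric(1))
    main <- tx_exons[[which.max(lens)]]
    gstart <- min(main[, 1L]); gend <- max(main[, 2L])
    scafseq <- as.character(genome[[scaffold]])
    scaflen <- nchar(scafseq)

    to_local <- function(iv) {
      if (strand == "+") {
        loc <- cbind(iv[, 1L] - gstart, iv[, 2L] - gstart)
      } else {
        loc <- cbind(gend - iv[, 2L], gend - iv[, 1L])
        loc <- loc[rev(seq_len(nrow(loc))), , drop = FALSE]
      }
      as_interval_matrix(loc)
    }

    gseq <- substring(scafseq, gstart + 1L, gend)
    if (strand == "-") gseq <- revcomp(gseq)
    frame <- if (strand == "+") scafseq else revcomp(scafseq)
    frame_off <- if (strand == "+") gstart else scaflen - gend

    models[[length(models) + 1L]] <- gene_model(
      taxon = taxon, gene_id = gene_id, exons = to_local(main),
      gene_seq = gseq, scaffold = scaffold, span = c(gstart, gend),
      strand = strand, flank_seq = frame, flank_offset = frame_off,
      transcripts = lapply(tx_exons, to_local))
  }
  models
}

#' Write gene models back to GFF3
#'
#' Inverse of [parse_gff3()]: emits gene/mRNA/exon/CDS features with 1-based
#' inclusive coordinates on the original strand.
#'
#' @param models list of [gene_model()].
#' @param path output GFF3 path.
#' @export
write_gene_gff3 <- function(models, path) {
  rows <- list()
  for (m in models) {
    gstart <- m$span[1L]; gend <- m$span[2L]
    to_genomic <- function(iv) {
      if (m$strand == "+") cbind(gstart + iv[, 1L], gstart + iv[, 2L])
      else cbind(gend - iv[, 2L], gend - iv[, 1L])
    }
    add <- function(type, s, e, id = NA, parent = NA) {
      attrs <- character(0)
      if (!is.na(id)) attrs <- c(attrs, sprintf("ID=%s", id))
      if (!is.na(parent)) attrs <- c(attrs, sprintf("Parent=%s", parent))
      rows[[length(rows) + 1L]] <<- sprintf(
        "%s\tintronarch\t%s\t%d\t%d\t.\t%s\t.\t%s",
        m$scaffold, type, s + 1L, e, m$strand, paste(attrs, collapse = ";"))
    }
    add("gene", gstart, gend, id = m$gene_id)
    txs <- m$transcripts %||%
      stats::setNames(list(m$exons), paste0(m$gene_id, ".t1"))
    for (tid in names(txs)) {
      ge <- to_genomic(txs[[tid]])
      ge <- ge[order(ge[, 1L]), , drop = FALSE]
      add("mRNA", min(ge[, 1L]), max(ge[, 2L]), id = tid, parent = m$gene_id)
      for (k in seq_len(nrow(ge))) add("CDS", ge[k, 1L], ge[k, 2L], parent = tid)
    }
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Parse a rooted Newick species tree
#'
#' Reads a single rooted, bifurcating Newick tree. Unlabeled internal nodes
#' receive deterministic labels (`N` + postorder index) so that event
#' reports are reproducible.
#'
#' @param path Newick file path, or a Newick string.
#' @return an [ape::read.tree()] `phylo` object with complete node labels.
#' @export
parse_newick <- function(path) {
  tree <- if (grepl("\\(", path)) ape::read.tree(text = path)
          else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree")
  if (inherits(tree, "multiPhylo")) stop("expected a single tree")
  root_children <- sum(tree$edge[, 1L] == ape::Ntip(tree) + 1L)
  if (root_children > 2L)
    stop("tree root is a trifurcation: the species tree must be rooted; ",
         "root it (e.g. with an outgroup) and retry")
  ensure_node_labels(tree)
}

#' @noRd
ensure_node_labels <- function(tree) {
  n_int <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_int)
  need <- !nzchar(lab) | is.na(lab)
  if (any(need)) {
    po <- ape::reorder.phylo(tree, "postorder")
    order_int <- unique(po$edge[, 1L])       # parents in postorder completion
    postorder_rank <- match(seq_len(n_int) + ape::Ntip(tree), order_int)
    lab[need] <- sprintf("N%02d", postorder_rank[need])
  }
  tree$node.label <- lab
  tree
}

#' Parse RepeatMasker .out annotations
#'
#' Reads the standard RepeatMasker `.out` layout (three header lines, then
#' whitespace-separated records) and maps the repeat class/family column to
#' the four-way TE class vocabulary: LTR/LINE/SINE to `retrotransposon`,
#' DNA to `DNA_transposon`, RC/Helitron to `helitron`, anything else to
#' `unclassified`. Malformed records are skipped with a counted warning.
#'
#' @param path `.out` file path.
#' @return data.frame with columns `target`, `start`, `end` (0-based
#'   half-open), `strand`, `name`, `class_family`, `te_class`,
#'   `superfamily`, `divergence`.
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) >= 1L && grepl("^\\s*SW", lines[1L]))
    lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  out <- list(); bad <- 0L
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 13L || is.na(suppressWarnings(as.integer(f[6L]))) ||
        is.na(suppressWarnings(as.integer(f[7L])))) {
      bad <- bad + 1L
      next
    }
    cf <- f[11L]
    out[[length(out) + 1L]] <- data.frame(
      target = f[5L],
      start = as.integer(f[6L]) - 1L, end = as.integer(f[7L]),
      strand = if (f[9L] %in% c("C", "-")) "-" else "+",
      name = f[10L], class_family = cf,
      te_class = te_class_of(cf), superfamily = te_superfamily_of(cf),
      divergence = suppressWarnings(as.numeric(f[2L])),
      stringsAsFactors = FALSE)
  }
  if (bad > 0L)
    warning(sprintf("skipped %d malformed RepeatMasker record(s)", bad))
  if (length(out) == 0L) {
    return(data.frame(target = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      name = character(0), class_family = character(0),
                      te_class = character(0), superfamily = character(0),
                      divergence = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' @noRd
te_class_of <- function(class_family) {
  top <- sub("/.*", "", class_family)
  ifelse(top %in% c("LTR", "LINE", "SINE", "Retroposon"), "retrotransposon",
  ifelse(top == "DNA", "DNA_transposon",
  ifelse(top == "RC" | grepl("Helitron", class_family, ignore.case = TRUE),
         "helitron", "unclassified")))
}

#' @noRd
te_superfamily_of <- function(class_family) {
  ifelse(grepl("/", class_family), sub(".*/", "", class_family), NA_character_)
}

#' Write pipeline report tables
#'
#' Writes every result component present to TSV (percent columns rendered
#' with two decimals) plus a JSON run manifest. Missing components are
#' silently skipped; an empty table yields a header-only TSV.
#'
#' @param results named list of pipeline results (see [run_pipeline()]).
#' @param out_dir output directory, created if needed.
#' @return invisible character vector of files written.
#' @export
write_report_tables <- function(results, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", out_dir))
  written <- character(0)
  put_tsv <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  render_pct <- function(df) {
    for (cl in grep("percent|fraction_pct", names(df), value = TRUE))
      df[[cl]] <- fmt_pct(df[[cl]])
    df
  }
  if (!is.null(results$per_gene_metrics))
    put_tsv(results$per_gene_metrics, "per_gene_metrics.tsv")
  if (!is.null(results$splice_census)) {
    put_tsv(results$splice_census$records, "splice_sites.tsv")
    put_tsv(render_pct(results$splice_census$summary), "splice_census.tsv")
  }
  if (!is.null(results$intron_bins)) put_tsv(results$intron_bins, "intron_bins.tsv")
  if (!is.null(results$presence_matrix)) {
    m <- results$presence_matrix
    df <- data.frame(taxon = rownames(m), as.data.frame(m),
                     check.names = FALSE)
    put_tsv(df, "presence_matrix.tsv")
  }
  if (!is.null(results$history)) {
    put_tsv(results$history$events, "branch_events.tsv")
    p <- file.path(out_dir, "tree_intron_counts.nwk")
    writeLines(annotated_newick(results$history), p)
    written <- c(written, p)
  }
  if (!is.null(results$duplications)) {
    put_tsv(results$duplications, "duplication_blocks.tsv")
    put_tsv(duplication_bed(results$duplications), "duplication_blocks.bed")
  }
  if (!is.null(results$te_profiles))
    put_tsv(render_pct(results$te_profiles), "te_profiles.tsv")
  if (!is.null(results$te_correlations))
    put_tsv(results$te_correlations, "te_correlations.tsv")
  if (!is.null(results$as_events)) put_tsv(results$as_events, "as_events.tsv")
  if (!is.null(results$uorfs)) put_tsv(results$uorfs, "uorfs.tsv")
  if (!is.null(results$manifest)) {
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(results$manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, p)
  }
  invisible(written)
}

#' @noRd
duplication_bed <- function(blocks) {
  if (nrow(blocks) == 0L) {
    return(data.frame(chrom = character(0), chromStart = integer(0),
                      chromEnd = integer(0), name = character(0)))
  }
  data.frame(chrom = paste(blocks$taxon, blocks$gene_id, sep = ":"),
             chromStart = blocks$start, chromEnd = blocks$end,
             name = sprintf("exon%d-%d:%s", blocks$exon_from, blocks$exon_to,
                            blocks$location))
}
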