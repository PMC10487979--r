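# Emission of simulator output in the pipeline's input formats, plus the
# matching readers for the non-GFF3 pieces.

#' Emit simulated family files
#'
#' Writes, per taxon, a genome-slice FASTA (gene + flanks as one scaffold)
#' and a GFF3 annotation; family-wide protein FASTA, true protein MSA,
#' Newick tree and a JSON ground-truth log; a RepeatMasker-style `.out`
#' per taxon with TE insertions; and a multi-transcript GTF for isoform
#' taxa. Deterministic: equal seeds yield byte-identical files.
#'
#' @param models,truth output of [simulate_family()].
#' @param out_dir output directory (created if needed).
#' @return invisible named list of written paths.
#' @export
emit_files <- function(models, truth, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", out_dir))
  paths <- list(fasta = character(0), gff3 = character(0),
                rmout = character(0), gtf = character(0))
  for (taxon in names(models)) {
    m <- models[[taxon]]
    fa <- file.path(out_dir, paste0(taxon, ".fasta"))
    seqs <- Biostrings::DNAStringSet(stats::setNames(m$flank_seq, m$scaffold))
    Biostrings::writeXStringSet(seqs, fa)
    gff <- file.path(out_dir, paste0(taxon, ".gff3"))
    write_gene_gff3(list(m), gff)
    paths$fasta[taxon] <- fa; paths$gff3[taxon] <- gff

    reg <- truth$te_registry[[taxon]]
    if (!is.null(reg) && nrow(reg) > 0L) {
      rm_path <- file.path(out_dir, paste0(taxon, ".te.out"))
      write_repeatmasker_out(reg, m, rm_path)
      paths$rmout[taxon] <- rm_path
    }
    if (!is.null(m$transcripts) && length(m$transcripts) > 1L) {
      gtf <- file.path(out_dir, paste0(taxon, ".transcripts.gtf"))
      write_transcripts_gtf(m, gtf)
      paths$gtf[taxon] <- gtf
    }
  }
  prots <- Biostrings::AAStringSet(truth$msa)
  paths$proteins <- file.path(out_dir, "proteins.faa")
  Biostrings::writeXStringSet(prots, paths$proteins)
  paths$msa <- file.path(out_dir, "msa.faa")
  Biostrings::writeXStringSet(prots, paths$msa)
  paths$tree <- file.path(out_dir, "tree.nwk")
  ape::write.tree(truth$tree, paths$tree)
  paths$truth <- file.path(out_dir, "truth.json")
  tr <- truth
  tr$tree <- ape::write.tree(tr$tree)
  tr$config <- Filter(function(x) is.numeric(x) || is.character(x),
                      unclass(tr$config))
  tr$matrix <- list(taxa = rownames(truth$matrix),
                    sites = colnames(truth$matrix),
                    presence = unname(truth$matrix))
  jsonlite::write_json(tr, paths$truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' @noRd
write_repeatmasker_out <- function(reg, model, path) {
  hdr <- c(
    "   SW   perc perc perc  query                begin    end          (left)   repeat               class/family      begin   end    (left)     ID",
    "score   div. del. ins.  sequence                                            ",
    "")
  off <- model$flank_offset
  recs <- vapply(seq_len(nrow(reg)), function(i) {
    r <- reg[i, ]
    sprintf("%5d %6.1f  0.0  0.0  %-18s %7d %7d (%d) + %-18s %-16s %6d %6d (0) %5d",
            1000L, r$divergence, model$scaffold,
            off + r$start + 1L, off + r$end,
            nchar(model$flank_seq) - (off + r$end),
            r$name, r$class_family, 1L, r$end - r$start, i)
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' @noRd
write_transcripts_gtf <- function(model, path) {
  off <- model$flank_offset
  lines <- character(0)
  for (tid in names(model$transcripts)) {
    ex <- model$transcripts[[tid]]
    for (k in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\tintronarch\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        model$scaffold, off + ex[k, 1L] + 1L, off + ex[k, 2L],
        model$strand, model$gene_id, tid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-transcript GTF into exon chains
#'
#' @param path GTF file with exon features carrying `transcript_id`.
#' @return list per gene: `transcripts` (named list of 0-based half-open
#'   exon matrices on the genomic frame) and `strand`.
#' @export
parse_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) == "exon"]
  out <- list()
  for (gid in unique(gr$gene_id)) {
    sub <- gr[gr$gene_id == gid]
    strands <- unique(as.character(GenomicRanges::strand(sub)))
    if (length(strands) > 1L)
      stop(sprintf("transcripts of gene '%s' on different strands", gid))
    txs <- lapply(split(sub, sub$transcript_id), function(t) {
      iv <- cbind(GenomicRanges::start(t) - 1L, GenomicRanges::end(t))
      as_interval_matrix(iv[order(iv[, 1L]), , drop = FALSE])
    })
    out[[gid]] <- list(transcripts = txs, strand = strands)
  }
  out
}

#' Read a genome-size table
#'
#' @param path TSV with columns `taxon` and `genome_size`.
#' @return data.frame.
#' @export
read_genome_sizes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("taxon", "genome_size") %in% names(df)))
    stop("genome-size table needs columns 'taxon' and 'genome_size'")
  if (anyDuplicated(df$taxon)) stop("duplicate taxon keys in genome-size table")
  df
}
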