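# End-to-end orchestration: metrics -> homology -> parsimony ->
# duplication scan -> TE content -> isoforms -> report, with a JSON run
# manifest. Stages lacking inputs are skipped with a notice.

#' Run the full analysis pipeline
#'
#' @param config a named list (or path to a YAML/JSON file) with:
#'   \describe{
#'     \item{gff, fasta}{named character vectors of per-taxon GFF3 and
#'       FASTA paths (names = taxa).}
#'     \item{tree}{rooted Newick path or string.}
#'     \item{msa}{optional aligned protein FASTA; built by
#'       [align_proteins()] when absent.}
#'     \item{rmout}{optional named vector of RepeatMasker `.out` paths.}
#'     \item{transcripts}{optional named vector of multi-transcript GTFs.}
#'     \item{genome_sizes}{optional genome-size TSV path.}
#'     \item{out_dir}{output directory for report tables.}
#'     \item{seed}{integer seed recorded in the manifest.}
#'     \item{dup_scan}{optional list of [scan_duplications()] overrides
#'       (`k`, `min_identity`, `min_coverage`, `max_gap`).}
#'     \item{intron_bin_edges}{bin edges for [intron_length_bins()].}
#'   }
#' @return invisible list of results (per-gene metrics, census, presence
#'   matrix, event history, duplication blocks, TE profiles and
#'   correlations, AS events, uORFs, manifest); tables are also written to
#'   `out_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
              else read_yaml_config(config)
  }
  warnings_log <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[intronarch] ", msg)
    warnings_log <<- c(warnings_log, msg)
  }
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log,
                         paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  results <- list()

  # --- models -------------------------------------------------------------
  if (is.null(config$gff) || is.null(config$fasta))
    stop("config must name per-taxon 'gff' and 'fasta' inputs")
  taxa <- names(config$gff) %||% sub("\\.gff3?$", "", basename(config$gff))
  models <- stage("models", {
    out <- list()
    for (i in seq_along(config$gff)) {
      ms <- parse_gff3(config$gff[[i]], config$fasta[[i]], taxon = taxa[i])
      out <- c(out, ms)
    }
    out
  })
  names(models) <- vapply(models, `[[`, character(1), "taxon")

  genome_sizes <- if (!is.null(config$genome_sizes))
    read_genome_sizes(config$genome_sizes) else NULL

  # --- metrics ------------------------------------------------------------
  results$per_gene_metrics <- stage("metrics", {
    ls <- length_summary(models, genome_sizes)
    gc <- do.call(rbind, lapply(models, function(m) {
      p <- gc_profile(m)
      data.frame(gc_gene = p$gc_gene, gc_cds = p$gc_cds,
                 gc1 = p$gc1, gc2 = p$gc2, gc3 = p$gc3)
    }))
    cbind(ls, gc)
  })
  results$splice_census <- stage("census", splice_site_census(models))
  results$intron_bins <- stage("intron_bins",
    intron_length_bins(models,
                       edges = config$intron_bin_edges %||% c(5000, 10000)))

  # --- homology + parsimony ----------------------------------------------
  tree <- if (!is.null(config$tree)) stage("tree", parse_newick(config$tree))
          else NULL
  if (length(models) >= 2L) {
    results$presence_matrix <- stage("homology", {
      msa <- if (!is.null(config$msa)) {
        aln <- Biostrings::readAAStringSet(config$msa)
        stats::setNames(as.character(aln), names(aln))
      } else {
        prots <- vapply(models, function(m) translate_cds(m$cds_seq),
                        character(1))
        align_proteins(prots)
      }
      pos <- do.call(rbind, lapply(models, map_introns_to_alignment,
                                   msa = msa))
      build_presence_matrix(pos,
        column_tolerance = config$column_tolerance %||% 0)
    })
    if (!is.null(tree)) {
      ph <- stage("parsimony", {
        h <- dollo_reconstruct(results$presence_matrix, tree)
        # prime-style labels against the root's reconstructed complement
        root_lab <- rownames(h$node_states)[ape::Ntip(tree) + 1L]
        mat <- label_intron_sites(results$presence_matrix,
                                  h$node_states[root_lab, ] == 1)
        list(matrix = mat, history = dollo_reconstruct(mat, tree))
      })
      results$presence_matrix <- ph$matrix
      results$history <- ph$history
    } else {
      note("no tree supplied: parsimony stage skipped")
    }
  } else {
    note("fewer than two models: homology and parsimony stages skipped")
  }

  # --- duplication scan ---------------------------------------------------
  results$duplications <- stage("dupscan", {
    ds <- config$dup_scan %||% list()
    do.call(rbind, lapply(models, function(m)
      scan_duplications(m, k = ds$k %||% 11L,
                        min_identity = ds$min_identity %||% 0.70,
                        min_coverage = ds$min_coverage %||% 0.50,
                        min_score = ds$min_score %||% 30,
                        max_gap = ds$max_gap %||% 20000L)))
  })

  # --- TE content ---------------------------------------------------------
  if (!is.null(config$rmout) && length(config$rmout) > 0L) {
    results$te_profiles <- stage("te", {
      anns <- lapply(config$rmout, parse_repeatmasker_out)
      te_profile_table(models[names(models) %in% names(anns) |
                                rep(is.null(names(anns)), length(models))],
                       anns)
    })
    results$te_correlations <- stage("te_correlations",
      correlation_report(results$te_profiles, genome_sizes))
  } else {
    note("no RepeatMasker .out inputs: TE stage skipped")
  }

  # --- isoforms -----------------------------------------------------------
  iso_sets <- list()
  if (!is.null(config$transcripts)) {
    for (tx in config$transcripts) {
      parsed <- stage("isoforms", parse_transcripts_gtf(tx))
      iso_sets <- c(iso_sets, parsed)
    }
  }
  for (m in models) {
    if (!is.null(m$transcripts) && length(m$transcripts) > 1L)
      iso_sets[[m$gene_id]] <- list(transcripts = m$transcripts,
                                    strand = m$strand)
  }
  if (length(iso_sets) > 0L) {
    results$as_events <- stage("as_events", {
      do.call(rbind, lapply(names(iso_sets), function(gid) {
        ev <- classify_as_events(iso_sets[[gid]]$transcripts,
                                 strand = iso_sets[[gid]]$strand)
        if (nrow(ev)) cbind(data.frame(gene_id = gid), ev) else NULL
      }))
    })
  } else {
    note("no multi-transcript inputs: isoform stage skipped")
  }

  # --- manifest + report --------------------------------------------------
  inputs <- unlist(config[c("gff", "fasta", "tree", "msa", "rmout",
                            "transcripts", "genome_sizes")], use.names = TRUE)
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  results$manifest <- list(
    tool = "intronarch",
    version = as.character(utils::packageVersion("intronarch")),
    seed = config$seed %||% NA,
    config = config[setdiff(names(config), c("out_dir"))],
    input_digests = as.list(tools::md5sum(inputs)),
    record_counts = list(
      models = length(models),
      splice_sites = nrow(results$splice_census$records %||% data.frame()),
      sites = ncol(results$presence_matrix %||% matrix(nrow = 0, ncol = 0)),
      events = nrow(results$history$events %||% data.frame()),
      duplication_blocks = nrow(results$duplications %||% data.frame()),
      te_profiles = nrow(results$te_profiles %||% data.frame()),
      as_events = nrow(results$as_events %||% data.frame())),
    warnings = warnings_log)

  if (!is.null(config$out_dir))
    write_report_tables(results, config$out_dir)
  invisible(results)
}

#' @noRd
read_yaml_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading a YAML config requires the 'yaml' package; ",
         "pass a list or a JSON config instead")
  yaml::read_yaml(path)
}

#' Build a pipeline config from a simulator output directory
#'
#' Convenience for running the pipeline end-to-end on [emit_files()]
#' output.
#'
#' @param dir directory written by [emit_files()].
#' @param out_dir optional report directory.
#' @param seed seed recorded in the manifest.
#' @return config list for [run_pipeline()].
#' @export
pipeline_config_from_sim <- function(dir, out_dir = NULL, seed = 1L) {
  taxa <- sub("\\.gff3$", "", basename(Sys.glob(file.path(dir, "*.gff3"))))
  cfg <- list(
    gff = stats::setNames(file.path(dir, paste0(taxa, ".gff3")), taxa),
    fasta = stats::setNames(file.path(dir, paste0(taxa, ".fasta")), taxa),
    tree = file.path(dir, "tree.nwk"),
    msa = file.path(dir, "msa.faa"),
    seed = seed, out_dir = out_dir)
  rms <- Sys.glob(file.path(dir, "*.te.out"))
  if (length(rms))
    cfg$rmout <- stats::setNames(rms, sub("\\.te\\.out$", "", basename(rms)))
  gtfs <- Sys.glob(file.path(dir, "*.transcripts.gtf"))
  if (length(gtfs))
    cfg$transcripts <- stats::setNames(
      gtfs, sub("\\.transcripts\\.gtf$", "", basename(gtfs)))
  cfg
}
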