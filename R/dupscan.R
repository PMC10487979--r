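# Detection of partial gene duplications: every exon is searched against
# the gene and its flanking sequence by exact k-mer seeding followed by
# local-alignment refinement of the seeded windows; colinear exon hits are
# chained into duplication blocks and located relative to the gene.

#' Seeded local alignment search of a query in a subject
#'
#' Exact k-mer seeds are collected (both strands), merged into candidate
#' windows, and each window is refined by Smith-Waterman local alignment
#' (match +2, mismatch -3, gap open -5, gap extend -2; the first gap
#' character costs open + extend). Hits passing the identity and coverage
#' thresholds are returned; hits overlapping `exclude` (the query's own
#' location) are removed.
#'
#' @param query nucleotide string (e.g. one exon).
#' @param subject nucleotide string to scan (gene + flanks).
#' @param k seed length; a query shorter than `k` yields a warning and no
#'   hits.
#' @param min_identity,min_coverage hit filters in `[0, 1]`: identity over
#'   aligned columns (gaps count as mismatch), coverage = fraction of the
#'   query aligned.
#' @param min_score minimum alignment score. The default 30 is the
#'   smallest score whose chance expectation (Karlin-Altschul, match +2 /
#'   mismatch -3) stays below 0.01 on a megabase-scale frame; it admits
#'   any full match of a >= 16 nt exon while rejecting chance seed
#'   extensions.
#' @param exclude optional `c(start, end)` 0-based half-open interval of
#'   the subject to mask (self-location).
#' @param index optional prebuilt [kmer_index()] of the subject (reused
#'   across the per-exon queries of one scan).
#' @return data.frame with `start`, `end` (0-based half-open subject
#'   coordinates), `strand`, `identity`, `coverage`, `score`.
#' @export
seeded_local_search <- function(query, subject, k = 11L,
                                min_identity = 0.70, min_coverage = 0.50,
                                min_score = 30, exclude = NULL,
                                index = NULL) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0),
                      coverage = numeric(0), score = numeric(0))
  qlen <- nchar(query)
  if (qlen < k) {
    warning(sprintf("query (%d nt) shorter than seed length k=%d; skipped",
                    qlen, k))
    return(empty)
  }
  subj <- Biostrings::DNAString(subject)
  if (is.null(index)) index <- kmer_index(subject, k)
  if (k != index$k) stop("seed length does not match the supplied index")
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") toupper(query) else revcomp(query)
    seeds <- kmer_lookup(index, q)
    if (nrow(seeds) == 0L) next
    spos <- seeds$spos; qpos <- seeds$qpos
    windows <- seed_windows(qpos, spos, qlen, k, nchar(subject))
    for (w in seq_len(nrow(windows))) {
      ws <- windows[w, 1L]; we <- windows[w, 2L]
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q),
        Biostrings::subseq(subj, ws, we),
        type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 2, mismatch = -3, baseOnly = FALSE),
        gapOpening = 5, gapExtension = 2)
      pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
      sa <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
      if (length(pa) == 0L) next
      identity <- sum(pa == sa) / length(pa)
      coverage <- sum(pa != "-") / qlen
      if (identity < min_identity || coverage < min_coverage ||
          Biostrings::score(aln) < min_score) next
      h_start <- ws - 1L + IRanges::start(Biostrings::subject(aln)@range) - 1L
      h_end <- ws - 1L + IRanges::end(Biostrings::subject(aln)@range)
      hits[[length(hits) + 1L]] <- data.frame(
        start = h_start, end = h_end, strand = strand,
        identity = identity, coverage = coverage,
        score = Biostrings::score(aln), stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  if (!is.null(exclude)) {
    out <- out[out$end <= exclude[1L] | out$start >= exclude[2L], ,
               drop = FALSE]
  }
  dedupe_hits(out)
}

#' Exact k-mer index of a subject sequence
#'
#' 2-bit rolling encoding of every k-mer of the subject, grouped by code:
#' one lookup table shared by all queries scanned against the subject.
#' Positions containing non-ACGT characters are skipped.
#'
#' @param subject nucleotide string.
#' @param k k-mer length (<= 15, to keep codes in integer-exact doubles).
#' @return opaque index list for [seeded_local_search()].
#' @export
kmer_index <- function(subject, k = 11L) {
  if (k > 15L) stop("k must be <= 15")
  codes <- kmer_codes(subject, k)
  ok <- which(!is.na(codes))
  list(k = k, by_code = split(ok, codes[ok]))
}

#' @noRd
kmer_codes <- function(seq, k) {
  v <- c(A = 0, C = 1, G = 2, T = 3)[strsplit(toupper(seq), "",
                                              fixed = TRUE)[[1L]]]
  L <- length(v)
  if (L < k) return(numeric(0))
  n <- L - k + 1L
  code <- numeric(n)
  for (j in 0:(k - 1L)) code <- code * 4 + v[(1L + j):(n + j)]
  code
}

#' @noRd
kmer_lookup <- function(index, query) {
  qcodes <- kmer_codes(query, index$k)
  keys <- as.character(qcodes)
  found <- which(!is.na(qcodes) & keys %in% names(index$by_code))
  if (length(found) == 0L)
    return(data.frame(qpos = integer(0), spos = integer(0)))
  pos <- index$by_code[keys[found]]
  data.frame(qpos = rep(found, lengths(pos)),
             spos = unlist(pos, use.names = FALSE))
}

#' Merge seed matches into refinement windows
#' @noRd
seed_windows <- function(qpos, spos, qlen, k, slen) {
  diag <- spos - qpos
  ord <- order(diag, spos)
  diag <- diag[ord]; sp <- spos[ord]
  band <- cumsum(c(TRUE, diff(diag) > 32L | diff(sp) > qlen + 32L))
  t(vapply(split(seq_along(sp), band), function(ii) {
    c(max(1L, min(sp[ii]) - qlen - 16L),
      min(slen, max(sp[ii]) + k + qlen + 16L))
  }, integer(2)))
}

#' Keep the best-scoring hit among heavily overlapping ones
#' @noRd
dedupe_hits <- function(hits) {
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i < nrow(hits)) {
      later <- (i + 1L):nrow(hits)
      ov <- pmin(hits$end[later], hits$end[i]) -
        pmax(hits$start[later], hits$start[i])
      w <- pmin(hits$end[later] - hits$start[later],
                hits$end[i] - hits$start[i])
      keep[later][ov > 0.5 * w & hits$strand[later] == hits$strand[i]] <- FALSE
    }
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Chain exon hits into duplication blocks
#'
#' Hits (from all exons of one gene) are sorted by subject position and
#' runs of strictly increasing (plus strand) or strictly decreasing
#' (inverted copies) exon indices within `max_gap` are chained into one
#' block.
#'
#' @param hits data.frame of hits with an `exon_index` column in addition
#'   to the [seeded_local_search()] columns.
#' @param max_gap maximum nt between consecutive chained hits.
#' @param source_intervals optional matrix of the source exons' own
#'   intervals (row i = exon i, subject frame): a chain is never extended
#'   so that its merged interval would span a source exon of the chain --
#'   a duplicate copy cannot contain its own source.
#' @return data.frame of blocks: `exon_from`, `exon_to`, `start`, `end`,
#'   `strand`, `n_exons`, `mean_identity`.
#' @export
chain_hits_to_blocks <- function(hits, max_gap = 20000L,
                                 source_intervals = NULL) {
  empty <- data.frame(exon_from = integer(0), exon_to = integer(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_exons = integer(0),
                      mean_identity = numeric(0))
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$start), , drop = FALSE]
  blocks <- list()
  cur <- hits[1L, , drop = FALSE]
  flush <- function(cur) {
    data.frame(exon_from = min(cur$exon_index), exon_to = max(cur$exon_index),
               start = min(cur$start), end = max(cur$end),
               strand = cur$strand[1L], n_exons = nrow(cur),
               mean_identity = mean(cur$identity), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(hits))[-1L]) {
    h <- hits[i, , drop = FALSE]
    last <- cur[nrow(cur), ]
    step <- h$exon_index - last$exon_index
    colinear <- (h$strand == "+" & step > 0L) | (h$strand == "-" & step < 0L)
    spans_source <- FALSE
    if (!is.null(source_intervals)) {
      idx <- c(cur$exon_index, h$exon_index)
      src <- source_intervals[idx, , drop = FALSE]
      ms <- min(cur$start, h$start); me <- max(cur$end, h$end)
      spans_source <- any(pmin(me, src[, 2L]) > pmax(ms, src[, 1L]))
    }
    if (h$strand == last$strand && colinear && !spans_source &&
        h$start - last$end <= max_gap) {
      cur <- rbind(cur, h)
    } else {
      blocks[[length(blocks) + 1L]] <- flush(cur)
      cur <- h
    }
  }
  blocks[[length(blocks) + 1L]] <- flush(cur)
  do.call(rbind, blocks)
}

#' Classify a duplication block's location relative to the gene
#'
#' A block fully inside intron i is `internal` with that intron index; a
#' block before the gene start is `upstream` with the distance from the
#' block end to the gene start; after the gene end, `downstream`
#' analogously. A block straddling an exon/intron boundary is assigned the
#' intron containing its midpoint, with `straddle = TRUE`.
#'
#' @param block one row from [chain_hits_to_blocks()] (coordinates on the
#'   model's scanned frame, `model$flank_seq`).
#' @param model the source [gene_model()].
#' @return list with `location` (`"internal"`, `"upstream"`,
#'   `"downstream"`), `intron_index` or `distance`, and `straddle`.
#' @export
classify_block_location <- function(block, model) {
  off <- model$flank_offset
  gstart <- off; gend <- off + nchar(model$gene_seq)
  bs <- block$start; be <- block$end
  ex <- model$exons + off
  span_ex <- seq(block$exon_from, block$exon_to)
  ov_own <- any(pmin(be, ex[span_ex, 2L]) > pmax(bs, ex[span_ex, 1L]))
  if (ov_own)
    stop("self-hit leak: block overlaps its own source exon(s)")
  if (be <= gstart) {
    return(list(location = "upstream", distance = gstart - be,
                straddle = FALSE))
  }
  if (bs >= gend) {
    return(list(location = "downstream", distance = bs - gend,
                straddle = FALSE))
  }
  introns <- model$introns + off
  inside <- which(introns[, 1L] <= bs & be <= introns[, 2L])
  if (length(inside) == 1L) {
    return(list(location = "internal", intron_index = inside,
                straddle = FALSE))
  }
  mid <- (bs + be) / 2
  d <- pmax(introns[, 1L] - mid, 0) + pmax(mid - introns[, 2L], 0)
  list(location = "internal", intron_index = which.min(d), straddle = TRUE)
}

#' Scan a gene model for partial duplications
#'
#' Runs [seeded_local_search()] with every exon as query against the
#' model's scanned frame (gene + flanks), chains colinear hits into blocks
#' and classifies each block's location and completeness (`full` iff the
#' block spans every exon).
#'
#' @param model a [gene_model()].
#' @inheritParams seeded_local_search
#' @inheritParams chain_hits_to_blocks
#' @return data.frame of classified blocks (one row per block): taxon,
#'   gene_id, exon span, frame interval, strand, identities, location
#'   fields and completeness.
#' @export
scan_duplications <- function(model, k = 11L, min_identity = 0.70,
                              min_coverage = 0.50, min_score = 30,
                              max_gap = 20000L) {
  off <- model$flank_offset
  index <- kmer_index(model$flank_seq, k)
  hits <- list()
  for (i in seq_len(nrow(model$exons))) {
    ex_seq <- substring(model$gene_seq, model$exons[i, 1L] + 1L,
                        model$exons[i, 2L])
    h <- seeded_local_search(ex_seq, model$flank_seq, k = k,
                             min_identity = min_identity,
                             min_coverage = min_coverage,
                             min_score = min_score,
                             exclude = model$exons[i, ] + off,
                             index = index)
    if (nrow(h) > 0L) {
      h$exon_index <- i
      hits[[length(hits) + 1L]] <- h
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else NULL
  blocks <- chain_hits_to_blocks(hits, max_gap = max_gap,
                                 source_intervals = model$exons + off)
  if (nrow(blocks) == 0L) {
    return(data.frame(taxon = character(0), gene_id = character(0),
                      exon_from = integer(0), exon_to = integer(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_exons = integer(0),
                      mean_identity = numeric(0), location = character(0),
                      intron_index = integer(0), distance = integer(0),
                      straddle = logical(0), completeness = character(0)))
  }
  n_exons_gene <- nrow(model$exons)
  loc <- lapply(seq_len(nrow(blocks)), function(i)
    classify_block_location(blocks[i, ], model))
  blocks$location <- vapply(loc, `[[`, character(1), "location")
  blocks$intron_index <- vapply(loc, function(l)
    l$intron_index %||% NA_integer_, integer(1))
  blocks$distance <- vapply(loc, function(l)
    as.integer(l$distance %||% NA_integer_), integer(1))
  blocks$straddle <- vapply(loc, `[[`, logical(1), "straddle")
  blocks$completeness <- ifelse(
    blocks$exon_from == 1L & blocks$exon_to == n_exons_gene, "full", "partial")
  cbind(data.frame(taxon = model$taxon, gene_id = model$gene_id,
                   stringsAsFactors = FALSE), blocks)
}
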