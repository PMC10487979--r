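# Classification of alternative-splicing events by pairwise intron-chain
# comparison, and detection of upstream ORFs in transcript leaders.

#' @noRd
intron_chain <- function(exons) {
  exons <- as_interval_matrix(exons)
  n <- nrow(exons)
  if (n < 2L) return(as_interval_matrix(NULL))
  cbind(start = exons[-n, 2L], end = exons[-1L, 1L])
}

#' Classify alternative-splicing events among a gene's transcripts
#'
#' Transcript pairs are compared by their intron chains within the shared
#' genomic span. Differing introns are grouped into event regions and
#' typed: a single overlapping intron pair with equal acceptor but shifted
#' donor is `alt_donor` (and vice versa `alt_acceptor`); one transcript's
#' two introns fused into the other's single intron spanning an internal
#' exon is `exon_skipping`; two internal exons each unique to one
#' transcript between shared flanks, non-overlapping, is
#' `mutually_exclusive`; an intron of one transcript contained in an exon
#' of the other is `intron_retention`; everything else -- including
#' alternative first-exon usage, where the chains inside the shared span
#' agree but one transcript splices additional introns outside it -- is
#' `other`. Events identical across pairs are deduplicated.
#'
#' @param transcripts named list of exon interval matrices (0-based
#'   half-open, common coordinate frame, ascending order).
#' @param strand `"+"` or `"-"`; on `"-"` the frame is flipped so donor /
#'   acceptor designations follow transcription.
#' @return data.frame: `transcript_a`, `transcript_b`, `event_type`,
#'   `start`, `end` (affected interval, input frame).
#' @export
classify_as_events <- function(transcripts, strand = "+") {
  empty <- data.frame(transcript_a = character(0), transcript_b = character(0),
                      event_type = character(0), start = integer(0),
                      end = integer(0))
  if (length(transcripts) < 2L) return(empty)
  if (!strand %in% c("+", "-")) stop("transcripts must share a strand")
  txs <- lapply(transcripts, as_interval_matrix)
  flip_c <- max(vapply(txs, function(m) max(m[, 2L]), integer(1)))
  if (strand == "-")
    txs <- lapply(txs, function(m)
      as_interval_matrix(cbind(flip_c - m[, 2L], flip_c - m[, 1L])[rev(seq_len(nrow(m))), , drop = FALSE]))

  ids <- names(txs)
  out <- list()
  for (i in seq_along(txs)[-length(txs)]) {
    for (j in (i + 1L):length(txs)) {
      evs <- classify_pair(txs[[i]], txs[[j]])
      if (nrow(evs) == 0L) next
      evs$transcript_a <- ids[i]; evs$transcript_b <- ids[j]
      out[[length(out) + 1L]] <- evs
    }
  }
  if (length(out) == 0L) return(empty)
  out <- do.call(rbind, out)
  if (strand == "-") {
    s <- flip_c - out$end; e <- flip_c - out$start
    out$start <- s; out$end <- e
  }
  out <- out[!duplicated(out[, c("event_type", "start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("transcript_a", "transcript_b", "event_type", "start", "end")]
}

#' @noRd
classify_pair <- function(a, b) {
  empty <- data.frame(event_type = character(0), start = integer(0),
                      end = integer(0))
  shared <- c(max(a[1L, 1L], b[1L, 1L]), min(a[nrow(a), 2L], b[nrow(b), 2L]))
  if (shared[2L] <= shared[1L]) return(empty)
  ia <- intron_chain(a); ib <- intron_chain(b)
  within <- function(iv) iv[iv[, 1L] >= shared[1L] & iv[, 2L] <= shared[2L], ,
                            drop = FALSE]
  wa <- within(ia); wb <- within(ib)
  key <- function(m) paste(m[, 1L], m[, 2L])
  da <- wa[!key(wa) %in% key(wb), , drop = FALSE]
  db <- wb[!key(wb) %in% key(wa), , drop = FALSE]

  if (nrow(da) == 0L && nrow(db) == 0L) {
    # identical chains inside the shared span; alternative first/last exon
    # usage if exactly one transcript splices introns outside it
    oa <- nrow(ia) - nrow(wa); ob <- nrow(ib) - nrow(wb)
    if (xor(oa > 0L, ob > 0L)) {
      reg <- range(a[1L, 1L], b[1L, 1L], a[nrow(a), 2L], b[nrow(b), 2L])
      return(data.frame(event_type = "other", start = reg[1L], end = reg[2L]))
    }
    return(empty)
  }

  # group differing introns (either transcript) into overlapping regions
  tag <- function(m, w) cbind(m, who = rep(w, nrow(m)))
  all_d <- rbind(tag(da, 1L), tag(db, 2L))
  all_d <- all_d[order(all_d[, 1L]), , drop = FALSE]
  grp <- integer(nrow(all_d)); g <- 1L; grp[1L] <- 1L
  reach <- all_d[1L, 2L]
  for (r in seq_len(nrow(all_d))[-1L]) {
    if (all_d[r, 1L] <= reach) grp[r] <- g
    else { g <- g + 1L; grp[r] <- g }
    reach <- max(reach, all_d[r, 2L])
  }

  evs <- lapply(split(seq_len(nrow(all_d)), grp), function(rows) {
    m <- all_d[rows, , drop = FALSE]
    ga <- m[m[, "who"] == 1L, , drop = FALSE]
    gb <- m[m[, "who"] == 2L, , drop = FALSE]
    reg <- c(min(m[, 1L]), max(m[, 2L]))
    type <- classify_group(ga[, 1:2, drop = FALSE], gb[, 1:2, drop = FALSE],
                           a, b)
    data.frame(event_type = type, start = reg[1L], end = reg[2L])
  })
  do.call(rbind, evs)
}

#' @noRd
classify_group <- function(ga, gb, a, b) {
  na <- nrow(ga); nb <- nrow(gb)
  contained_in_exon <- function(iv, exons) {
    any(exons[, 1L] <= iv[1L] & iv[2L] <= exons[, 2L])
  }
  if ((na == 1L && nb == 0L) || (na == 0L && nb == 1L)) {
    iv <- if (na == 1L) ga[1L, ] else gb[1L, ]
    other_ex <- if (na == 1L) b else a
    if (contained_in_exon(iv, other_ex)) return("intron_retention")
    return("other")
  }
  if (na == 1L && nb == 1L) {
    if (ga[1L, 1L] == gb[1L, 1L] && ga[1L, 2L] != gb[1L, 2L])
      return("alt_acceptor")                       # 3' end of the intron
    if (ga[1L, 2L] == gb[1L, 2L] && ga[1L, 1L] != gb[1L, 1L])
      return("alt_donor")                          # 5' end of the intron
    return("other")
  }
  skip <- function(two, one) {
    nrow(two) == 2L && nrow(one) == 1L &&
      one[1L, 1L] == two[1L, 1L] && one[1L, 2L] == two[2L, 2L]
  }
  if (skip(ga, gb) || skip(gb, ga)) return("exon_skipping")
  if (na == 2L && nb == 2L &&
      ga[1L, 1L] == gb[1L, 1L] && ga[2L, 2L] == gb[2L, 2L]) {
    exon_a <- c(ga[1L, 2L], ga[2L, 1L])
    exon_b <- c(gb[1L, 2L], gb[2L, 1L])
    if (exon_a[2L] <= exon_b[1L] || exon_b[2L] <= exon_a[1L])
      return("mutually_exclusive")
  }
  "other"
}

#' Find upstream open reading frames
#'
#' Reports every `ATG ... stop` ORF, in any frame, lying entirely upstream
#' of the transcript's annotated main start codon. The amino-acid length
#' counts the initiator Met and excludes the stop.
#'
#' @param transcript_seq spliced transcript sequence.
#' @param main_start_offset 0-based offset of the main start codon in the
#'   transcript.
#' @param min_aa minimum uORF length in aa (default 2).
#' @return data.frame: `start`, `stop_end` (0-based transcript offsets;
#'   `stop_end` is the half-open end of the stop codon), `length_aa`,
#'   `frame`.
#' @export
find_uorfs <- function(transcript_seq, main_start_offset, min_aa = 2L) {
  empty <- data.frame(start = integer(0), stop_end = integer(0),
                      length_aa = integer(0), frame = integer(0))
  seq <- toupper(transcript_seq)
  if (main_start_offset < 3L) return(empty)
  leader_end <- main_start_offset           # exclusive
  out <- list()
  for (s in 0:(leader_end - 3L)) {
    if (substring(seq, s + 1L, s + 3L) != "ATG") next
    pos <- s
    repeat {
      pos <- pos + 3L
      if (pos + 3L > leader_end) break      # stop must stay upstream
      codon <- substring(seq, pos + 1L, pos + 3L)
      if (codon %in% STOP_CODONS) {
        aa <- (pos - s) %/% 3L
        if (aa >= min_aa)
          out[[length(out) + 1L]] <- data.frame(
            start = s, stop_end = pos + 3L, length_aa = aa, frame = s %% 3L)
        break
      }
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}
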