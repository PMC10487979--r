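# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (enumeration / full DP) and share no code with the
# implementation they check.

# --- gene-model builders ----------------------------------------------------

# A gene whose introns carry the given splice-site types ("GT-AG", "GG-CA"...)
make_splice_model <- function(types, taxon = "tx", gene_id = "g1",
                              exon_len = 6L, intron_len = 10L) {
  n_ex <- length(types) + 1L
  exon_seq <- strrep("A", exon_len)
  introns <- vapply(types, function(t) {
    ends <- strsplit(t, "-")[[1L]]
    paste0(ends[1L], strrep("C", intron_len - 4L), ends[2L])
  }, character(1))
  gene_seq <- paste0(exon_seq,
                     paste0(introns, exon_seq, collapse = ""))
  starts <- (seq_len(n_ex) - 1L) * (exon_len + intron_len)
  exons <- cbind(starts, starts + exon_len)
  gene_model(taxon, gene_id, exons, gene_seq)
}

# A coding gene with introns at the given CDS offsets (for homology tests)
make_coding_model <- function(taxon, cds, offsets,
                              intron_seqs = NULL, gene_id = NULL) {
  if (is.null(intron_seqs))
    intron_seqs <- vapply(seq_along(offsets), function(i)
      paste0("GT", strrep("T", 20), "AG"), character(1))
  pieces <- character(0); prev <- 0L
  starts <- integer(0); ends <- integer(0); shift <- 0L
  bounds <- c(0L, offsets, nchar(cds))
  for (i in seq_len(length(bounds) - 1L)) {
    starts <- c(starts, bounds[i] + shift)
    ends <- c(ends, bounds[i + 1L] + shift)
    pieces <- c(pieces, substring(cds, bounds[i] + 1L, bounds[i + 1L]))
    if (i <= length(offsets)) {
      pieces <- c(pieces, intron_seqs[i])
      shift <- shift + nchar(intron_seqs[i])
    }
  }
  gene_model(taxon, gene_id %||% paste0(taxon, "_g1"),
             cbind(starts, ends), paste(pieces, collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna_fix <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

# a random CDS with no internal stops (start/stop codons included)
random_cds_fix <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

# --- parsimony oracles ------------------------------------------------------

# all rooted binary tree shapes with n leaves, as newick strings over t1..tn
tree_shapes <- function(n) {
  shapes <- function(k) {
    if (k == 1L) return(list("L"))
    out <- list()
    for (a in seq_len(k %/% 2L)) {
      for (l in shapes(a)) for (r in shapes(k - a)) {
        if (a * 2L == k && paste(l) > paste(r)) next  # unordered pair
        out[[length(out) + 1L]] <- sprintf("(%s,%s)", l, r)
      }
    }
    unique(out)
  }
  vapply(shapes(n), function(s) {
    i <- 0L
    while (grepl("L", s, fixed = TRUE)) {
      i <- i + 1L
      s <- sub("L", sprintf("t%d", i), s, fixed = TRUE)
    }
    paste0(s, ";")
  }, character(1))
}

# structural view of a phylo tree used by the enumeration oracles
oracle_tree <- function(tree) {
  ntip <- ape::Ntip(tree)
  nall <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nall)
  for (k in seq_len(nrow(tree$edge)))
    parent[tree$edge[k, 2L]] <- tree$edge[k, 1L]
  list(ntip = ntip, nall = nall, root = ntip + 1L, parent = parent,
       tips = tree$tip.label)
}

# minimum events by exhaustive enumeration of internal-node labelings.
# Gains = 0->1 edges plus a gain "at or before the root" when the root is
# present; mode "dollo" restricts to single-gain labelings, mode "fitch"
# forces the root absent and counts all changes.
enum_min_events <- function(tree, pattern, mode = c("dollo", "fitch")) {
  mode <- match.arg(mode)
  ot <- oracle_tree(tree)
  states <- rep(NA_integer_, ot$nall)
  states[seq_len(ot$ntip)] <- pattern[ot$tips]
  internal <- (ot$ntip + 1L):ot$nall
  best <- Inf
  for (mask in 0:(2^length(internal) - 1L)) {
    st <- states
    st[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1L), 1L)
    if (mode == "fitch" && st[ot$root] != 0L) next
    gains <- as.integer(st[ot$root] == 1L)
    losses <- 0L
    for (v in seq_len(ot$nall)) {
      p <- ot$parent[v]
      if (is.na(p)) next
      if (st[p] == 0L && st[v] == 1L) gains <- gains + 1L
      if (st[p] == 1L && st[v] == 0L) losses <- losses + 1L
    }
    if (mode == "dollo" && gains != 1L) next
    best <- min(best, gains + losses)
  }
  best
}

# --- alignment oracle -------------------------------------------------------

# full Smith-Waterman with affine gaps, Biostrings gap convention (the
# first gap character costs open + extend). Returns the optimal score.
sw_oracle <- function(query, subject, match = 2, mismatch = -3,
                      gap_open = 5, gap_ext = 2) {
  q <- strsplit(query, "")[[1L]]; s <- strsplit(subject, "")[[1L]]
  n <- length(q); m <- length(s)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in query (move along subject)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in subject
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - gap_open - gap_ext, E[i, j - 1L] - gap_ext)
      F[i, j] <- max(H[i - 1L, j] - gap_open - gap_ext, F[i - 1L, j] - gap_ext)
      sc <- if (q[i - 1L] == s[j - 1L]) match else mismatch
      H[i, j] <- max(0, H[i - 1L, j - 1L] + sc, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# brute-force positional GC tally (independent of gc_by_codon_position)
gc_pos_oracle <- function(cds) {
  chars <- strsplit(toupper(cds), "")[[1L]]
  chars <- chars[seq_len(3L * (length(chars) %/% 3L))]
  vapply(1:3, function(p) {
    cc <- chars[seq(p, length(chars), by = 3L)]
    100 * sum(cc %in% c("G", "C")) / sum(cc %in% c("A", "C", "G", "T"))
  }, numeric(1))
}

translate_cds_fix <- function(cds) {
  sub("\\*$", "", as.character(Biostrings::translate(Biostrings::DNAString(cds))))
}
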