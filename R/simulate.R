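# Synthetic ortholog-family simulator: an ancestral multi-exon gene is
# evolved along a rooted species tree with per-branch intron gains and
# losses, TE insertions into introns, CDS substitution with third-position
# bias, and leaf-specific partial duplications and isoform operations.
# Every event is logged, so reconstructions can be scored against truth.

#' Built-in synthetic TE consensus library
#'
#' Four small synthetic consensus sequences, one per TE class (with Gypsy
#' and Copia LTR variants). These are generated sequences, not real repeat
#' consensi.
#'
#' @param seed RNG seed for the library sequences.
#' @return data.frame: `name`, `te_class`, `superfamily`, `class_family`,
#'   `seq`, `weight` (sampling weight at insertion).
#' @export
te_library <- function(seed = 20230913L) {
  with_seed(seed, {
    data.frame(
      name = c("synGypsy1", "synCopia1", "synDNA1", "synHelitron1",
               "synUnk1"),
      te_class = c("retrotransposon", "retrotransposon", "DNA_transposon",
                   "helitron", "unclassified"),
      superfamily = c("Gypsy", "Copia", "hAT", "Helitron", NA),
      class_family = c("LTR/Gypsy", "LTR/Copia", "DNA/hAT", "RC/Helitron",
                       "Unknown"),
      seq = c(random_dna(520), random_dna(430), random_dna(310),
              random_dna(360), random_dna(280)),
      weight = c(0.40, 0.25, 0.15, 0.05, 0.15),
      stringsAsFactors = FALSE)
  })
}

#' Balanced rooted binary tree
#'
#' @param n number of leaves (any integer >= 2; uneven splits are taken as
#'   floor/ceiling halves).
#' @param labels leaf labels (default `t01..`).
#' @return a rooted `phylo` with labeled internal nodes.
#' @export
balanced_tree <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  build <- function(lab) {
    if (length(lab) == 1L) return(lab)
    h <- length(lab) %/% 2L
    sprintf("(%s,%s)", build(lab[seq_len(h)]), build(lab[-seq_len(h)]))
  }
  parse_newick(paste0(build(labels), ";"))
}

#' Simulation configuration
#'
#' Assembles and validates the parameter set of the family simulator. The
#' defaults emulate a conserved seed-plant-like coding gene: 23 exons
#' (hence 22 ancestral intron sites), a ~3.5 kb CDS, short base introns
#' that grow only by TE insertion, rare intron gain and more frequent loss,
#' and mostly canonical GT-AG splice sites with a small non-canonical
#' fraction dominated by GG-CA.
#'
#' @param seed integer RNG seed; the whole simulation is deterministic
#'   given the seed.
#' @param tree `phylo`, Newick string, or `NULL` to build a
#'   [balanced_tree()] with `n_leaves` leaves.
#' @param n_leaves leaves of the generated tree when `tree` is `NULL`.
#' @param root_exons ancestral exon count (>= 2).
#' @param cds_codons ancestral CDS length in codons (incl. start/stop).
#' @param intron_meanlog,intron_sdlog lognormal intron-length parameters.
#' @param min_intron minimum intron length (nt).
#' @param gain_rate,loss_rate expected intron gains / losses per branch.
#' @param subst_rate CDS substitutions per site per branch (applied with a
#'   3:1 bias to third codon positions; nonsense changes are rejected).
#' @param intron_subst_rate substitutions per intron site per branch
#'   (terminal dinucleotides protected).
#' @param te_rate expected TE insertions per branch: a scalar for all
#'   branches, or a named per-taxon vector applied to terminal branches
#'   only (0 elsewhere).
#' @param te_divergence_max TE copies are inserted with a divergence drawn
#'   uniformly from `[0, te_divergence_max]`.
#' @param noncanonical_prob probability that a newly created intron gets a
#'   non-canonical splice-site type.
#' @param noncanonical_types named probability vector of non-canonical
#'   site types.
#' @param flank_length plain flanking sequence on each side of the gene.
#' @param duplications list of planted duplications:
#'   `list(taxon=, exon_from=, exon_to=, target=list(type="intron",
#'   index=) | list(type="upstream"|"downstream", distance=),
#'   divergence=)`.
#' @param isoforms list of planted isoform operations: `list(taxon=,
#'   op="skip_exon"|"alt_donor"|"alt_acceptor"|"retain_intron"|
#'   "mutually_exclusive"|"alt_first", exon=, shift=, offset=)`.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, tree = NULL, n_leaves = 16L,
                       root_exons = 23L, cds_codons = 1166L,
                       intron_meanlog = log(250), intron_sdlog = 0.7,
                       min_intron = 60L,
                       gain_rate = 0.1, loss_rate = 0.3,
                       subst_rate = 0.005, intron_subst_rate = 0.01,
                       te_rate = 0.3, te_divergence_max = 0.15,
                       noncanonical_prob = 0.0595,
                       noncanonical_types = c("GG-CA" = 0.30, "GC-AG" = 0.25,
                                              "AT-AC" = 0.20, "CT-AC" = 0.15,
                                              "GG-AG" = 0.10),
                       flank_length = 2000L,
                       duplications = list(), isoforms = list()) {
  if (root_exons < 2L) stop("root_exons must be >= 2")
  if (any(c(gain_rate, loss_rate, subst_rate, intron_subst_rate,
            unlist(te_rate)) < 0))
    stop("rates must be non-negative")
  if (cds_codons * 3L < root_exons) stop("CDS too short for the exon count")
  if (is.null(tree)) tree <- balanced_tree(n_leaves)
  if (is.character(tree)) tree <- parse_newick(tree)
  tree <- ensure_node_labels(tree)
  structure(list(seed = as.integer(seed), tree = tree,
                 root_exons = as.integer(root_exons),
                 cds_codons = as.integer(cds_codons),
                 intron_meanlog = intron_meanlog, intron_sdlog = intron_sdlog,
                 min_intron = as.integer(min_intron),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 subst_rate = subst_rate,
                 intron_subst_rate = intron_subst_rate,
                 te_rate = te_rate, te_divergence_max = te_divergence_max,
                 noncanonical_prob = noncanonical_prob,
                 noncanonical_types = noncanonical_types /
                   sum(noncanonical_types),
                 flank_length = as.integer(flank_length),
                 te_lib = te_library(),
                 duplications = duplications, isoforms = isoforms),
            class = "sim_config")
}

#' @noRd
random_cds <- function(n_codons) {
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L,
                  paste, collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

#' @noRd
new_intron_seq <- function(config) {
  len <- max(config$min_intron,
             round(stats::rlnorm(1, config$intron_meanlog,
                                 config$intron_sdlog)))
  type <- "GT-AG"
  if (stats::runif(1) < config$noncanonical_prob)
    type <- sample(names(config$noncanonical_types), 1L,
                   prob = config$noncanonical_types)
  ends <- strsplit(type, "-")[[1L]]
  paste0(ends[1L], random_dna(len - 4L), ends[2L])
}

#' @noRd
substitute_cds <- function(cds, rate) {
  if (rate <= 0) return(cds)
  chars <- strsplit(cds, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  pos3 <- seq_len(n) %% 3L == 0L
  # mean rate preserved with a 3:1 third-position bias
  p <- ifelse(pos3, 9 * rate / 5, 3 * rate / 5)
  p[1:3] <- 0; p[(n - 2):n] <- 0           # keep start/stop codons intact
  hit <- which(stats::runif(n) < p)
  for (i in hit) {
    new <- sample(setdiff(DNA_BASES, chars[i]), 1L)
    codon_start <- i - (i - 1L) %% 3L
    codon <- chars[codon_start:(codon_start + 2L)]
    codon[i - codon_start + 1L] <- new
    if (paste(codon, collapse = "") %in% STOP_CODONS) next  # reject nonsense
    chars[i] <- new
  }
  paste(chars, collapse = "")
}

#' @noRd
substitute_intron <- function(intron, rate) {
  if (rate <= 0) return(intron)
  seq <- intron$seq
  n <- nchar(seq)
  if (n <= 4L) return(intron)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(n) < rate)
  hit <- hit[hit > 2L & hit <= n - 2L]      # protect splice dinucleotides
  for (i in hit) chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  intron$seq <- paste(chars, collapse = "")
  intron
}

#' @noRd
insert_te <- function(intron, config) {
  lib <- config$te_lib
  el <- lib[sample(nrow(lib), 1L, prob = lib$weight), ]
  div <- stats::runif(1, 0, config$te_divergence_max)
  copy <- mutate_dna(el$seq, div)
  L <- nchar(copy)
  n <- nchar(intron$seq)
  p <- sample(seq(3L, max(3L, n - 2L)), 1L)  # insertion point, 0-based p-1
  pos0 <- p - 1L
  te <- intron$te
  if (nrow(te) > 0L) {
    # shift records downstream of the insertion point, then split any
    # record the insertion lands inside (its right part shifts by L)
    inside <- te$start < pos0 & pos0 < te$end
    after <- !inside & te$start >= pos0
    split_left <- split_right <- NULL
    if (any(inside)) {
      sp <- te[inside, , drop = FALSE]
      split_left <- sp; split_left$end <- pos0
      split_right <- sp
      split_right$start <- pos0 + L; split_right$end <- sp$end + L
    }
    te$start[after] <- te$start[after] + L
    te$end[after] <- te$end[after] + L
    te <- rbind(te[!inside, , drop = FALSE], split_left, split_right)
  }
  te <- rbind(te, data.frame(start = pos0, end = pos0 + L,
                             name = el$name, te_class = el$te_class,
                             superfamily = el$superfamily,
                             class_family = el$class_family,
                             divergence = 100 * div,
                             stringsAsFactors = FALSE))
  intron$seq <- paste0(substring(intron$seq, 1L, pos0), copy,
                       substring(intron$seq, pos0 + 1L, n))
  intron$te <- te[order(te$start), , drop = FALSE]
  intron
}

#' @noRd
empty_te_registry <- function() {
  data.frame(start = integer(0), end = integer(0), name = character(0),
             te_class = character(0), superfamily = character(0),
             class_family = character(0), divergence = numeric(0),
             stringsAsFactors = FALSE)
}

#' Simulate an ortholog family along a tree
#'
#' Builds an ancestral gene from the configured distributions, then walks
#' the tree: on every branch the CDS is substituted (third-position
#' biased, nonsense-rejecting), introns are lost (uniformly among those
#' present), gained (at uniform codon boundaries with uniform phase, with
#' mostly canonical splice sites) and extended by TE insertion, all with
#' Poisson event counts. At designated leaves, partial duplications and
#' isoform operations are applied. Everything is logged in the truth
#' object. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `models` (named list of [gene_model()]) and `truth`:
#'   `events` (branch, site, type), `sites` (site id, cds_offset, phase,
#'   origin branch), `root_sites`, `te_registry` (per taxon, gene-local
#'   intervals), `duplications` (planted, with frame intervals),
#'   `isoforms`, `matrix` (true presence/absence), `msa` (true protein
#'   alignment), `tree`, `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_family_impl(config))
}

#' @noRd
simulate_family_impl <- function(config) {
  tree <- config$tree
  idx <- tree_index(tree)
  ncds <- config$cds_codons * 3L

  # ancestral state
  n_introns <- config$root_exons - 1L
  offsets <- sort(sample(seq_len(config$cds_codons - 1L), n_introns)) * 3L +
    sample(0:2, n_introns, replace = TRUE)
  offsets <- pmin(offsets, ncds - 1L)
  offsets <- sort(unique(offsets))
  root_introns <- lapply(seq_along(offsets), function(i) {
    list(site = sprintf("s%02d", i), offset = offsets[i],
         phase = offsets[i] %% 3L, seq = new_intron_seq(config),
         te = empty_te_registry())
  })
  root_state <- list(cds = random_cds(config$cds_codons),
                     introns = root_introns)

  env <- new.env()
  env$events <- list()
  env$sites <- data.frame(
    site = vapply(root_introns, `[[`, character(1), "site"),
    cds_offset = vapply(root_introns, `[[`, numeric(1), "offset"),
    phase = vapply(root_introns, `[[`, numeric(1), "phase"),
    origin = "root", stringsAsFactors = FALSE)
  env$gain_counter <- 0L
  env$leaf_states <- list()

  te_rate_for <- function(child) {
    tr <- config$te_rate
    if (length(tr) == 1L && is.null(names(tr))) return(as.numeric(tr))
    if (child <= idx$ntip) {
      taxon <- idx$labels[child]
      return(as.numeric(tr[taxon] %||% 0))
    }
    0
  }

  evolve <- function(node, state) {
    for (child in idx$children[[node]]) {
      branch <- idx$labels[child]
      st <- state
      st$cds <- substitute_cds(st$cds, config$subst_rate)
      st$introns <- lapply(st$introns, substitute_intron,
                           rate = config$intron_subst_rate)
      # losses
      n_loss <- stats::rpois(1L, config$loss_rate)
      for (k in seq_len(n_loss)) {
        if (length(st$introns) == 0L) {
          env$events[[length(env$events) + 1L]] <- data.frame(
            branch = branch, site = NA_character_, type = "loss_skipped")
          next
        }
        drop_i <- sample.int(length(st$introns), 1L)
        env$events[[length(env$events) + 1L]] <- data.frame(
          branch = branch, site = st$introns[[drop_i]]$site, type = "loss")
        st$introns <- st$introns[-drop_i]
      }
      # gains
      n_gain <- stats::rpois(1L, config$gain_rate)
      for (k in seq_len(n_gain)) {
        used <- vapply(st$introns, `[[`, numeric(1), "offset")
        cand <- setdiff(3L * seq_len(config$cds_codons - 1L), used)
        if (length(cand) == 0L) next
        base <- sample(cand, 1L)
        off <- min(base + sample(0:2, 1L), ncds - 1L)
        if (off %in% used) off <- base
        env$gain_counter <- env$gain_counter + 1L
        site <- sprintf("g%02d", env$gain_counter)
        st$introns <- c(st$introns, list(list(
          site = site, offset = off, phase = off %% 3L,
          seq = new_intron_seq(config), te = empty_te_registry())))
        env$sites <- rbind(env$sites, data.frame(
          site = site, cds_offset = off, phase = off %% 3L,
          origin = branch, stringsAsFactors = FALSE))
        env$events[[length(env$events) + 1L]] <- data.frame(
          branch = branch, site = site, type = "gain")
      }
      # TE insertions
      n_te <- stats::rpois(1L, te_rate_for(child))
      for (k in seq_len(n_te)) {
        if (length(st$introns) == 0L) next
        ti <- sample.int(length(st$introns), 1L)
        st$introns[[ti]] <- insert_te(st$introns[[ti]], config)
      }
      ord <- order(vapply(st$introns, `[[`, numeric(1), "offset"))
      st$introns <- st$introns[ord]
      if (child <= idx$ntip) {
        env$leaf_states[[idx$labels[child]]] <- st
      } else {
        evolve(child, st)
      }
    }
  }
  evolve(idx$root, root_state)

  taxa <- tree$tip.label
  truth_dups <- list(); truth_isos <- list()
  models <- list(); te_registry <- list()
  for (taxon in taxa) {
    st <- env$leaf_states[[taxon]]
    asm <- assemble_leaf(taxon, st, config)
    models[[taxon]] <- asm$model
    te_registry[[taxon]] <- asm$te
    if (!is.null(asm$dup)) truth_dups[[length(truth_dups) + 1L]] <- asm$dup
    if (!is.null(asm$iso)) truth_isos[[length(truth_isos) + 1L]] <- asm$iso
  }

  events <- if (length(env$events)) do.call(rbind, env$events) else
    data.frame(branch = character(0), site = character(0),
               type = character(0))
  # true presence matrix over all sites ever segregating at a leaf
  site_ids <- env$sites$site
  mat <- matrix(0L, nrow = length(taxa), ncol = length(site_ids),
                dimnames = list(taxa, site_ids))
  for (taxon in taxa) {
    present <- vapply(env$leaf_states[[taxon]]$introns, `[[`, character(1),
                      "site")
    mat[taxon, present] <- 1L
  }
  keep <- colSums(mat) > 0L
  mat <- mat[, keep, drop = FALSE]
  ord <- order(env$sites$cds_offset[match(colnames(mat), env$sites$site)])
  mat <- mat[, ord, drop = FALSE]

  prots <- vapply(models, function(m) translate_cds(m$cds_seq), character(1))
  truth <- list(
    events = events, sites = env$sites,
    root_sites = vapply(root_introns, `[[`, character(1), "site"),
    te_registry = te_registry,
    duplications = if (length(truth_dups)) do.call(rbind, truth_dups) else NULL,
    isoforms = if (length(truth_isos)) do.call(rbind, truth_isos) else NULL,
    matrix = mat, msa = prots, tree = tree, config = config)
  list(models = models, truth = truth)
}

#' Assemble a leaf gene model, applying duplications and isoform ops
#' @noRd
assemble_leaf <- function(taxon, st, config) {
  dup_spec <- Filter(function(d) d$taxon == taxon, config$duplications)
  iso_spec <- Filter(function(i) i$taxon == taxon, config$isoforms)
  dup_truth <- NULL

  # provisional exon layout in gene-local coordinates (pre-duplication)
  layout <- function(introns, cds_len) {
    offs <- vapply(introns, `[[`, numeric(1), "offset")
    ilen <- vapply(introns, function(i) nchar(i$seq), numeric(1))
    bounds <- c(0L, offs, cds_len)                 # exon CDS boundaries
    starts <- integer(0); ends <- integer(0); shift <- 0L
    for (i in seq_len(length(bounds) - 1L)) {
      starts <- c(starts, bounds[i] + shift)
      ends <- c(ends, bounds[i + 1L] + shift)
      if (i <= length(introns)) shift <- shift + ilen[i]
    }
    cbind(starts, ends)
  }
  build_gene <- function(cds, introns) {
    offs <- vapply(introns, `[[`, numeric(1), "offset")
    pieces <- character(0); prev <- 0L
    for (i in seq_along(introns)) {
      pieces <- c(pieces, substring(cds, prev + 1L, offs[i]),
                  introns[[i]]$seq)
      prev <- offs[i]
    }
    paste(c(pieces, substring(cds, prev + 1L, nchar(cds))), collapse = "")
  }

  cds_len <- nchar(st$cds)
  # duplication segments are cut from the pre-insertion gene
  pre_exons <- layout(st$introns, cds_len)
  pre_gene <- build_gene(st$cds, st$introns)

  flank_up <- config$flank_length
  flank_dn <- config$flank_length
  up_extra <- ""; dn_extra <- ""

  for (d in dup_spec) {
    seg <- substring(pre_gene, pre_exons[d$exon_from, 1L] + 1L,
                     pre_exons[d$exon_to, 2L])
    seg <- mutate_dna(seg, d$divergence %||% 0)
    tgt <- d$target
    if (tgt$type == "intron") {
      it <- tgt$index
      iseq <- st$introns[[it]]$seq
      mid <- nchar(iseq) %/% 2L
      st$introns[[it]]$seq <- paste0(substring(iseq, 1L, mid), seg,
                                     substring(iseq, mid + 1L, nchar(iseq)))
      te <- st$introns[[it]]$te
      if (nrow(te) > 0L) {    # shift TE records past the insertion point
        L <- nchar(seg)
        mv <- te$start >= mid
        te$start[mv] <- te$start[mv] + L; te$end[mv] <- te$end[mv] + L
        st$introns[[it]]$te <- te
      }
      loc <- "internal"; locval <- it
    } else if (tgt$type == "upstream") {
      up_extra <- paste0(random_dna(500L), seg, random_dna(tgt$distance))
      loc <- "upstream"; locval <- tgt$distance
    } else {
      dn_extra <- paste0(random_dna(tgt$distance), seg, random_dna(500L))
      loc <- "downstream"; locval <- tgt$distance
    }
    dup_truth <- rbind(dup_truth, data.frame(
      taxon = taxon, exon_from = d$exon_from, exon_to = d$exon_to,
      location = loc, locvalue = locval, divergence = d$divergence %||% 0,
      seg_length = nchar(seg), stringsAsFactors = FALSE))
  }

  gene_seq <- build_gene(st$cds, st$introns)
  exons <- layout(st$introns, cds_len)
  frame <- paste0(random_dna(flank_up), up_extra, gene_seq, dn_extra,
                  random_dna(flank_dn))
  offset <- flank_up + nchar(up_extra)

  # TE registry in gene-local coordinates
  te_rows <- list()
  for (i in seq_along(st$introns)) {
    te <- st$introns[[i]]$te
    if (nrow(te) == 0L) next
    istart <- exons[i, 2L]
    te$start <- te$start + istart; te$end <- te$end + istart
    te$intron_index <- i
    te_rows[[length(te_rows) + 1L]] <- te
  }
  te_reg <- if (length(te_rows)) do.call(rbind, te_rows) else
    cbind(empty_te_registry(), data.frame(intron_index = integer(0)))

  # isoform operations on the constitutive exon chain
  transcripts <- NULL
  iso_truth <- NULL
  if (length(iso_spec) > 0L) {
    transcripts <- list(t1 = as_interval_matrix(exons))
    for (s in seq_along(iso_spec)) {
      io <- iso_spec[[s]]
      alt <- apply_isoform_op(exons, io)
      tid <- sprintf("t%d", s + 1L)
      transcripts[[tid]] <- as_interval_matrix(alt)
      iso_truth <- rbind(iso_truth, data.frame(
        taxon = taxon, transcript = tid, op = io$op,
        exon = io$exon %||% NA_integer_, stringsAsFactors = FALSE))
    }
    names(transcripts) <- paste(taxon, names(transcripts), sep = ".")
    if (!is.null(iso_truth))
      iso_truth$transcript <- paste(taxon, iso_truth$transcript, sep = ".")
  }

  model <- gene_model(
    taxon = taxon, gene_id = paste0(taxon, "_g1"),
    exons = exons, gene_seq = gene_seq,
    scaffold = paste0(taxon, "_scaf1"),
    span = c(offset, offset + nchar(gene_seq)), strand = "+",
    flank_seq = frame, flank_offset = offset,
    transcripts = transcripts)
  list(model = model, te = te_reg, dup = dup_truth, iso = iso_truth)
}

#' @noRd
apply_isoform_op <- function(exons, io) {
  n <- nrow(exons)
  ex <- exons
  switch(io$op,
    skip_exon = ex[-io$exon, , drop = FALSE],
    alt_donor = {                      # shift the donor of intron `exon`
      ex[io$exon, 2L] <- ex[io$exon, 2L] + io$shift
      ex
    },
    alt_acceptor = {
      ex[io$exon + 1L, 1L] <- ex[io$exon + 1L, 1L] + io$shift
      ex
    },
    retain_intron = {
      ex[io$exon, 2L] <- ex[io$exon + 1L, 2L]
      ex[-(io$exon + 1L), , drop = FALSE]
    },
    mutually_exclusive = {
      # replace exon `exon` with a novel exon inside the preceding intron
      istart <- ex[io$exon - 1L, 2L]; iend <- ex[io$exon, 1L]
      w <- min(60L, (iend - istart) %/% 3L)
      ns <- istart + (iend - istart) %/% 3L
      ex[io$exon, ] <- c(ns, ns + w)
      ex[order(ex[, 1L]), , drop = FALSE]
    },
    alt_first = {                      # start `offset` nt before exon end
      first <- c(ex[io$exon, 2L] - io$offset, ex[io$exon, 2L])
      rbind(first, ex[seq_len(n) > io$exon, , drop = FALSE])
    },
    stop(sprintf("unknown isoform op '%s'", io$op)))
}
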