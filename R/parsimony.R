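# Ancestral reconstruction of intron presence/absence on a rooted species
# tree. Two methods: Dollo parsimony (each site gained exactly once, lost
# freely; the default, since intronless is taken as the ancestral form) and
# Fitch/Sankoff unit-cost parsimony with the root state constrained.

#' @noRd
tree_index <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  nall <- ntip + nnode
  parent <- integer(nall); parent[] <- NA_integer_
  children <- vector("list", nall)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]; c <- tree$edge[k, 2L]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  # ape's postorder edge list places every edge of a subtree before the
  # edge entering it, so the child column (plus the root) is a postorder
  # node sequence: children always precede their parent.
  po <- ape::reorder.phylo(tree, "postorder")
  postorder <- c(po$edge[, 2L], ntip + 1L)
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else sprintf("N%02d", seq_len(nnode)))
  list(ntip = ntip, nall = nall, root = ntip + 1L, parent = parent,
       children = children, postorder = postorder, labels = labels)
}

#' @noRd
validate_matrix_tree <- function(mat, tree) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("presence matrix needs taxon rownames and site colnames")
  extra_mat <- setdiff(rownames(mat), tree$tip.label)
  if (length(extra_mat))
    stop("matrix taxa missing from tree: ", paste(extra_mat, collapse = ", "))
  extra_tree <- setdiff(tree$tip.label, rownames(mat))
  if (length(extra_tree))
    warning("tree leaves without gene models (treated as missing data): ",
            paste(extra_tree, collapse = ", "))
  invisible(TRUE)
}

#' @noRd
leaf_states <- function(mat, idx) {
  # nall x nsites matrix of 0/1/NA; internal nodes NA for now
  st <- matrix(NA_real_, nrow = idx$nall, ncol = ncol(mat))
  pos <- match(idx$labels[seq_len(idx$ntip)], rownames(mat))
  have <- !is.na(pos)
  st[seq_len(idx$ntip)[have], ] <- as.matrix(mat[pos[have], , drop = FALSE])
  st
}

#' Dollo parsimony reconstruction of intron sites
#'
#' Under the Dollo constraint each site is gained exactly once: the gain is
#' placed on the branch entering the most recent common ancestor of all
#' leaves carrying the site, and losses on the maximal subtrees below that
#' node containing no carrier. Taxa with a missing gene (`NA` rows) are
#' excluded per site rather than coded absent. Sites with zero carriers are
#' dropped with a warning. A gain whose MRCA is the root is reported with
#' `at_root = TRUE` ("gained at or before the root").
#'
#' @param mat binary presence/absence matrix (taxa x sites; `NA` = missing
#'   data), e.g. from [build_presence_matrix()].
#' @param tree rooted `phylo` tree with labeled internal nodes
#'   ([parse_newick()]).
#' @return an `event_history`: list with `method`, `tree`, `node_states`
#'   (nodes x sites, rownames = tip then node labels), `events` data.frame
#'   (`site`, `branch` = label of the child node of the branch, `type`
#'   gain/loss, `at_root`), and `node_counts` (introns per node).
#' @export
dollo_reconstruct <- function(mat, tree, root_state = "absent") {
  stopifnot(identical(root_state, "absent"))
  tree <- ensure_node_labels(tree)
  validate_matrix_tree(mat, tree)
  idx <- tree_index(tree)
  st <- leaf_states(mat, idx)

  node_states <- matrix(0, nrow = idx$nall, ncol = ncol(mat),
                        dimnames = list(idx$labels, colnames(mat)))
  events <- list()
  dropped <- character(0)

  for (s in seq_len(ncol(mat))) {
    x <- st[, s]
    pres <- sum(x[seq_len(idx$ntip)] == 1, na.rm = TRUE)
    if (pres == 0L) { dropped <- c(dropped, colnames(mat)[s]); next }
    # postorder tallies of carrier and observed leaves per subtree
    ncar <- integer(idx$nall); nobs <- integer(idx$nall)
    for (v in idx$postorder) {
      if (v <= idx$ntip) {
        ncar[v] <- as.integer(!is.na(x[v]) && x[v] == 1)
        nobs[v] <- as.integer(!is.na(x[v]))
      } else {
        ncar[v] <- sum(ncar[idx$children[[v]]])
        nobs[v] <- sum(nobs[idx$children[[v]]])
      }
    }
    # MRCA of carriers: ascend from any carrier until all are covered
    v <- which(x == 1 & seq_len(idx$nall) <= idx$ntip)[1L]
    while (ncar[v] < pres) v <- idx$parent[v]
    mrca <- v
    events[[length(events) + 1L]] <- data.frame(
      site = colnames(mat)[s], branch = idx$labels[mrca], type = "gain",
      at_root = mrca == idx$root, stringsAsFactors = FALSE)
    # states and losses: preorder walk below the MRCA
    stack <- mrca
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      node_states[v, s] <- 1
      for (ch in idx$children[[v]]) {
        if (ncar[ch] > 0L) {
          stack <- c(stack, ch)
        } else if (nobs[ch] > 0L) {  # maximal carrier-free observed subtree
          events[[length(events) + 1L]] <- data.frame(
            site = colnames(mat)[s], branch = idx$labels[ch], type = "loss",
            at_root = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    # leaves keep their observed coding (NA where missing)
    node_states[seq_len(idx$ntip), s] <- x[seq_len(idx$ntip)]
  }
  if (length(dropped))
    warning("dropped site(s) with zero presences: ",
            paste(dropped, collapse = ", "))
  finish_history("dollo", tree, node_states, events, dropped)
}

#' Constrained Fitch (Sankoff unit-cost) reconstruction
#'
#' Minimum-change reconstruction of each binary site with the root state
#' forced to `root_constraint`. Ambiguous assignments are resolved by
#' ACCTRAN (changes pushed toward the root; the default) or DELTRAN
#' (changes delayed toward the tips).
#'
#' @inheritParams dollo_reconstruct
#' @param root_constraint `"absent"` or `"present"`.
#' @param tiebreak `"ACCTRAN"` or `"DELTRAN"`.
#' @return an `event_history` (see [dollo_reconstruct()]).
#' @export
fitch_reconstruct <- function(mat, tree, root_constraint = "absent",
                              tiebreak = c("ACCTRAN", "DELTRAN")) {
  tiebreak <- match.arg(tiebreak)
  root_s <- if (identical(root_constraint, "absent")) 1L else 2L  # col index
  tree <- ensure_node_labels(tree)
  validate_matrix_tree(mat, tree)
  idx <- tree_index(tree)
  st <- leaf_states(mat, idx)

  node_states <- matrix(0, nrow = idx$nall, ncol = ncol(mat),
                        dimnames = list(idx$labels, colnames(mat)))
  events <- list()
  dropped <- character(0)

  for (s in seq_len(ncol(mat))) {
    x <- st[, s]
    if (sum(x[seq_len(idx$ntip)] == 1, na.rm = TRUE) == 0L) {
      dropped <- c(dropped, colnames(mat)[s]); next
    }
    cost <- matrix(0, nrow = idx$nall, ncol = 2L)  # states 0, 1
    for (v in idx$postorder) {
      if (v <= idx$ntip) {
        if (!is.na(x[v])) {
          cost[v, ] <- if (x[v] == 1) c(Inf, 0) else c(0, Inf)
        }
      } else {
        for (ch in idx$children[[v]]) {
          cost[v, 1L] <- cost[v, 1L] + min(cost[ch, 1L], cost[ch, 2L] + 1)
          cost[v, 2L] <- cost[v, 2L] + min(cost[ch, 2L], cost[ch, 1L] + 1)
        }
      }
    }
    assign <- integer(idx$nall)
    assign[idx$root] <- root_s - 1L
    stack <- idx$root
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (ch in idx$children[[v]]) {
        ps <- assign[v]
        c0 <- cost[ch, 1L] + as.numeric(ps != 0L)
        c1 <- cost[ch, 2L] + as.numeric(ps != 1L)
        if (c0 == c1) {
          assign[ch] <- if (tiebreak == "ACCTRAN") 1L - ps else ps
        } else {
          assign[ch] <- if (c0 < c1) 0L else 1L
        }
        if (assign[ch] != ps) {
          events[[length(events) + 1L]] <- data.frame(
            site = colnames(mat)[s], branch = idx$labels[ch],
            type = if (assign[ch] == 1L) "gain" else "loss",
            at_root = FALSE, stringsAsFactors = FALSE)
        }
        if (ch > idx$ntip) stack <- c(stack, ch)
      }
    }
    node_states[, s] <- assign
    node_states[seq_len(idx$ntip), s] <- x[seq_len(idx$ntip)]
  }
  if (length(dropped))
    warning("dropped site(s) with zero presences: ",
            paste(dropped, collapse = ", "))
  finish_history("fitch", tree, node_states, events, dropped,
                 tiebreak = tiebreak)
}

#' @noRd
finish_history <- function(method, tree, node_states, events, dropped,
                           tiebreak = NULL) {
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(site = character(0), branch = character(0),
               type = character(0), at_root = logical(0))
  structure(list(method = method, tiebreak = tiebreak, tree = tree,
                 node_states = node_states, events = ev,
                 dropped_sites = dropped,
                 node_counts = rowSums(node_states == 1, na.rm = TRUE)),
            class = "event_history")
}

#' @export
print.event_history <- function(x, ...) {
  cat(sprintf("<event_history> %s parsimony: %d sites, %d gains, %d losses\n",
              x$method, ncol(x$node_states),
              sum(x$events$type == "gain"), sum(x$events$type == "loss")))
  invisible(x)
}

#' Intron count reconstructed at an ancestral node
#'
#' @param history an `event_history` from [dollo_reconstruct()] or
#'   [fitch_reconstruct()].
#' @param node a node label (internal node or tip).
#' @return integer count of sites reconstructed present at that node.
#' @export
ancestral_intron_count <- function(history, node) {
  if (!node %in% rownames(history$node_states))
    stop(sprintf("unknown node label '%s'", node))
  sum(history$node_states[node, ] == 1, na.rm = TRUE)
}

#' Per-branch event summary
#'
#' One row per branch carrying events, with the `+gains/-losses` shorthand
#' used in gain/loss schematics.
#'
#' @param history an `event_history`.
#' @return data.frame with `branch`, `gains`, `losses`, `summary`.
#' @export
branch_event_summary <- function(history) {
  ev <- history$events
  if (nrow(ev) == 0L)
    return(data.frame(branch = character(0), gains = integer(0),
                      losses = integer(0), summary = character(0)))
  agg <- stats::aggregate(cbind(gains = ev$type == "gain",
                                losses = ev$type == "loss"),
                          by = list(branch = ev$branch), FUN = sum)
  agg$summary <- paste0(ifelse(agg$gains > 0, paste0("+", agg$gains), ""),
                        ifelse(agg$gains > 0 & agg$losses > 0, "/", ""),
                        ifelse(agg$losses > 0, paste0("-", agg$losses), ""))
  agg
}

#' @noRd
annotated_newick <- function(history) {
  tree <- history$tree
  cnt <- history$node_counts
  labs <- rownames(history$node_states)
  ntip <- ape::Ntip(tree)
  tree$node.label <- sprintf("%s_%d", labs[(ntip + 1):length(labs)],
                             cnt[(ntip + 1):length(labs)])
  ape::write.tree(tree)
}

#' Flag sites whose event placement is method-sensitive
#'
#' Marks sites whose reconstructed event set differs between Dollo and
#' constrained-Fitch parsimony; such placements are low-confidence.
#'
#' @inheritParams dollo_reconstruct
#' @return named logical vector over sites.
#' @export
flag_method_sensitive <- function(mat, tree) {
  d <- suppressWarnings(dollo_reconstruct(mat, tree))
  f <- suppressWarnings(fitch_reconstruct(mat, tree))
  vapply(colnames(mat), function(s) {
    ed <- d$events[d$events$site == s, c("branch", "type")]
    ef <- f$events[f$events$site == s, c("branch", "type")]
    !identical(ed[order(ed$branch, ed$type), ],
               ef[order(ef$branch, ef$type), ]) &&
      !(nrow(ed) == nrow(ef) &&
          all(sort(paste(ed$branch, ed$type)) == sort(paste(ef$branch, ef$type))))
  }, logical(1))
}
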