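#' Parsimony reconstruction of character evolution on species trees
#'
#' Presence/absence characters (e.g. "does this lineage retain the gene, or a
#' particular protein form") are reconstructed under Dollo parsimony: a single
#' gain at the most recent common ancestor of the tips carrying the character,
#' followed by an unlimited number of independent losses. Multistate
#' architecture characters are reconstructed under Fitch parsimony
#' (minimum-change), generalised to polytomies. Missing data (`?`) is
#' unconstrained: an unsampled or unsequenced tip never forces a loss or a
#' change.
#'
#' Trees are `ape::phylo` objects; node references in the results use ape's
#' node numbering (tips `1..n`, internal nodes `n+1..`), with labels reported
#' where present.
#'
#' @name phyletics
NULL

#' Read a rooted tree from a newick file
#'
#' Wraps [ape::read.tree()] with stricter validation: unbalanced parentheses
#' are reported with their character position, duplicate leaf names are an
#' error, and the tree must have at least one leaf. Branch lengths are parsed
#' but unused. Basal polytomies are allowed.
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced ')' at character ", i, " of ", path,
                         call. = FALSE)
  }
  if (depth != 0L) stop("unbalanced '(' in ", path, ": ", depth,
                        " unclosed at end of file", call. = FALSE)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("cannot parse newick in ", path, call. = FALSE)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    stop("duplicate leaf name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  invisible(tree)
}

#' Write a tree to a newick file
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# children of each node as a list indexed by node number
node_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

root_node <- function(tree) {
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
}

node_label <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  lab <- tree$node.label[node - ntip]
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) paste0("node", node) else lab
}

# match a named state vector against the tree tips; error on unknown tips
match_states <- function(tree, states) {
  unknown <- setdiff(names(states), tree$tip.label)
  if (length(unknown) > 0) {
    stop("tip(s) in state table but not in tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- setNames(rep("?", ape::Ntip(tree)), tree$tip.label)
  out[names(states)] <- as.character(states)
  out
}

#' Dollo parsimony for a presence/absence character
#'
#' Places the single gain at the most recent common ancestor of all tips with
#' state 1. Within the gain clade, a node is *retaining* iff at least one
#' descendant tip (or the node itself, for tips) has state 1. A loss is
#' placed on every edge from a retaining node to a child whose subtree
#' contains no state-1 tip but at least one definite state-0 tip; subtrees
#' containing only `?` tips are unconstrained and never charged a loss. This
#' yields the minimum number of losses compatible with a single gain.
#'
#' @param tree An `ape::phylo` tree.
#' @param states Named vector over (a subset of) the tips with values `"1"`,
#'   `"0"` or `"?"` (numeric 0/1 accepted); missing tips are treated as `?`.
#' @return List with `gain_node` (number or `NA`), `gain_label`,
#'   `loss_edges` (`data.frame` of `parent`, `child`, `child_label`),
#'   `n_losses`.
#' @export
dollo_reconstruct <- function(tree, states) {
  validate_tree(tree)
  st <- match_states(tree, states)
  ntip <- ape::Ntip(tree)
  ones <- which(st == "1")
  if (length(ones) == 0) {
    return(list(gain_node = NA_integer_, gain_label = NA_character_,
                loss_edges = data.frame(parent = integer(), child = integer(),
                                        child_label = character()),
                n_losses = 0L))
  }
  gain <- if (length(ones) == 1) ones[1] else ape::getMRCA(tree, ones)
  kids <- node_children(tree)
  n_nodes <- ntip + tree$Nnode
  has_one <- logical(n_nodes)   # subtree contains a state-1 tip
  has_zero <- logical(n_nodes)  # subtree contains a definite state-0 tip
  has_one[seq_len(ntip)] <- st == "1"
  has_zero[seq_len(ntip)] <- st == "0"
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]; ch <- po[i, 2]
    has_one[p] <- has_one[p] || has_one[ch]
    has_zero[p] <- has_zero[p] || has_zero[ch]
  }
  # walk the gain clade top-down, charging losses at the tops of maximal
  # no-presence subtrees that contain a definite absence
  loss <- list()
  visit <- gain
  while (length(visit) > 0) {
    node <- visit[1]; visit <- visit[-1]
    for (ch in kids[[node]]) {
      if (has_one[ch]) {
        visit <- c(visit, ch)
      } else if (has_zero[ch]) {
        loss[[length(loss) + 1L]] <- c(node, ch)
      } # all-? subtree: unconstrained, no loss charged
    }
  }
  loss_df <- if (length(loss) == 0) {
    data.frame(parent = integer(), child = integer(),
               child_label = character(), stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, loss)
    data.frame(parent = m[, 1], child = m[, 2],
               child_label = vapply(m[, 2], function(x) node_label(tree, x), ""),
               stringsAsFactors = FALSE)
  }
  list(gain_node = gain, gain_label = node_label(tree, gain),
       loss_edges = loss_df, n_losses = nrow(loss_df))
}

#' Fitch parsimony for a multistate character
#'
#' Two-pass minimum-change reconstruction generalised to polytomies
#' (Hartigan's method): in the bottom-up pass the candidate set of a node is
#' the set of states attaining the maximum count over its children's sets,
#' and the change count is incremented by (number of children minus that
#' maximum count); on binary nodes this reduces to the familiar
#' intersection/union rule with one change per union event. `?` tips carry
#' the full observed state set. The top-down pass returns one optimal
#' labeling, breaking ties towards the lexicographically smallest state.
#'
#' @param tree An `ape::phylo` tree.
#' @param states Named character vector over (a subset of) the tips; `"?"` or
#'   missing tips are unconstrained.
#' @return List with `n_changes` and `labeling` (named character vector over
#'   all nodes, names are tip labels / `nodeN`).
#' @export
fitch_count <- function(tree, states) {
  validate_tree(tree)
  st <- match_states(tree, states)
  ntip <- ape::Ntip(tree)
  alphabet <- sort(unique(st[st != "?"]))
  if (length(alphabet) == 0) stop("no labeled tips", call. = FALSE)
  n_nodes <- ntip + tree$Nnode
  sets <- vector("list", n_nodes)
  for (i in seq_len(ntip)) {
    sets[[i]] <- if (st[i] == "?") alphabet else st[i]
  }
  kids <- node_children(tree)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  internal <- unique(po[, 1])
  n_changes <- 0L
  for (node in internal) {
    counts <- table(unlist(sets[kids[[node]]]))
    k <- max(counts)
    sets[[node]] <- sort(names(counts)[counts == k])
    n_changes <- n_changes + (length(kids[[node]]) - k)
  }
  # top-down pass
  labeling <- character(n_nodes)
  root <- root_node(tree)
  labeling[root] <- sets[[root]][1]
  pre <- rev(internal)  # parents before children among internals
  for (node in pre) {
    for (ch in kids[[node]]) {
      labeling[ch] <- if (labeling[node] %in% sets[[ch]]) labeling[node]
                      else sets[[ch]][1]
    }
  }
  names(labeling) <- vapply(seq_len(n_nodes),
                            function(x) node_label(tree, x), "")
  list(n_changes = as.integer(n_changes), labeling = labeling)
}

#' Dollo gain/loss report over a phyletic matrix
#'
#' Runs [dollo_reconstruct()] on every column of a presence/absence matrix
#' and tabulates per-character gains and losses plus the grand total of
#' independent loss events.
#'
#' @param tree An `ape::phylo` tree.
#' @param matrix `data.frame` or matrix of tip x character states over
#'   \{0, 1, ?\}, with row names (or an `id` column) naming tips.
#' @return List with `per_character` (`data.frame`: `character`, `gain_node`,
#'   `gain_label`, `n_losses`), `total_losses`, and `reconstructions` (named
#'   list of full results).
#' @export
count_total_losses <- function(tree, matrix) {
  mat <- as.data.frame(matrix, stringsAsFactors = FALSE)
  if ("id" %in% names(mat)) {
    rownames(mat) <- mat$id
    mat$id <- NULL
  }
  recs <- lapply(names(mat), function(ch) {
    dollo_reconstruct(tree, setNames(as.character(mat[[ch]]), rownames(mat)))
  })
  names(recs) <- names(mat)
  per <- data.frame(
    character = names(mat),
    gain_node = vapply(recs, function(r) r$gain_node, 1L),
    gain_label = vapply(recs, function(r) r$gain_label, ""),
    n_losses = vapply(recs, function(r) r$n_losses, 1L),
    stringsAsFactors = FALSE)
  list(per_character = per, total_losses = sum(per$n_losses),
       reconstructions = recs)
}

#' Read a tip-state matrix from a TSV file
#'
#' First column `tip`, remaining columns one character each; states are kept
#' as character (`0`, `1`, `?`, or class labels).
#'
#' @param path Path to the TSV.
#' @return `data.frame` with tips as row names.
#' @export
read_states <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE)
  if (names(tab)[1] != "tip") stop("state table must have first column 'tip'",
                                   call. = FALSE)
  rownames(tab) <- tab$tip
  tab$tip <- NULL
  tab
}

#' Write a tip-state matrix to a TSV file
#'
#' @param matrix `data.frame` with tips as row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_states <- function(matrix, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("tip", names(matrix)), collapse = "\t"), con)
  for (i in seq_len(nrow(matrix))) {
    writeLines(paste(c(rownames(matrix)[i],
                       as.character(unlist(matrix[i, ]))), collapse = "\t"),
               con)
  }
  invisible(path)
}
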