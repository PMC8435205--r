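#' Rooted tree with node-support annotations
#'
#' Wraps an `ape` phylo object together with per-internal-node support values
#' parsed from node labels of the form `"GB/bootstrap"` (Goodman-Bremer value
#' and bootstrap resampling frequency in percent); either field may be
#' absent.
#'
#' @param phy an `ape::phylo` object (rooted; polytomies allowed).
#' @param support optional data.frame (`node`, `gb`, `bootstrap`); if `NULL`,
#'   parsed from `phy$node.label`.
#' @param label_pattern separator between the support fields in node labels.
#' @return object of class `annotated_tree` with `$phy` and `$support`.
#' @export
annotated_tree <- function(phy, support = NULL, label_pattern = "/") {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape phylo object")
  if (anyDuplicated(phy$tip.label)) stop("terminal labels must be unique")
  if (is.null(support)) {
    support <- parse_support_labels(phy, label_pattern)
  }
  if (any(!is.na(support$bootstrap) &
          (support$bootstrap < 0 | support$bootstrap > 100))) {
    stop("bootstrap frequencies must lie in [0, 100]")
  }
  structure(list(phy = phy, support = support), class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat(sprintf("annotated_tree: %d terminals, %d internal nodes (%d with support)\n",
              length(x$phy$tip.label), x$phy$Nnode,
              sum(!is.na(x$support$gb) | !is.na(x$support$bootstrap))))
  invisible(x)
}

parse_support_labels <- function(phy, label_pattern = "/") {
  n_tip <- length(phy$tip.label)
  nodes <- n_tip + seq_len(phy$Nnode)
  gb <- rep(NA_real_, phy$Nnode)
  bs <- rep(NA_real_, phy$Nnode)
  labs <- phy$node.label
  if (!is.null(labs)) {
    for (i in seq_along(labs)) {
      lab <- labs[i]
      if (is.na(lab) || !nzchar(lab)) next
      parts <- strsplit(lab, label_pattern, fixed = TRUE)[[1]]
      gb[i] <- suppressWarnings(as.numeric(parts[1]))
      if (length(parts) >= 2) {
        bs[i] <- suppressWarnings(as.numeric(parts[2]))
      }
    }
  }
  data.frame(node = nodes, gb = gb, bootstrap = bs)
}

#' Read a Newick tree with support-annotated node labels
#'
#' @param path Newick file; internal node labels are parsed as
#'   `"GB/bootstrap"`.
#' @param label_pattern separator between the two support fields.
#' @return an [annotated_tree()].
#' @export
read_annotated_tree <- function(path, label_pattern = "/") {
  annotated_tree(ape::read.tree(path), label_pattern = label_pattern)
}

#' Re-root an annotated tree on an outgroup
#'
#' @param atree an [annotated_tree()].
#' @param outgroup tip label(s) of the outgroup.
#' @return re-rooted `annotated_tree` (node supports re-parsed from labels,
#'   which ape carries through re-rooting).
#' @export
root_on_outgroup <- function(atree, outgroup) {
  phy <- ape::root(atree$phy, outgroup = outgroup, resolve.root = TRUE)
  annotated_tree(phy)
}

# children of each node as a list indexed by node id
children_list <- function(phy) {
  n_node <- max(phy$edge)
  kids <- vector("list", n_node)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[e, 2])
  }
  kids
}

# parent of each node (NA for the root)
parent_vector <- function(phy) {
  n_node <- max(phy$edge)
  par <- rep(NA_integer_, n_node)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

root_node <- function(phy) length(phy$tip.label) + 1L

# tip indices descending from each node
descendant_tips <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- max(phy$edge)
  post <- ape::reorder.phylo(phy, "postorder")$edge
  desc <- vector("list", n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  for (e in seq_len(nrow(post))) {
    desc[[post[e, 1]]] <- c(desc[[post[e, 1]]], desc[[post[e, 2]]])
  }
  desc
}

#' Check whether a terminal set is monophyletic
#'
#' True iff the most recent common ancestor of the set has exactly that set
#' as terminal descendants. A singleton is monophyletic (its own leaf).
#'
#' @param tree an [annotated_tree()] or `phylo`.
#' @param terminals character vector of tip labels.
#' @return list `monophyletic` (logical), `mrca` (node id; the tip itself for
#'   a singleton), `intruders` (tip labels under the MRCA but outside the
#'   set).
#' @export
check_monophyly <- function(tree, terminals) {
  phy <- if (inherits(tree, "annotated_tree")) tree$phy else tree
  idx <- match(terminals, phy$tip.label)
  if (anyNA(idx)) {
    stop("unknown terminal(s): ",
         paste(terminals[is.na(idx)], collapse = ", "))
  }
  if (length(idx) == 1) {
    return(list(monophyletic = TRUE, mrca = idx, intruders = character(0)))
  }
  mrca <- ape::getMRCA(phy, idx)
  tips <- descendant_tips(phy)[[mrca]]
  intr <- setdiff(tips, idx)
  list(monophyletic = length(intr) == 0, mrca = mrca,
       intruders = phy$tip.label[intr])
}

#' Support values at a node
#'
#' @param atree an [annotated_tree()].
#' @param node internal node id.
#' @return list `gb`, `bootstrap` (NA when the node is a tip or unlabelled).
#' @export
node_support <- function(atree, node) {
  row <- atree$support[atree$support$node == node, ]
  if (nrow(row) == 0) return(list(gb = NA_real_, bootstrap = NA_real_))
  list(gb = row$gb, bootstrap = row$bootstrap)
}

# length of the stem branch subtending a node (NA for the root)
stem_length <- function(phy, node) {
  if (is.null(phy$edge.length)) return(NA_real_)
  e <- which(phy$edge[, 2] == node)
  if (!length(e)) return(NA_real_)
  phy$edge.length[e]
}
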