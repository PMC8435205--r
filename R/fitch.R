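# Unit-cost (Fitch) parsimony over the five-state alphabet, with exact
# handling of polytomies and ambiguous terminals, most-parsimonious
# reconstruction (MPR) sets via a down/up dynamic program, and exact MPR
# enumeration by top-down backtracking over per-node optimal choices.

BIG <- 1e9  # effectively infinite cost

# column as integer bitmasks aligned to tree tip order
column_for_tree <- function(phy, column) {
  if (is.null(names(column))) stop("column must be named by terminal")
  idx <- match(phy$tip.label, names(column))
  if (anyNA(idx)) {
    stop("terminal(s) missing from column: ",
         paste(phy$tip.label[is.na(idx)], collapse = ", "))
  }
  col <- as.integer(column[idx])
  if (any(is.na(col) | col <= 0L)) stop("state sets must be non-empty")
  col
}

# postorder sequence of internal nodes (children before parents)
postorder_nodes <- function(phy) {
  post <- ape::reorder.phylo(phy, "postorder")$edge
  unique(post[, 1])
}

#' Fitch down-pass with Hartigan's multifurcation rule
#'
#' Computes per-node preliminary state sets and the parsimony length of one
#' alignment column on a rooted tree. Binary nodes follow the classic Fitch
#' intersection/union rule; multifurcations use the state-frequency
#' (Hartigan) generalization, which keeps the length exact. Ambiguous
#' terminals contribute their whole state set.
#'
#' @param tree an [annotated_tree()] or `phylo`.
#' @param column named integer vector of state-set bitmasks (see
#'   [encode_states()]), one per terminal.
#' @return list `node_sets` (bitmask per node, tips first) and `length`.
#' @export
fitch_downpass <- function(tree, column) {
  phy <- if (inherits(tree, "annotated_tree")) tree$phy else tree
  col <- column_for_tree(phy, column)
  n_tip <- length(phy$tip.label)
  n_node <- max(phy$edge)
  sets <- integer(n_node)
  sets[seq_len(n_tip)] <- col
  kids <- children_list(phy)
  len <- 0L
  for (u in postorder_nodes(phy)) {
    counts <- integer(5)
    for (v in kids[[u]]) {
      counts <- counts + as.integer(bitwAnd(sets[v], STATE_BITS) > 0)
    }
    m <- max(counts)
    sets[u] <- sum(STATE_BITS[counts == m])
    len <- len + length(kids[[u]]) - m
  }
  list(node_sets = sets, length = len)
}

# Unit-cost Sankoff tables. Returns:
#   cost[node, s]  min cost of node's subtree with node in state s
#   aux[node, s]   min cost of the rest of the tree given node in state s
#   f = cost + aux total-tree cost with node pinned to s; L = min f(root, .)
sankoff_tables <- function(phy, col) {
  n_tip <- length(phy$tip.label)
  n_node <- max(phy$edge)
  kids <- children_list(phy)
  cost <- matrix(BIG, n_node, 5)
  for (i in seq_len(n_tip)) {
    cost[i, bitwAnd(col[i], STATE_BITS) > 0] <- 0
  }
  post <- postorder_nodes(phy)
  for (u in post) {
    acc <- numeric(5)
    for (v in kids[[u]]) {
      acc <- acc + pmin(cost[v, ], min(cost[v, ]) + 1)
    }
    cost[u, ] <- acc
  }
  root <- root_node(phy)
  L <- min(cost[root, ])
  aux <- matrix(BIG, n_node, 5)
  aux[root, ] <- 0
  pre <- rev(post)  # parents before children
  for (u in pre) {
    for (v in kids[[u]]) {
      contrib_v <- pmin(cost[v, ], min(cost[v, ]) + 1)
      rest <- cost[u, ] - contrib_v + aux[u, ]
      aux[v, ] <- pmin(rest, min(rest) + 1)
    }
  }
  list(cost = cost, aux = aux, length = L, root = root)
}

# per-node MPR state sets (states appearing in >= 1 MPR), as bitmasks
mpr_state_sets <- function(phy, col) {
  st <- sankoff_tables(phy, col)
  f <- st$cost + st$aux
  n_node <- nrow(f)
  vapply(seq_len(n_node), function(v) {
    sum(STATE_BITS[f[v, ] <= st$length + 1e-9])
  }, numeric(1))
}

# state pairs (parent t, child s) realizable on an edge in some MPR
edge_state_pairs <- function(phy, col, child) {
  st <- sankoff_tables(phy, col)
  u <- parent_vector(phy)[child]
  if (is.na(u)) stop("node is the root; it has no stem edge")
  contrib_v <- pmin(st$cost[child, ], min(st$cost[child, ]) + 1)
  rest <- st$cost[u, ] - contrib_v + st$aux[u, ]
  pairs <- which(outer(rest, st$cost[child, ],
                       function(rt, cs) rt + cs) +
                   (1 - diag(5)) <= st$length + 1e-9, arr.ind = TRUE)
  data.frame(parent_state = STATE_CHARS[pairs[, 1]],
             child_state = STATE_CHARS[pairs[, 2]],
             stringsAsFactors = FALSE)
}

#' Enumerate most-parsimonious reconstructions of a column
#'
#' Exhaustive mode enumerates every minimum-length assignment of states to
#' all nodes (ambiguous terminals included) by backtracking over the
#' per-node optimal choices of the unit-cost dynamic program — exact, and
#' far cheaper than scanning all labelings. Up-pass mode returns only the
#' per-node MPR state sets (states appearing in at least one MPR).
#'
#' @param tree an [annotated_tree()] or `phylo`.
#' @param column named bitmask vector (see [fitch_downpass()]).
#' @param max_nodes exhaustive mode refuses trees with more internal nodes
#'   than this (default 20); use up-pass mode beyond.
#' @param mode `"exhaustive"` or `"uppass"`.
#' @param max_mprs hard cap on the number of enumerated reconstructions.
#' @return exhaustive mode: list `labelings` (matrix, one row per MPR, one
#'   column per node, entries in `A C G T -`), `length`; up-pass mode: list
#'   `mpr_sets` (bitmask per node), `length`.
#' @export
enumerate_mprs <- function(tree, column, max_nodes = 20,
                           mode = c("exhaustive", "uppass"),
                           max_mprs = 100000) {
  mode <- match.arg(mode)
  phy <- if (inherits(tree, "annotated_tree")) tree$phy else tree
  col <- column_for_tree(phy, column)
  if (mode == "uppass") {
    st <- sankoff_tables(phy, col)
    return(list(mpr_sets = mpr_state_sets(phy, col), length = st$length))
  }
  if (phy$Nnode > max_nodes) {
    stop("tree has ", phy$Nnode, " internal nodes (> max_nodes = ",
         max_nodes, "); use mode = 'uppass'")
  }
  st <- sankoff_tables(phy, col)
  kids <- children_list(phy)
  n_node <- max(phy$edge)
  root <- st$root
  # preorder expansion: partial labelings grow one node at a time
  pre <- integer(0)
  stack <- root
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, u)
    stack <- c(stack, kids[[u]])
  }
  root_states <- which(st$cost[root, ] <= st$length + 1e-9)
  labelings <- matrix(NA_integer_, length(root_states), n_node)
  labelings[, root] <- root_states
  for (u in pre) {
    for (v in kids[[u]]) {
      grown <- vector("list", nrow(labelings))
      for (r in seq_len(nrow(labelings))) {
        t <- labelings[r, u]
        opts <- st$cost[v, ] + (seq_len(5) != t)
        allowed <- which(opts <= min(opts) + 1e-9)
        block <- labelings[rep(r, length(allowed)), , drop = FALSE]
        block[, v] <- allowed
        grown[[r]] <- block
      }
      labelings <- do.call(rbind, grown)
      if (nrow(labelings) > max_mprs) {
        stop("more than max_mprs = ", max_mprs,
             " reconstructions; raise the cap or use mode = 'uppass'")
      }
    }
  }
  lab <- matrix(STATE_CHARS[labelings], nrow(labelings), n_node)
  list(labelings = lab, length = st$length)
}

# per-MPR bookkeeping for one state character s:
#   origins = edges gaining s (parent != s, child == s), root counted as an
#   origin when assigned s; losses = edges losing s
state_history <- function(phy, labeling, s) {
  par <- parent_vector(phy)
  child_nodes <- which(!is.na(par))
  gains <- sum(labeling[par[child_nodes]] != s & labeling[child_nodes] == s)
  losses <- sum(labeling[par[child_nodes]] == s & labeling[child_nodes] != s)
  root <- root_node(phy)
  list(origins = gains + (labeling[root] == s), losses = losses)
}
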