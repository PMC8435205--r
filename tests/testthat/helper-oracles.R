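# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-pair loops, exhaustive enumeration) so they check
# the package implementations from a different route.

# Gower: per-pair loop over jointly observed features, range-normalized
gower_oracle <- function(x) {
  n <- nrow(x)
  rng <- apply(x, 2, function(col) diff(range(col, na.rm = TRUE)))
  rng[rng == 0] <- 1
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- 0
      cnt <- 0
      for (f in seq_len(ncol(x))) {
        if (!is.na(x[i, f]) && !is.na(x[j, f])) {
          num <- num + abs(x[i, f] - x[j, f]) / rng[f]
          cnt <- cnt + 1
        }
      }
      d[i, j] <- num / cnt
    }
  }
  d
}

# Mantel r: explicit double loop over unordered pairs
mantel_r_oracle <- function(dx, dy) {
  n <- nrow(dx)
  vx <- c()
  vy <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      vx <- c(vx, dx[i, j])
      vy <- c(vy, dy[i, j])
    }
  }
  stats::cor(vx, vy)
}

# Welch t statistic, df and two-sided p from the closed form
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# p-distance by explicit character loop
p_distance_oracle <- function(a, b, policy = "pairwise_deletion") {
  mism <- 0
  comp <- 0
  for (k in seq_along(a)) {
    ca <- a[k]
    cb <- b[k]
    if (ca %in% c("?", "N") || cb %in% c("?", "N")) next
    if (policy == "pairwise_deletion" && (ca == "-" || cb == "-")) next
    comp <- comp + 1
    if (ca != cb) mism <- mism + 1
  }
  mism / comp
}

# exhaustive unit-cost parsimony: enumerate all labelings of every node
# (leaves resolved within their observed sets, internal nodes over the
# observed-state union); returns the minimum length and all optimal
# labelings as a matrix of state characters
parsimony_oracle <- function(phy, col_masks) {
  state_chars <- c("A", "C", "G", "T", "-")
  bits <- as.integer(2^(0:4))
  n_tip <- length(phy$tip.label)
  n_node <- max(phy$edge)
  observed <- which(bitwAnd(Reduce(bitwOr, col_masks), bits) > 0)
  domains <- vector("list", n_node)
  for (i in seq_len(n_tip)) {
    domains[[i]] <- which(bitwAnd(col_masks[i], bits) > 0)
  }
  for (v in (n_tip + 1):n_node) domains[[v]] <- observed
  grid <- as.matrix(expand.grid(domains, KEEP.OUT.ATTRS = FALSE))
  costs <- rep(0L, nrow(grid))
  for (e in seq_len(nrow(phy$edge))) {
    costs <- costs + (grid[, phy$edge[e, 1]] != grid[, phy$edge[e, 2]])
  }
  best <- min(costs)
  lab <- matrix(state_chars[grid[costs == best, , drop = FALSE]],
                ncol = n_node)
  list(length = best, labelings = lab)
}

# canonical string form of a labeling set, for set equality checks
labeling_key <- function(m) sort(apply(m, 1, paste, collapse = ""))

# monophyly by scanning every node's descendant tip set
monophyly_oracle <- function(phy, tips) {
  n_tip <- length(phy$tip.label)
  target <- sort(match(tips, phy$tip.label))
  if (length(target) == 1) return(TRUE)
  for (v in (n_tip + 1):max(phy$edge)) {
    desc <- c()
    stack <- v
    while (length(stack)) {
      u <- stack[1]
      stack <- stack[-1]
      kids <- phy$edge[phy$edge[, 1] == u, 2]
      for (k in kids) {
        if (k <= n_tip) desc <- c(desc, k) else stack <- c(stack, k)
      }
    }
    if (identical(sort(desc), target)) return(TRUE)
  }
  FALSE
}

# random state column over a tree's tips; optionally with ambiguity codes
random_column <- function(phy, n_states = 4, amb_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- c("A", "C", "G", "T", "-")[seq_len(n_states)]
  draw <- sample(chars, length(phy$tip.label), replace = TRUE)
  if (amb_prob > 0) {
    amb <- runif(length(draw)) < amb_prob
    draw[amb] <- sample(c("R", "Y", "N"), sum(amb), replace = TRUE)
  }
  encode_states(stats::setNames(draw, phy$tip.label))
}

# small rooted tree with n tips, fixed seed
random_tree <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n, tip.label = LETTERS[seq_len(n)])
  phy$edge.length <- NULL
  phy
}

# tiny 4-species alignment/tree fixture rooted on the outgroup side
toy_diagnosis_fixture <- function() {
  phy <- ape::read.tree(text = "(out,((A1,A2),(B1,B2)));")
  chars <- rbind(
    out = strsplit("GGGGG", "")[[1]],
    A1  = strsplit("TGGAG", "")[[1]],
    A2  = strsplit("TGGAG", "")[[1]],
    B1  = strsplit("GGTAG", "")[[1]],
    B2  = strsplit("GGTAG", "")[[1]]
  )
  sm <- c(out = "out", A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  list(tree = annotated_tree(phy),
       aln = alignment_set(chars, marker = "toy", species_map = sm))
}
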