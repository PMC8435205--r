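#' Gower dissimilarity between specimens
#'
#' For numeric features scaled to a common range, the Gower dissimilarity of
#' two specimens is the mean, over features observed in both, of
#' `|x_if - x_jf| / range_f`. After [minmax_scale()] every range is 1.
#' Handles missing cells by pairwise deletion, so it also serves the
#' no-imputation analysis arm.
#'
#' @param tm a [trait_matrix()] or a plain numeric matrix of scaled values.
#' @return symmetric specimen x specimen dissimilarity matrix with zero
#'   diagonal and entries in `[0, 1]`.
#' @export
gower_distance <- function(tm) {
  x <- if (inherits(tm, "trait_matrix")) tm$values else as.matrix(tm)
  rng <- apply(x, 2, function(col) diff(range(col, na.rm = TRUE)))
  rng[rng == 0] <- 1  # constant feature contributes zero difference
  xs <- sweep(x, 2, rng, "/")
  n <- nrow(xs)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  obs <- !is.na(xs)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      both <- obs[i, ] & obs[j, ]
      if (!any(both)) {
        stop(sprintf("specimens %s and %s share no observed features",
                     rownames(x)[i], rownames(x)[j]))
      }
      d[i, j] <- d[j, i] <- mean(abs(xs[i, both] - xs[j, both]))
    }
  }
  d
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal-style NMDS minimizing stress-1 with monotone regression of
#' disparities, via `vegan::metaMDS` (engine `monoMDS`) with multiple random
#' restarts plus a classical principal-coordinates start; the lowest-stress
#' solution is returned. Deterministic for a fixed seed.
#'
#' @param d symmetric non-negative dissimilarity matrix (or `dist`).
#' @param k target dimension (default 2).
#' @param restarts number of random restarts (default 20).
#' @param seed integer RNG seed.
#' @return object of class `nmds_result`: `points` (n x k specimen scores),
#'   `stress` (Kruskal stress-1, on [0, 1]), `converged`, `k`, `restarts`,
#'   `seed`.
#' @export
nmds <- function(d, k = 2, restarts = 20, seed = 1) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm)) || any(dm < 0)) {
    stop("input must be a symmetric non-negative dissimilarity matrix")
  }
  n <- nrow(dm)
  if (k < 1) stop("k must be >= 1")
  if (n <= 2) {
    pts <- matrix(0, n, k, dimnames = list(rownames(dm), NULL))
    if (n == 2) pts[, 1] <- c(-dm[1, 2], dm[1, 2]) / 2
    return(structure(list(points = pts, stress = 0, converged = TRUE,
                          k = k, restarts = 0L, seed = seed),
                     class = "nmds_result"))
  }
  dd <- stats::as.dist(dm)
  set.seed(seed)
  fit_pcoa <- vegan::monoMDS(dd, y = pcoa_config(dm, k), k = k,
                             model = "global")
  fit_rand <- suppressWarnings(suppressMessages(
    vegan::metaMDS(dd, k = k, trymax = restarts, trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  ))
  best <- if (fit_pcoa$stress <= fit_rand$stress) fit_pcoa else fit_rand
  pts <- best$points
  rownames(pts) <- rownames(dm)
  structure(list(points = pts, stress = best$stress,
                 converged = isTRUE(best$converged) ||
                   is.null(best$converged),
                 k = k, restarts = restarts, seed = seed),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): %d points, stress-1 = %.5f\n",
              x$k, nrow(x$points), x$stress))
  invisible(x)
}

# classical PCoA configuration used as the deterministic NMDS start;
# padded with zero axes if the matrix supports fewer than k dimensions
pcoa_config <- function(dm, k) {
  cfg <- suppressWarnings(stats::cmdscale(dm, k = k))
  if (ncol(cfg) < k) {
    cfg <- cbind(cfg, matrix(0, nrow(cfg), k - ncol(cfg)))
  }
  cfg
}

#' Kruskal stress-1 of a fixed configuration
#'
#' Evaluates the stress of an arbitrary configuration against a dissimilarity
#' matrix without moving the points (monotone regression of disparities is
#' still performed). Used to verify that the optimized solution improves on
#' its start.
#'
#' @param d dissimilarity matrix.
#' @param config n x k coordinate matrix.
#' @return stress-1 value.
#' @export
stress1 <- function(d, config) {
  fit <- vegan::monoMDS(stats::as.dist(as.matrix(d)), y = as.matrix(config),
                        k = ncol(config), model = "global", maxit = 0)
  fit$stress
}

#' Weighted-average feature scores in ordination space
#'
#' Places each feature at the weighted average of specimen scores, the
#' weights being the feature's (nonnegative, scaled) values — the same
#' weighted-averaging used to map variable contributions into an MDS plot.
#'
#' @param ord an [nmds()] result (or any list with `$points`).
#' @param tm the scaled [trait_matrix()] (or matrix) the ordination was
#'   computed from; specimen sets must match.
#' @return data.frame of feature coordinates with a `defined` flag; features
#'   with all-zero weight have `NA` coordinates and `defined = FALSE`.
#' @export
feature_scores <- function(ord, tm) {
  x <- if (inherits(tm, "trait_matrix")) tm$values else as.matrix(tm)
  pts <- ord$points
  if (nrow(x) != nrow(pts) ||
      !all(rownames(x) == rownames(pts))) {
    stop("specimen sets of ordination and trait matrix do not match")
  }
  if (any(x < 0, na.rm = TRUE)) stop("feature weights must be nonnegative")
  tot <- colSums(x, na.rm = TRUE)
  out <- matrix(NA_real_, ncol(x), ncol(pts),
                dimnames = list(colnames(x),
                                paste0("axis", seq_len(ncol(pts)))))
  if (any(tot > 0)) {
    sc <- suppressWarnings(vegan::wascores(pts, x[, tot > 0, drop = FALSE]))
    out[rownames(sc), ] <- sc
  }
  res <- data.frame(feature = colnames(x), out, defined = tot > 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  res
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation `r` of the off-diagonal upper triangles, with a
#' one-tailed ("greater") permutation test: rows and columns of the second
#' matrix are permuted `permutations` times and
#' `p = (1 + #\{r_perm >= r_obs\}) / (permutations + 1)`, so p never reaches
#' zero. Deterministic for a fixed seed.
#'
#' @param dx,dy symmetric distance matrices over the same specimens in the
#'   same order.
#' @param permutations number of permutations (default 9999).
#' @param seed integer RNG seed.
#' @return list `r`, `r_squared`, `p`, `permutations`, `seed`, `n`.
#' @export
mantel_test <- function(dx, dy, permutations = 9999, seed = 1) {
  mx <- as.matrix(dx)
  my <- as.matrix(dy)
  n <- nrow(mx)
  if (n < 4) stop("Mantel test needs at least 4 specimens")
  if (!all(dim(my) == dim(mx))) stop("matrices must have matching dimensions")
  ut <- upper.tri(mx)
  vx <- mx[ut]
  r_obs <- stats::cor(vx, my[ut])
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(permutations)) {
    perm <- sample.int(n)
    rp <- stats::cor(vx, my[perm, perm][ut])
    if (rp >= r_obs) hits <- hits + 1L
  }
  p <- (1 + hits) / (permutations + 1)
  list(r = r_obs, r_squared = r_obs^2, p = p,
       permutations = permutations, seed = seed, n = n)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value (wraps `stats::t.test(var.equal = FALSE)`).
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2, with
#'   nonzero variance in at least one.
#' @return list `t`, `df`, `p`.
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample needs at least 2 values")
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    stop("both samples have zero variance")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Euclidean geographic distance matrix from decimal-degree coordinates
#'
#' Plain Euclidean distance on raw (lat, lon) decimal degrees — the
#' coordinate treatment used for the geographic side of the Mantel test.
#' A great-circle alternative is available but off by default.
#'
#' @param coords two-column (lat, lon) matrix.
#' @param great_circle if `TRUE`, use great-circle (haversine) distances in
#'   km instead.
#' @return symmetric distance matrix.
#' @export
geo_distance <- function(coords, great_circle = FALSE) {
  coords <- as.matrix(coords)
  if (anyNA(coords)) stop("coordinates contain missing values")
  if (great_circle) {
    n <- nrow(coords)
    d <- matrix(0, n, n, dimnames = list(rownames(coords), rownames(coords)))
    for (i in seq_len(max(n - 1, 0))) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- geosphere::distHaversine(
          coords[i, c(2, 1)], coords[j, c(2, 1)]) / 1000
      }
    }
    return(d)
  }
  as.matrix(stats::dist(coords))
}
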