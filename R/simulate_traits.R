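# Synthetic morphometric data with known ground truth: power-law trait
# allometry against bell diameter, locality-level structure, and MCAR
# missingness. Emulates the statistical structure the morphometric pipeline
# assumes; see the methods vignette for what it deliberately does not
# emulate.

#' Specification for the trait simulator
#'
#' Defaults describe a medusa-like study: 8 locality groups spread along a
#' latitudinal gradient, 10 specimens each, bell diameters log-normal around
#' 10-20 cm, 8 allometric features (exponents 0.6-1.3) plus 3
#' size-independent noise features, multiplicative lognormal noise of
#' sigma = 0.05, a weak geographic trait gradient (geographic SD about 0.4x
#' the residual noise SD, the weak-but-detectable regime of a globally
#' sampled medusa dataset), and 10% MCAR missingness (roughly a third of
#' specimens fully complete).
#'
#' @param localities data.frame `name`, `lat`, `lon` of locality centroids.
#' @param n_per_locality specimens per locality.
#' @param f1_meanlog,f1_sdlog log-normal parameters of bell diameter (cm);
#'   `f1_meanlog` may be a vector (one per locality).
#' @param features data.frame `code`, `a` (scale), `b_true` (allometric
#'   exponent; 0 for size-independent features), `sigma` (lognormal noise
#'   SD), `size_dep` (logical).
#' @param geo_strength multiplicative strength of the latitudinal locality
#'   effect on traits (0 = no geographic structure).
#' @param miss_rate MCAR missingness rate applied to feature cells (never to
#'   f1).
#' @param seed integer RNG seed.
#' @return list of class `trait_sim_spec`.
#' @export
trait_sim_spec <- function(localities = default_localities(),
                           n_per_locality = 10,
                           f1_meanlog = log(15), f1_sdlog = 0.25,
                           features = default_trait_features(),
                           geo_strength = 0.02,
                           miss_rate = 0.1,
                           seed = 1) {
  if (miss_rate < 0 || miss_rate >= 1) stop("miss_rate must be in [0, 1)")
  if (any(features$sigma < 0)) stop("noise sigma must be nonnegative")
  structure(list(localities = localities,
                 n_per_locality = n_per_locality,
                 f1_meanlog = f1_meanlog, f1_sdlog = f1_sdlog,
                 features = features, geo_strength = geo_strength,
                 miss_rate = miss_rate, seed = seed),
            class = "trait_sim_spec")
}

#' Default simulated locality centroids
#'
#' @return data.frame `name`, `lat`, `lon`.
#' @export
default_localities <- function() {
  data.frame(
    name = paste0("loc", 1:8),
    lat = seq(-50, 55, length.out = 8),
    lon = seq(-120, 140, length.out = 8),
    stringsAsFactors = FALSE
  )
}

#' Default simulated feature panel
#'
#' Eight allometric features plus three size-independent noise features.
#'
#' @return data.frame understood by [trait_sim_spec()].
#' @export
default_trait_features <- function() {
  data.frame(
    code = c(paste0("f", 3:10), paste0("g", 1:3)),
    a = c(0.5, 0.8, 1.2, 0.3, 2.0, 0.6, 1.5, 0.9, 3.0, 1.0, 5.0),
    b_true = c(1.3, 0.9, 1.0, 0.7, 1.1, 0.6, 1.2, 0.8, 0, 0, 0),
    sigma = rep(0.05, 11),
    size_dep = c(rep(TRUE, 8), rep(FALSE, 3)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a trait matrix with ground truth
#'
#' Each size-dependent feature is generated as
#' `Y = a * f1^b_true * exp(geo + eps)` with `eps ~ N(0, sigma^2)` and a
#' locality effect `geo` proportional to scaled latitude (alternating sign
#' across features); size-independent features omit the `f1^b` term. MCAR
#' missingness is applied after the true values are recorded.
#'
#' @param spec a [trait_sim_spec()].
#' @param seed optional override of `spec$seed`.
#' @return list `tm` (a [trait_matrix()] with missing cells), `truth`: list
#'   `values` (complete matrix), `b_true` (named), `masked` (logical matrix
#'   of hidden cells), `locality_means` (locality x feature, over complete
#'   values), `spec`.
#' @export
simulate_traits <- function(spec = trait_sim_spec(), seed = NULL) {
  if (!inherits(spec, "trait_sim_spec")) stop("'spec' must be a trait_sim_spec")
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  locs <- spec$localities
  nl <- nrow(locs)
  if (nl < 1 || spec$n_per_locality < 1) stop("degenerate simulation spec")
  n <- nl * spec$n_per_locality
  loc_of <- rep(locs$name, each = spec$n_per_locality)
  ml <- rep(spec$f1_meanlog, length.out = nl)
  f1 <- exp(stats::rnorm(n, mean = rep(ml, each = spec$n_per_locality),
                         sd = spec$f1_sdlog))
  u <- if (nl > 1) {
    (locs$lat - mean(locs$lat)) / max(stats::sd(locs$lat), 1e-9)
  } else {
    0
  }
  u_of <- rep(u, each = spec$n_per_locality)
  fts <- spec$features
  p <- nrow(fts)
  vals <- matrix(NA_real_, n, p,
                 dimnames = list(sprintf("sp%03d", seq_len(n)), fts$code))
  for (j in seq_len(p)) {
    geo <- spec$geo_strength * (-1)^j * u_of
    eps <- stats::rnorm(n, 0, fts$sigma[j])
    base <- if (fts$size_dep[j]) fts$a[j] * f1^fts$b_true[j] else fts$a[j]
    vals[, j] <- base * exp(geo + eps)
  }
  truth_vals <- vals
  mask <- matrix(stats::runif(n * p) < spec$miss_rate, n, p,
                 dimnames = dimnames(vals))
  # keep every feature estimable everywhere: at least 3 observed per feature
  for (j in seq_len(p)) {
    if (sum(!mask[, j]) < 3) mask[seq_len(3), j] <- FALSE
  }
  vals[mask] <- NA_real_
  coords <- cbind(lat = rep(locs$lat, each = spec$n_per_locality),
                  lon = rep(locs$lon, each = spec$n_per_locality))
  tm <- trait_matrix(vals, size = f1, locality = loc_of, coords = coords,
                     feature_kind = "continuous")
  lm_means <- do.call(rbind, lapply(locs$name, function(l) {
    colMeans(truth_vals[loc_of == l, , drop = FALSE])
  }))
  rownames(lm_means) <- locs$name
  list(tm = tm,
       truth = list(values = truth_vals,
                    b_true = stats::setNames(fts$b_true, fts$code),
                    masked = mask,
                    locality_means = lm_means,
                    spec = spec, seed = seed))
}
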