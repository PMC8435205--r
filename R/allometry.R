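#' Fit the log-log allometry of one feature against bell diameter
#'
#' Ordinary least squares of `log(Y)` on `log(f1)` over the entire dataset
#' (not per locality), giving the allometric exponent `b` used by both the
#' Lleonart size correction and the missing-data estimator. Natural logs are
#' used; the slope is log-base invariant, the intercept is reported on the
#' natural-log scale.
#'
#' @param tm a [trait_matrix()].
#' @param feature feature code (column name).
#' @return one-row data.frame: `feature`, `slope`, `intercept`, `p_value`
#'   (two-sided, H0: slope = 0), `n`, `fittable`.
#' @export
fit_allometry <- function(tm, feature) {
  y <- tm$values[, feature]
  x <- tm$size
  ok <- !is.na(y)
  if (any(ok & y <= 0)) {
    bad <- which(ok & y <= 0)[1]
    stop(sprintf("nonpositive value for feature %s in specimen %s",
                 feature, specimen_ids(tm)[bad]))
  }
  if (sum(ok) < 3) {
    return(data.frame(feature = feature, slope = NA_real_,
                      intercept = NA_real_, p_value = NA_real_,
                      n = sum(ok), fittable = FALSE,
                      stringsAsFactors = FALSE))
  }
  ly <- log(y[ok])
  lx <- log(x[ok])
  if (stats::var(ly) == 0) {
    # invariant feature: zero slope, no size relationship
    return(data.frame(feature = feature, slope = 0, intercept = ly[1],
                      p_value = 1, n = sum(ok), fittable = TRUE,
                      stringsAsFactors = FALSE))
  }
  fit <- stats::lm(ly ~ lx)
  # noiseless fixtures trigger the "essentially perfect fit" warning
  cf <- suppressWarnings(summary(fit))$coefficients
  data.frame(feature = feature, slope = unname(cf["lx", "Estimate"]),
             intercept = unname(cf["(Intercept)", "Estimate"]),
             p_value = unname(cf["lx", "Pr(>|t|)"]),
             n = sum(ok), fittable = TRUE, stringsAsFactors = FALSE)
}

#' Fit allometries for all non-categorical features
#'
#' @param tm a [trait_matrix()].
#' @return data.frame with one row per feature (class `allometry_model`);
#'   categorical features get an unfittable placeholder row.
#' @export
fit_allometry_all <- function(tm) {
  rows <- lapply(feature_codes(tm), function(f) {
    if (tm$feature_kind[f] == "categorical") {
      data.frame(feature = f, slope = NA_real_, intercept = NA_real_,
                 p_value = NA_real_, n = 0L, fittable = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      fit_allometry(tm, f)
    }
  })
  am <- do.call(rbind, rows)
  rownames(am) <- am$feature
  class(am) <- c("allometry_model", "data.frame")
  am
}

am_entry <- function(am, feature) {
  if (!feature %in% rownames(am)) {
    stop("no allometry entry for feature ", feature)
  }
  am[feature, ]
}

#' Estimate missing trait values by allometric back-projection
#'
#' Lleonart-style estimation: a missing value of feature Y for specimen i is
#' reconstructed from the raw mean of Y among specimens of i's locality group
#' that did measure it, rescaled from the group's mean bell diameter to the
#' specimen's own: `Yhat = mean_group(Y) * (f1_i / f1_m)^b`, with `f1_m` the
#' mean f1 of those same donor specimens and `b` the fitted allometric slope.
#' When the group has no observed value for the feature, the nearest locality
#' group with data is used (smallest great-circle distance between locality
#' centroids), unless an explicit fallback chain is configured.
#'
#' @param tm a [trait_matrix()].
#' @param am an `allometry_model` from [fit_allometry_all()].
#' @param fallback optional named list: `fallback[[locality]]` is a character
#'   vector of donor localities to try, in order, overriding the geographic
#'   rule (used e.g. for aquarium groups without coordinates, or to fold in
#'   morphological-similarity judgment).
#' @return the trait matrix with all previously missing cells filled and
#'   flagged in `$imputed`; observed cells are untouched.
#' @export
impute_missing <- function(tm, am, fallback = NULL) {
  vals <- tm$values
  miss <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(miss) == 0) return(tm)
  cent <- locality_centroids(tm)
  for (k in seq_len(nrow(miss))) {
    i <- miss[k, 1]
    j <- miss[k, 2]
    f <- colnames(vals)[j]
    e <- am_entry(am, f)
    if (!isTRUE(e$fittable)) {
      stop("feature ", f, " has no fitted allometry; drop it before imputing")
    }
    loc <- tm$locality[i]
    donors <- donor_specimens(tm, loc, j, cent, fallback)
    mg <- mean(tm$values[donors, j])
    f1m <- mean(tm$size[donors])
    vals[i, j] <- mg * (tm$size[i] / f1m)^e$slope
    tm$imputed[i, j] <- TRUE
  }
  tm$values <- vals
  tm
}

# specimens donating the group mean for (locality, feature column j);
# walks the fallback chain (manual, else nearest centroid) when the home
# group has no observed value
donor_specimens <- function(tm, loc, j, cent, fallback) {
  obs <- !is.na(tm$values[, j])
  home <- tm$locality == loc & obs
  if (any(home)) return(which(home))
  f <- colnames(tm$values)[j]
  if (!is.null(fallback) && !is.null(fallback[[loc]])) {
    for (alt in fallback[[loc]]) {
      cand <- tm$locality == alt & obs
      if (any(cand)) return(which(cand))
    }
    stop("fallback chain for locality ", loc,
         " has no observed data for feature ", f)
  }
  have <- unique(tm$locality[obs])
  if (!length(have)) {
    stop("no locality anywhere has observed data for feature ", f,
         "; drop the feature first")
  }
  if (anyNA(cent[loc, ])) {
    stop("locality ", loc, " has no coordinates for nearest-locality ",
         "fallback (feature ", f, "); configure a manual fallback")
  }
  have <- have[!is.na(cent[have, "lat"])]
  if (!length(have)) {
    stop("no coordinate-bearing locality has data for feature ", f)
  }
  d <- geosphere::distHaversine(cent[loc, c("lon", "lat")],
                                cent[have, c("lon", "lat"), drop = FALSE])
  best <- have[which.min(d)]
  which(tm$locality == best & !is.na(tm$values[, j]))
}

#' Allometric size correction (Lleonart standardization)
#'
#' Scales every specimen to its locality group's mean bell diameter:
#' `Y* = Y_i * (f1_m / f1_i)^b`, with `f1_m` the mean f1 of the specimen's
#' locality group and `b` the globally fitted slope. Removes the allometric
#' size signal so residual variation reflects shape. The size variable itself
#' is left untransformed.
#'
#' @param tm a complete (no missing cells) [trait_matrix()]; run
#'   [impute_missing()] first.
#' @param am an `allometry_model`.
#' @return the size-corrected trait matrix.
#' @export
size_correct <- function(tm, am) {
  if (anyNA(tm$values)) {
    stop("missing cells remain; impute (or drop specimens) before size correction")
  }
  f1m <- tapply(tm$size, tm$locality, mean)[tm$locality]
  ratio <- as.numeric(f1m) / tm$size
  for (f in feature_codes(tm)) {
    e <- am_entry(am, f)
    if (!isTRUE(e$fittable)) {
      stop("feature ", f, " has no fitted allometry; drop it or fit first")
    }
    tm$values[, f] <- tm$values[, f] * ratio^e$slope
  }
  tm
}

#' Drop uninformative or excluded features
#'
#' Applies, in order: (a) categorical features are excluded; (b) explicitly
#' configured exclusions (defaults f19 number of lobes and f20 number of
#' rhopalia, which can be distorted by asymmetric development); (c) features
#' without a significant log-log relationship with f1 (slope p-value >=
#' `alpha`, or unfittable); (d) near-invariant features (variance over
#' observed values below `var_tol`).
#'
#' @param tm a [trait_matrix()].
#' @param am an `allometry_model`.
#' @param alpha significance threshold for the slope test (default 0.05).
#' @param exclude feature codes to drop unconditionally.
#' @param var_tol near-zero variance threshold (default 1e-12).
#' @return the reduced trait matrix; `attr(, "removal_log")` is a data.frame
#'   (`feature`, `rule`) naming the first rule that fired for each dropped
#'   feature.
#' @export
filter_features <- function(tm, am, alpha = 0.05,
                            exclude = c("f19", "f20"), var_tol = 1e-12) {
  log_rows <- list()
  keep <- character(0)
  for (f in feature_codes(tm)) {
    rule <- NULL
    e <- am_entry(am, f)
    if (tm$feature_kind[f] == "categorical") {
      rule <- "categorical"
    } else if (f %in% exclude) {
      rule <- "configured_exclusion"
    } else if (stats::var(tm$values[, f], na.rm = TRUE) < var_tol) {
      # checked before the slope rule: a constant feature trivially lacks a
      # size relationship, but invariance is the informative reason
      rule <- "near_invariant"
    } else if (!isTRUE(e$fittable) || is.na(e$p_value) ||
               e$p_value >= alpha) {
      rule <- "no_significant_size_relationship"
    }
    if (is.null(rule)) {
      keep <- c(keep, f)
    } else {
      log_rows[[f]] <- data.frame(feature = f, rule = rule,
                                  stringsAsFactors = FALSE)
    }
  }
  if (!length(keep)) stop("all features were removed; relax the filters")
  out <- tm_subset(tm, features = keep)
  attr(out, "removal_log") <- if (length(log_rows)) {
    do.call(rbind, unname(log_rows))
  } else {
    data.frame(feature = character(0), rule = character(0))
  }
  out
}

#' Rescale every feature to the unit interval
#'
#' Per feature: `(x - min) / (max - min)`, so 0 and 1 are attained.
#'
#' @param tm a complete [trait_matrix()] with no constant features (filter
#'   first).
#' @return the scaled trait matrix.
#' @export
minmax_scale <- function(tm) {
  if (anyNA(tm$values)) stop("missing cells remain; impute or drop first")
  for (f in feature_codes(tm)) {
    x <- tm$values[, f]
    r <- range(x)
    if (r[1] == r[2]) {
      stop("feature ", f, " is constant; filter before scaling")
    }
    tm$values[, f] <- (x - r[1]) / (r[2] - r[1])
  }
  tm
}
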