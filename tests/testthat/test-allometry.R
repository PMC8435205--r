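# Allometric fitting, Lleonart imputation and size correction

make_tm <- function(values, f1, locality = NULL, coords = NULL, ...) {
  n <- nrow(values)
  if (is.null(locality)) locality <- rep("L1", n)
  trait_matrix(values, size = f1, locality = locality, coords = coords, ...)
}

test_that("fit_allometry recovers exact log-linear data and flags invariants", {
  f1 <- c(5, 10, 15, 20)
  y <- 0.5 * f1^1.3
  tm <- make_tm(cbind(y = y, const = rep(3, 4)), f1)
  fit <- fit_allometry(tm, "y")
  expect_equal(fit$slope, 1.3, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-8)
  flat <- fit_allometry(tm, "const")
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)
})

test_that("fit_allometry errors on nonpositive values, flags tiny samples", {
  tm <- make_tm(cbind(y = c(1, -2, 3)), c(5, 10, 15))
  expect_error(fit_allometry(tm, "y"), "nonpositive")
  tm2 <- make_tm(cbind(y = c(1, NA, NA)), c(5, 10, 15))
  fit <- fit_allometry(tm2, "y")
  expect_false(fit$fittable)
})

test_that("noisy synthetic allometry is recovered within 0.05", {
  spec <- trait_sim_spec(
    n_per_locality = 100,
    localities = data.frame(name = "L1", lat = 0, lon = 0),
    features = data.frame(code = "y", a = 0.5, b_true = 0.9, sigma = 0.05,
                          size_dep = TRUE),
    geo_strength = 0, miss_rate = 0, seed = 42)
  st <- simulate_traits(spec)
  fit <- fit_allometry(st$tm, "y")
  expect_lt(abs(fit$slope - 0.9), 0.05)
})

test_that("imputation reproduces the trivial proportional cases", {
  # group mean Y = 3, f1_m = 10; third specimen missing
  vals <- cbind(y = c(2, 4, NA))
  tm <- make_tm(vals, f1 = c(8, 12, 10))
  am <- data.frame(feature = "y", slope = 2.5, intercept = 0, p_value = 0.01,
                   n = 2, fittable = TRUE, row.names = "y")
  class(am) <- c("allometry_model", "data.frame")
  out <- impute_missing(tm, am)
  expect_equal(unname(out$values[3, "y"]), 3)  # f1_i = f1_m: any slope
  expect_true(out$imputed[3, "y"])
  expect_equal(out$values[1:2, "y"], tm$values[1:2, "y"])
  tm2 <- make_tm(vals, f1 = c(8, 12, 20))
  am$slope <- 1
  out2 <- impute_missing(tm2, am)
  expect_equal(unname(out2$values[3, "y"]), 6)  # doubling f1 doubles Y at b=1
})

test_that("imputation is exact on noiseless allometric data", {
  # the raw-group-mean estimator is exact when the allometry is proportional
  # (b = 1, arbitrary donor sizes) ...
  spec <- trait_sim_spec(n_per_locality = 12,
                         features = data.frame(code = c("y1", "y2"),
                                               a = c(0.5, 2),
                                               b_true = 1, sigma = 0,
                                               size_dep = TRUE),
                         geo_strength = 0, miss_rate = 0, seed = 7)
  st <- simulate_traits(spec)
  tm <- st$tm
  set.seed(8)
  hide <- matrix(runif(length(tm$values)) < 0.2, nrow(tm$values))
  tm$values[hide] <- NA
  am <- fit_allometry_all(tm)
  out <- impute_missing(tm, am)
  expect_equal(out$values[hide], st$truth$values[hide], tolerance = 1e-8)
  # ... and when donors share one bell diameter (any exponent)
  spec2 <- trait_sim_spec(n_per_locality = 10, f1_sdlog = 0,
                          features = data.frame(code = "y", a = 0.7,
                                                b_true = 1.3, sigma = 0,
                                                size_dep = TRUE),
                          geo_strength = 0, miss_rate = 0, seed = 9)
  st2 <- simulate_traits(spec2)
  tm2 <- st2$tm
  tm2$values[c(2, 15), 1] <- NA
  am2 <- data.frame(feature = "y", slope = 1.3, intercept = 0, p_value = 0,
                    n = 10, fittable = TRUE, row.names = "y")
  class(am2) <- c("allometry_model", "data.frame")
  out2 <- impute_missing(tm2, am2)
  expect_equal(out2$values[c(2, 15), 1], st2$truth$values[c(2, 15), 1],
               tolerance = 1e-10)
})

test_that("imputation under 20% MCAR and sigma = 0.05 recovers held-out values", {
  spec <- trait_sim_spec(n_per_locality = 25,
                         features = default_trait_features()[1:6, ],
                         geo_strength = 0, miss_rate = 0.2, seed = 21)
  st <- simulate_traits(spec)
  am <- fit_allometry_all(st$tm)
  out <- impute_missing(st$tm, am)
  hidden <- st$truth$masked
  rel_err <- abs(out$values[hidden] - st$truth$values[hidden]) /
    st$truth$values[hidden]
  expect_lt(mean(rel_err), 2 * 0.05)
})

test_that("nearest-locality fallback and its error modes behave", {
  vals <- cbind(y = c(1, 2, NA))
  tm <- trait_matrix(vals, size = c(10, 10, 10),
                     locality = c("far", "near", "empty"),
                     coords = cbind(c(0, 40, 41), c(0, 10, 10)))
  am <- fit_allometry_all(trait_matrix(cbind(y = c(1, 2, 3)),
                                       size = c(5, 10, 20),
                                       locality = "x"))
  out <- impute_missing(tm, am, fallback = NULL)
  # nearest centroid is "near" (lat 40 vs 41), so donor mean is 2
  e <- am["y", ]
  expect_equal(unname(out$values[3, "y"]), 2 * (10 / 10)^e$slope)
  # no data anywhere for the feature
  tm_none <- trait_matrix(cbind(y = c(NA_real_, NA_real_)),
                          size = c(5, 5), locality = c("a", "b"))
  expect_error(impute_missing(tm_none, am), "no locality")
  # missing coordinates without manual fallback
  tm_nc <- trait_matrix(cbind(y = c(1, NA)), size = c(10, 10),
                        locality = c("a", "aq"))
  expect_error(impute_missing(tm_nc, am), "coordinates")
  out_manual <- impute_missing(tm_nc, am, fallback = list(aq = "a"))
  expect_equal(unname(out_manual$values[2, "y"]), 1)
})

test_that("size correction is identity at group-mean size or zero slope", {
  vals <- cbind(y = c(2, 3, 4))
  am <- data.frame(feature = "y", slope = 1.7, intercept = 0, p_value = 0,
                   n = 3, fittable = TRUE, row.names = "y")
  class(am) <- c("allometry_model", "data.frame")
  tm_eq <- make_tm(vals, f1 = c(10, 10, 10))
  expect_equal(size_correct(tm_eq, am)$values, tm_eq$values)
  am0 <- am
  am0$slope <- 0
  tm_any <- make_tm(vals, f1 = c(5, 10, 20))
  expect_equal(size_correct(tm_any, am0)$values, tm_any$values)
  expect_error(size_correct(make_tm(cbind(y = c(1, NA, 2)), c(5, 10, 20)),
                            am), "missing")
})

test_that("size correction removes the within-locality allometric slope", {
  spec <- trait_sim_spec(n_per_locality = 60,
                         localities = data.frame(name = c("L1", "L2"),
                                                 lat = c(0, 30),
                                                 lon = c(0, 30)),
                         features = default_trait_features()[1:5, ],
                         geo_strength = 0, miss_rate = 0, seed = 5)
  st <- simulate_traits(spec)
  am <- fit_allometry_all(st$tm)
  cor_tm <- size_correct(st$tm, am)
  for (f in colnames(cor_tm$values)) {
    idx <- cor_tm$locality == "L1"
    refit <- stats::lm(log(cor_tm$values[idx, f]) ~ log(cor_tm$size[idx]))
    # residual slope should be noise-level, far below the true exponents
    expect_lt(abs(stats::coef(refit)[2]), 0.1)
  }
})

test_that("feature filtering applies its rules in order with a removal log", {
  spec <- trait_sim_spec(n_per_locality = 40,
                         features = data.frame(
                           code = c("f3", "f4", "f19", "f20", "cat1",
                                    "flat", "g1"),
                           a = c(1, 2, 1, 1, 1, 5, 3),
                           b_true = c(1.1, 0.8, 1, 1, 0, 0, 0),
                           sigma = c(0.05, 0.05, 0.05, 0.05, 0.05, 0, 0.05),
                           size_dep = c(TRUE, TRUE, TRUE, TRUE, FALSE,
                                        FALSE, FALSE)),
                         geo_strength = 0, miss_rate = 0, seed = 9)
  st <- simulate_traits(spec)
  tm <- st$tm
  tm$feature_kind["cat1"] <- "categorical"
  am <- fit_allometry_all(tm)
  out <- filter_features(tm, am)
  expect_identical(colnames(out$values), c("f3", "f4"))
  lg <- attr(out, "removal_log")
  rules <- stats::setNames(lg$rule, lg$feature)
  expect_identical(unname(rules["cat1"]), "categorical")
  expect_identical(unname(rules[c("f19", "f20")]),
                   rep("configured_exclusion", 2))
  expect_identical(unname(rules["flat"]), "near_invariant")
  expect_identical(unname(rules["g1"]), "no_significant_size_relationship")
  expect_error(filter_features(tm_subset(tm, features = "g1"), am), "all features")
})

test_that("filtering keeps exactly the allometric features in a mixed set", {
  spec <- trait_sim_spec(n_per_locality = 50,
                         features = data.frame(
                           code = c(paste0("f", 3:7), paste0("g", 1:3)),
                           a = c(1, 2, 0.5, 1.5, 0.8, 2, 1, 3),
                           b_true = c(1.2, 0.9, 1.0, 0.7, 1.1, 0, 0, 0),
                           sigma = 0.05,
                           size_dep = c(rep(TRUE, 5), rep(FALSE, 3))),
                         geo_strength = 0, miss_rate = 0, seed = 13)
  st <- simulate_traits(spec)
  am <- fit_allometry_all(st$tm)
  out <- filter_features(st$tm, am, alpha = 0.05, exclude = character(0))
  expect_setequal(colnames(out$values), paste0("f", 3:7))
})

test_that("minmax scaling attains both bounds and is idempotent", {
  tm <- make_tm(cbind(a = c(2, 4, 6), b = c(0, 0.4, 1)), c(5, 10, 20))
  out <- minmax_scale(tm)
  expect_equal(unname(out$values[, "a"]), c(0, 0.5, 1))
  expect_equal(out$values[, "b"], tm$values[, "b"])
  expect_equal(apply(out$values, 2, min), c(a = 0, b = 0))
  expect_equal(apply(out$values, 2, max), c(a = 1, b = 1))
  expect_error(minmax_scale(make_tm(cbind(k = c(2, 2, 2)), c(5, 10, 20))),
               "constant")
})
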