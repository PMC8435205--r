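# End-to-end orchestration: a serializable run configuration and the two
# pipeline drivers (morphospace and molecular diagnosis), writing all
# intermediates to an artifact directory.

#' Run configuration
#'
#' Collects every tunable threshold and seed in one serializable object.
#' Defaults: slope-significance alpha 0.05, Goodman-Bremer minimum 2,
#' bootstrap minimum 75, pairwise-deletion gap policy, 2-D NMDS with 20
#' restarts, 9,999 Mantel permutations.
#'
#' @param alpha slope-significance threshold for feature filtering.
#' @param gb_min,boot_min support thresholds for hypothesis screening.
#' @param gap_policy p-distance gap policy.
#' @param mds_k,mds_restarts NMDS dimension and restarts.
#' @param permutations Mantel permutations.
#' @param exclude_features features dropped unconditionally.
#' @param great_circle use great-circle geographic distances instead of
#'   Euclidean-on-degrees.
#' @param seed integer RNG seed for every stochastic step.
#' @return list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, gb_min = 2, boot_min = 75,
                       gap_policy = c("pairwise_deletion",
                                      "gap_as_difference"),
                       mds_k = 2, mds_restarts = 20,
                       permutations = 9999,
                       exclude_features = c("f19", "f20"),
                       great_circle = FALSE,
                       seed = 1) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(alpha > 0, alpha < 1, boot_min >= 0, boot_min <= 100,
            mds_k >= 1, permutations >= 1)
  structure(list(alpha = alpha, gb_min = gb_min, boot_min = boot_min,
                 gap_policy = gap_policy, mds_k = mds_k,
                 mds_restarts = mds_restarts, permutations = permutations,
                 exclude_features = exclude_features,
                 great_circle = great_circle, seed = seed),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config` the path; `read_run_config` a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Run the morphometric pipeline
#'
#' Fixed-order pipeline: allometry fit, missing-data estimation, size
#' correction, feature filtering, 0-1 scaling, Gower dissimilarity, NMDS
#' with weighted-average feature scores, and a Mantel test of morphological
#' against geographic distance (aquarium specimens excluded from the Mantel
#' side). All intermediates, a feature-removal log and a JSON summary are
#' written to `out_dir`.
#'
#' @param tm a [trait_matrix()] or path of a trait CSV.
#' @param config a [run_config()].
#' @param out_dir artifact directory (created if absent).
#' @param impute estimate missing data first (`TRUE`, the default) or drop
#'   incomplete specimens instead (the no-estimation analysis arm).
#' @param fallback optional imputation fallback map, see [impute_missing()].
#' @return (invisibly) list `tm_final`, `ordination`, `feature_scores`,
#'   `mantel`, `allometry`, `removal_log`, `n_imputed`, `summary_path`.
#' @export
run_morphospace <- function(tm, config = run_config(), out_dir,
                            impute = TRUE, fallback = NULL) {
  if (is.character(tm)) tm <- read_trait_csv(tm)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  am <- fit_allometry_all(tm)
  utils::write.csv(am, file.path(out_dir, "allometry.csv"),
                   row.names = FALSE)
  if (impute) {
    tm2 <- impute_missing(tm, am, fallback = fallback)
    n_imputed <- sum(tm2$imputed)
  } else {
    complete <- rowSums(is.na(tm$values)) == 0
    tm2 <- tm_subset(tm, specimens = which(complete))
    n_imputed <- 0L
  }
  tm3 <- size_correct(tm2, am)
  tm4 <- filter_features(tm3, am, alpha = config$alpha,
                         exclude = config$exclude_features)
  removal_log <- attr(tm4, "removal_log")
  utils::write.csv(removal_log, file.path(out_dir, "removed_features.csv"),
                   row.names = FALSE)
  tm5 <- minmax_scale(tm4)
  write_trait_csv(tm5, file.path(out_dir, "corrected_scaled.csv"))
  d <- gower_distance(tm5)
  utils::write.csv(d, file.path(out_dir, "gower.csv"))
  ord <- nmds(d, k = config$mds_k, restarts = config$mds_restarts,
              seed = config$seed)
  utils::write.csv(data.frame(specimen_id = rownames(ord$points),
                              ord$points),
                   file.path(out_dir, "ordination_scores.csv"),
                   row.names = FALSE)
  fs <- feature_scores(ord, tm5)
  utils::write.csv(fs, file.path(out_dir, "feature_scores.csv"),
                   row.names = FALSE)
  # Mantel: geographic vs morphological distance, aquarium specimens out
  keep <- !tm5$aquarium & !is.na(tm5$coords[, "lat"]) &
    !is.na(tm5$coords[, "lon"])
  mant <- NULL
  if (sum(keep) >= 4) {
    dgeo <- geo_distance(tm5$coords[keep, , drop = FALSE],
                         great_circle = config$great_circle)
    mant <- mantel_test(dgeo, d[keep, keep],
                        permutations = config$permutations,
                        seed = config$seed)
    jsonlite::write_json(mant, file.path(out_dir, "mantel.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    n_specimens = nrow(tm5$values),
    n_features_retained = ncol(tm5$values),
    n_imputed_cells = n_imputed,
    nmds_stress = ord$stress,
    mantel = mant,
    seed = config$seed
  ), summary_path, auto_unbox = TRUE, digits = NA)
  invisible(list(tm_final = tm5, ordination = ord, feature_scores = fs,
                 mantel = mant, allometry = am, removal_log = removal_log,
                 n_imputed = n_imputed, summary_path = summary_path))
}

#' Run the molecular diagnosis pipeline
#'
#' Per marker: monophyly screen of every species, synapomorphy
#' classification, and uncorrected p-distance partition; then hypothesis
#' screening across markers (and consolidation when a concatenated tree is
#' given). Writes the per-position diagnostic listing (TSV), per-category
#' counts (JSON), min-max distance summaries (TSV) and the hypothesis
#' report.
#'
#' @param trees named list of [annotated_tree()] per marker.
#' @param alns named list of [alignment_set()] per marker (same names).
#' @param config a [run_config()].
#' @param out_dir artifact directory.
#' @param concat_tree optional concatenated-analysis [annotated_tree()].
#' @param concat_species_map species map for the concatenated tree's
#'   terminals (defaults to the union of the marker maps).
#' @return (invisibly) list `report`, `screen`, `consolidated`,
#'   `distance_summaries`, `gap_summaries`.
#' @export
run_diagnosis <- function(trees, alns, config = run_config(), out_dir,
                          concat_tree = NULL, concat_species_map = NULL) {
  if (!length(alns) || is.null(names(alns))) {
    stop("'alns' must be a non-empty named list")
  }
  for (m in names(alns)) {
    if (!length(alns[[m]]$species_map)) stop("empty species map for ", m)
    missing_tips <- setdiff(trees[[m]]$phy$tip.label,
                            rownames(alns[[m]]$chars))
    if (length(missing_tips)) {
      stop("marker ", m, ": tree terminals absent from alignment: ",
           paste(missing_tips, collapse = ", "))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- diagnose_all(trees, alns)
  write_diagnostic_report(report,
                          file.path(out_dir, "diagnostic_characters.tsv"),
                          file.path(out_dir, "synapomorphy_counts.json"))
  dsums <- list()
  gsums <- list()
  for (m in names(alns)) {
    pd <- p_distance_matrix(alns[[m]], policy = config$gap_policy)
    utils::write.csv(pd, file.path(out_dir, paste0("pdist_", m, ".csv")))
    ds <- partition_distances(pd, alns[[m]]$species_map)
    write_distance_summary(ds, file.path(out_dir,
                                         paste0("pdist_summary_", m, ".tsv")))
    utils::write.csv(ds$histogram,
                     file.path(out_dir, paste0("pdist_hist_", m, ".csv")),
                     row.names = FALSE)
    dsums[[m]] <- ds
    gsums[[m]] <- gap_summary(ds)
  }
  species_map <- unlist(lapply(unname(alns), function(a) a$species_map))
  species_map <- species_map[!duplicated(names(species_map))]
  screen <- screen_hypotheses(trees, species_map,
                              gb_min = config$gb_min,
                              boot_min = config$boot_min)
  utils::write.csv(screen, file.path(out_dir, "hypothesis_screen.csv"),
                   row.names = FALSE)
  consolidated <- NULL
  if (!is.null(concat_tree)) {
    if (is.null(concat_species_map)) concat_species_map <- species_map
    consolidated <- consolidate(concat_tree, screen, concat_species_map,
                                gb_min = config$gb_min,
                                boot_min = config$boot_min)
    utils::write.csv(consolidated,
                     file.path(out_dir, "hypotheses_consolidated.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(status = as.list(attr(screen, "status")),
         gap_summaries = gsums, seed = config$seed),
    file.path(out_dir, "diagnosis_summary.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, screen = screen,
                 consolidated = consolidated,
                 distance_summaries = dsums, gap_summaries = gsums))
}
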