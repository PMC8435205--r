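#' Specimen-by-feature trait matrix
#'
#' Container for medusa morphometric data: a specimens x features numeric
#' matrix with an explicit missingness mask, the per-specimen bell diameter
#' (feature f1, the size variable), a locality-group label, optional decimal
#' degree coordinates, and an aquarium flag for captive specimens (which have
#' no meaningful collection coordinates).
#'
#' @param values numeric matrix (specimens x features); `NA` marks a missing
#'   measurement. Row names are specimen ids, column names feature codes.
#' @param size numeric vector of bell diameters (f1, cm), strictly positive,
#'   one per specimen.
#' @param locality character vector of locality-group labels, one per specimen.
#' @param coords optional two-column matrix/data.frame (lat, lon) in decimal
#'   degrees; rows may be `NA` (e.g. aquarium specimens).
#' @param aquarium logical vector flagging aquarium/captive specimens.
#' @param feature_kind character vector, one per feature, each one of
#'   `"continuous"`, `"meristic"`, `"categorical"`.
#' @return an object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, size, locality, coords = NULL,
                         aquarium = NULL, feature_kind = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- paste0("sp", seq_len(n))
  if (is.null(colnames(values))) colnames(values) <- paste0("f", seq_len(p))
  size <- as.numeric(size)
  if (length(size) != n) stop("'size' must have one entry per specimen")
  if (anyNA(size) || any(size <= 0)) {
    stop("bell diameter f1 must be strictly positive and non-missing")
  }
  locality <- as.character(locality)
  if (length(locality) == 1L) locality <- rep(locality, n)
  if (length(locality) != n || anyNA(locality) || any(!nzchar(locality))) {
    stop("every specimen needs a locality label")
  }
  if (is.null(coords)) {
    coords <- matrix(NA_real_, n, 2, dimnames = list(rownames(values),
                                                     c("lat", "lon")))
  } else {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (nrow(coords) != n || ncol(coords) != 2) {
      stop("'coords' must be an n x 2 (lat, lon) matrix")
    }
    colnames(coords) <- c("lat", "lon")
    rownames(coords) <- rownames(values)
  }
  if (is.null(aquarium)) aquarium <- rep(FALSE, n)
  aquarium <- as.logical(aquarium)
  if (length(aquarium) != n) stop("'aquarium' must have one entry per specimen")
  if (is.null(feature_kind)) feature_kind <- rep("continuous", p)
  feature_kind <- as.character(feature_kind)
  if (length(feature_kind) == 1L) feature_kind <- rep(feature_kind, p)
  bad <- !feature_kind %in% c("continuous", "meristic", "categorical")
  if (any(bad)) {
    stop("unknown feature kind(s): ",
         paste(unique(feature_kind[bad]), collapse = ", "))
  }
  if (length(feature_kind) != p) {
    stop("'feature_kind' must have one entry per feature")
  }
  structure(list(
    values = values,
    imputed = matrix(FALSE, n, p, dimnames = dimnames(values)),
    size = stats::setNames(size, rownames(values)),
    locality = stats::setNames(locality, rownames(values)),
    coords = coords,
    aquarium = stats::setNames(aquarium, rownames(values)),
    feature_kind = stats::setNames(feature_kind, colnames(values))
  ), class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d specimens x %d features (%d missing cells, %d imputed)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)),
              sum(x$imputed)))
  cat(sprintf("  localities: %s\n",
              paste(unique(x$locality), collapse = ", ")))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

specimen_ids <- function(tm) rownames(tm$values)
feature_codes <- function(tm) colnames(tm$values)

#' Subset a trait matrix
#'
#' @param tm a [trait_matrix()].
#' @param specimens,features index vectors (names, integers or logical).
#' @return a `trait_matrix` restricted to the selection.
#' @export
tm_subset <- function(tm, specimens = NULL, features = NULL) {
  if (is.null(specimens)) specimens <- seq_len(nrow(tm$values))
  if (is.null(features)) features <- seq_len(ncol(tm$values))
  out <- tm
  out$values <- tm$values[specimens, features, drop = FALSE]
  out$imputed <- tm$imputed[specimens, features, drop = FALSE]
  out$size <- tm$size[specimens]
  out$locality <- tm$locality[specimens]
  out$coords <- tm$coords[specimens, , drop = FALSE]
  out$aquarium <- tm$aquarium[specimens]
  out$feature_kind <- tm$feature_kind[features]
  out
}

#' Read a specimen trait table from CSV
#'
#' Expected layout: one row per specimen with reserved columns `specimen_id`,
#' `locality`, `lat`, `lon`, `aquarium`, `f1`; all remaining columns are
#' features and empty cells are missing values. Feature kinds can be supplied
#' through a metadata CSV with columns `feature`, `kind` and optional
#' `exclude`.
#'
#' @param path CSV file path.
#' @param meta_path optional feature-metadata CSV path.
#' @return a [trait_matrix()]; any `exclude`-flagged features are kept but the
#'   flag is recorded in `attr(, "exclude")`.
#' @export
read_trait_csv <- function(path, meta_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reserved <- c("specimen_id", "locality", "lat", "lon", "aquarium", "f1")
  missing_cols <- setdiff(c("specimen_id", "locality", "f1"), names(df))
  if (length(missing_cols)) {
    stop("trait CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  feats <- setdiff(names(df), reserved)
  vals <- as.matrix(df[, feats, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$specimen_id
  kind <- rep("continuous", length(feats))
  excl <- character(0)
  if (!is.null(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    kind <- meta$kind[match(feats, meta$feature)]
    kind[is.na(kind)] <- "continuous"
    if ("exclude" %in% names(meta)) {
      excl <- meta$feature[!is.na(meta$exclude) & meta$exclude %in%
                             c(TRUE, "TRUE", "true", 1)]
    }
  }
  tm <- trait_matrix(
    vals,
    size = df$f1,
    locality = df$locality,
    coords = if (all(c("lat", "lon") %in% names(df)))
      cbind(df$lat, df$lon) else NULL,
    aquarium = if ("aquarium" %in% names(df)) df$aquarium else NULL,
    feature_kind = kind
  )
  attr(tm, "exclude") <- excl
  tm
}

#' Write a trait matrix to CSV
#'
#' Inverse of [read_trait_csv()]: reserved columns first, then features.
#'
#' @param tm a [trait_matrix()].
#' @param path output CSV path.
#' @export
write_trait_csv <- function(tm, path) {
  df <- data.frame(
    specimen_id = specimen_ids(tm),
    locality = unname(tm$locality),
    lat = tm$coords[, "lat"],
    lon = tm$coords[, "lon"],
    aquarium = unname(tm$aquarium),
    f1 = unname(tm$size),
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(tm$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# mean position (decimal degrees) of each locality group, from specimens
# that have coordinates
locality_centroids <- function(tm) {
  locs <- unique(tm$locality)
  out <- matrix(NA_real_, length(locs), 2,
                dimnames = list(locs, c("lat", "lon")))
  for (l in locs) {
    idx <- tm$locality == l & !is.na(tm$coords[, "lat"]) &
      !is.na(tm$coords[, "lon"])
    if (any(idx)) {
      out[l, ] <- colMeans(tm$coords[idx, , drop = FALSE])
    }
  }
  out
}
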