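# Uncorrected pairwise distances (proportion of mismatched sites) and their
# intra- vs interspecific partition, the raw material of barcode-gap
# assessment.

#' Uncorrected p-distance between two aligned sequences
#'
#' Number of base mismatches divided by the number of compared sites, with
#' no substitution-model correction. Under the default `pairwise_deletion`
#' policy, sites where either sequence has `-`, `?` or `N` are excluded from
#' both numerator and denominator; under `gap_as_difference`, gaps are
#' compared as a fifth state (a base against a gap is a mismatch, two gaps
#' match) and only `?`/`N` sites are excluded.
#'
#' @param seq_a,seq_b equal-length character vectors (or single strings) of
#'   aligned sequence characters.
#' @param policy `"pairwise_deletion"` (default) or `"gap_as_difference"`.
#' @return mismatch fraction in `[0, 1]`.
#' @export
p_distance <- function(seq_a, seq_b,
                       policy = c("pairwise_deletion", "gap_as_difference")) {
  policy <- match.arg(policy)
  if (length(seq_a) == 1 && nchar(seq_a) > 1) seq_a <- strsplit(seq_a, "")[[1]]
  if (length(seq_b) == 1 && nchar(seq_b) > 1) seq_b <- strsplit(seq_b, "")[[1]]
  a <- toupper(seq_a)
  b <- toupper(seq_b)
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  unknown <- c("?", "N")
  drop <- a %in% unknown | b %in% unknown
  if (policy == "pairwise_deletion") {
    drop <- drop | a == "-" | b == "-"
  }
  keep <- !drop
  if (!any(keep)) stop("no comparable sites between the two sequences")
  mean(a[keep] != b[keep])
}

#' All pairwise uncorrected p-distances of an alignment
#'
#' @param aln an [alignment_set()] or character matrix (terminals x
#'   positions).
#' @param policy gap policy, see [p_distance()].
#' @return symmetric matrix of mismatch fractions, zero diagonal.
#' @export
p_distance_matrix <- function(aln,
                              policy = c("pairwise_deletion",
                                         "gap_as_difference")) {
  policy <- match.arg(policy)
  chars <- if (inherits(aln, "alignment_set")) aln$chars else as.matrix(aln)
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(rownames(chars), rownames(chars)))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- p_distance(chars[i, ], chars[j, ],
                                       policy = policy)
    }
  }
  d
}

#' Partition pairwise distances into intra- and interspecific sets
#'
#' Every unordered pair is assigned to exactly one partition: within a
#' species (intra) or across species (inter). Reports per-species and
#' per-species-pair min-max ranges (the "minimum - maximum" summary format)
#' and pooled histograms.
#'
#' @param mat symmetric p-distance matrix.
#' @param species_map named character vector, terminal -> species, covering
#'   every row of `mat`.
#' @param bin_width histogram bin width in percentage points (default 0.5).
#' @return object of class `distance_summary`: `$intra` / `$inter` pooled
#'   value vectors, `$intra_ranges` (species, n, min, max), `$inter_ranges`
#'   (species_a, species_b, n, min, max), `$histogram` (breaks in percent,
#'   intra and inter counts), `$n_pairs`.
#' @export
partition_distances <- function(mat, species_map, bin_width = 0.5) {
  mat <- as.matrix(mat)
  terms <- rownames(mat)
  if (is.null(terms)) stop("distance matrix must carry terminal labels")
  sp <- species_map[terms]
  if (anyNA(sp)) {
    stop("species_map lacks terminal(s): ",
         paste(terms[is.na(sp)], collapse = ", "))
  }
  n <- nrow(mat)
  ut <- which(upper.tri(mat), arr.ind = TRUE)
  vals <- mat[upper.tri(mat)]
  same <- sp[ut[, 1]] == sp[ut[, 2]]
  intra <- vals[same]
  inter <- vals[!same]
  species <- sort(unique(sp))
  intra_ranges <- do.call(rbind, lapply(species, function(s) {
    v <- vals[same & sp[ut[, 1]] == s]
    data.frame(species = s, n = sum(sp == s),
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pair_idx <- which(!same)
  key <- vapply(pair_idx, function(k) {
    paste(sort(c(sp[ut[k, 1]], sp[ut[k, 2]])), collapse = "\r")
  }, character(1))
  inter_ranges <- do.call(rbind, lapply(split(pair_idx, key), function(kk) {
    ab <- sort(c(sp[ut[kk[1], 1]], sp[ut[kk[1], 2]]))
    v <- vals[kk]
    data.frame(species_a = ab[1], species_b = ab[2], n = length(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  rownames(inter_ranges) <- NULL
  pct_max <- max(c(intra, inter, 0)) * 100
  breaks <- seq(0, ceiling(pct_max / bin_width) * bin_width + bin_width,
                by = bin_width)
  hist_count <- function(v) {
    if (!length(v)) return(integer(length(breaks) - 1))
    as.integer(table(cut(v * 100, breaks, include.lowest = TRUE,
                         right = FALSE)))
  }
  structure(list(
    intra = intra, inter = inter,
    intra_ranges = intra_ranges, inter_ranges = inter_ranges,
    histogram = data.frame(lower_pct = breaks[-length(breaks)],
                           upper_pct = breaks[-1],
                           intra = hist_count(intra),
                           inter = hist_count(inter)),
    bin_width = bin_width,
    n_pairs = n * (n - 1) / 2
  ), class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("distance_summary: %d intra + %d inter pairs (of %d)\n",
              length(x$intra), length(x$inter), x$n_pairs))
  invisible(x)
}

#' Barcode-gap assessment
#'
#' Compares the largest intraspecific with the smallest interspecific
#' distance: a strict barcode gap exists when min(inter) > max(intra);
#' otherwise the overlap interval is reported.
#'
#' @param ds a [partition_distances()] result.
#' @return list `max_intra`, `min_inter`, `strict_gap`, `margin` (gap width
#'   when strict), `overlap` (c(lo, hi) when not); `NA`s and
#'   `strict_gap = NA` when either partition is empty.
#' @export
gap_summary <- function(ds) {
  if (!length(ds$intra) || !length(ds$inter)) {
    return(list(max_intra = NA_real_, min_inter = NA_real_,
                strict_gap = NA, margin = NA_real_, overlap = NULL))
  }
  max_intra <- max(ds$intra)
  min_inter <- min(ds$inter)
  strict <- min_inter > max_intra
  list(max_intra = max_intra, min_inter = min_inter, strict_gap = strict,
       margin = if (strict) min_inter - max_intra else NA_real_,
       overlap = if (strict) NULL else c(min_inter, max_intra))
}

#' Write a distance summary in the min-max TSV format
#'
#' @param ds a [partition_distances()] result.
#' @param path output TSV path; distances are written in percent as
#'   `"minimum - maximum"` strings.
#' @export
write_distance_summary <- function(ds, path) {
  fmt <- function(lo, hi) {
    ifelse(is.na(lo), "", sprintf("%.2f - %.2f", lo * 100, hi * 100))
  }
  rows <- rbind(
    data.frame(species_a = ds$intra_ranges$species,
               species_b = ds$intra_ranges$species,
               type = "intra", n = ds$intra_ranges$n,
               range = fmt(ds$intra_ranges$min, ds$intra_ranges$max),
               stringsAsFactors = FALSE),
    data.frame(species_a = ds$inter_ranges$species_a,
               species_b = ds$inter_ranges$species_b,
               type = "inter", n = ds$inter_ranges$n,
               range = fmt(ds$inter_ranges$min, ds$inter_ranges$max),
               stringsAsFactors = FALSE)
  )
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
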