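# Species-hypothesis screening: a hypothesis attains primary status when on
# at least one single-marker phylogeny its terminals are monophyletic with
# Goodman-Bremer support >= 2 and bootstrap resampling frequency >= 75
# (thresholds configurable); primary hypotheses are then re-evaluated on the
# concatenated phylogeny, where the stem branch length is recorded for the
# ad hoc differentiation assessment.

#' Screen species hypotheses against single-marker trees
#'
#' @param trees named list of [annotated_tree()] (one per marker).
#' @param species_map named character vector, terminal -> species; terminals
#'   absent from a tree are simply not testable on that marker.
#' @param gb_min minimum Goodman-Bremer support (default 2).
#' @param boot_min minimum bootstrap frequency in percent (default 75).
#' @return data.frame of class `hypothesis_screen` with one row per species
#'   x marker (`species`, `marker`, `n_terminals`, `monophyletic`, `gb`,
#'   `bootstrap`, `passes`, `note`) and attribute `"status"`: a named vector
#'   with values `"primary"` or `"untestable"` per species. Missing support
#'   values at the clade's node fail the threshold and are noted.
#' @export
screen_hypotheses <- function(trees, species_map, gb_min = 2, boot_min = 75) {
  if (!length(trees)) stop("at least one marker tree is required")
  species <- sort(unique(species_map))
  rows <- list()
  for (m in names(trees)) {
    atree <- trees[[m]]
    tips <- atree$phy$tip.label
    for (sp in species) {
      terms <- intersect(names(species_map)[species_map == sp], tips)
      if (!length(terms)) next
      mono <- check_monophyly(atree, terms)
      sup <- node_support(atree, mono$mrca)
      note <- ""
      if (mono$monophyletic && (is.na(sup$gb) || is.na(sup$bootstrap))) {
        note <- "support missing at clade node; treated as failing"
      }
      passes <- mono$monophyletic &&
        !is.na(sup$gb) && sup$gb >= gb_min &&
        !is.na(sup$bootstrap) && sup$bootstrap >= boot_min
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, marker = m, n_terminals = length(terms),
        monophyletic = mono$monophyletic,
        gb = sup$gb, bootstrap = sup$bootstrap,
        passes = passes, note = note, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  status <- stats::setNames(rep("untestable", length(species)), species)
  if (!is.null(tab)) {
    for (sp in unique(tab$species)) {
      status[sp] <- if (any(tab$passes[tab$species == sp]))
        "primary" else "untestable"
    }
  } else {
    tab <- data.frame(species = character(0), marker = character(0),
                      n_terminals = integer(0), monophyletic = logical(0),
                      gb = numeric(0), bootstrap = numeric(0),
                      passes = logical(0), note = character(0),
                      stringsAsFactors = FALSE)
  }
  attr(tab, "status") <- status
  class(tab) <- c("hypothesis_screen", "data.frame")
  tab
}

#' Consolidate hypotheses on the concatenated phylogeny
#'
#' Re-evaluates each primary species hypothesis on the concatenated tree:
#' monophyly plus the same support thresholds. The stem branch length of the
#' species clade is recorded (with its rank among the evaluated species,
#' longest first) for the ad hoc branch-length criterion, and no automatic
#' cutoff is imposed on it. The distribution criterion is surfaced as data
#' (`localities` per species, when provided), never auto-decided.
#'
#' @param concat_tree an [annotated_tree()] of the concatenated analysis.
#' @param screen a [screen_hypotheses()] result (its `"status"` attribute
#'   supplies the primary hypotheses).
#' @param species_map named character vector, terminal -> species, for the
#'   concatenated tree's terminals.
#' @param gb_min,boot_min support thresholds, as in [screen_hypotheses()].
#' @param localities optional named list: collection localities per species.
#' @return data.frame with one row per species: `species`, `status`
#'   (`corroborated` / `rejected` / `primary` / `untestable`),
#'   `monophyletic`, `gb`, `bootstrap`, `stem_length`, `stem_rank`,
#'   `conflicting_terminals`, `localities`.
#' @export
consolidate <- function(concat_tree, screen, species_map,
                        gb_min = 2, boot_min = 75, localities = NULL) {
  status0 <- attr(screen, "status")
  species <- names(status0)
  tips <- concat_tree$phy$tip.label
  rows <- lapply(species, function(sp) {
    out <- data.frame(species = sp, status = status0[[sp]],
                      monophyletic = NA, gb = NA_real_,
                      bootstrap = NA_real_, stem_length = NA_real_,
                      stem_rank = NA_integer_,
                      conflicting_terminals = "",
                      localities = if (!is.null(localities[[sp]]))
                        paste(localities[[sp]], collapse = "; ") else "",
                      stringsAsFactors = FALSE)
    if (status0[[sp]] != "primary") return(out)
    terms <- intersect(names(species_map)[species_map == sp], tips)
    if (!length(terms)) {
      out$status <- "untestable"
      return(out)
    }
    mono <- check_monophyly(concat_tree, terms)
    out$monophyletic <- mono$monophyletic
    if (!mono$monophyletic) {
      out$status <- "rejected"
      out$conflicting_terminals <- paste(mono$intruders, collapse = "; ")
      return(out)
    }
    sup <- node_support(concat_tree, mono$mrca)
    out$gb <- sup$gb
    out$bootstrap <- sup$bootstrap
    out$stem_length <- stem_length(concat_tree$phy, mono$mrca)
    passes <- !is.na(sup$gb) && sup$gb >= gb_min &&
      !is.na(sup$bootstrap) && sup$bootstrap >= boot_min
    out$status <- if (passes) "corroborated" else "primary"
    out
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$stem_length)
  tab$stem_rank[ok] <- rank(-tab$stem_length[ok], ties.method = "min")
  rownames(tab) <- NULL
  tab
}

#' Sequence-set completeness and chimerism bookkeeping
#'
#' For each terminal taxon of a concatenated matrix: completeness is the
#' proportion of markers with a sequence present, and chimerism the
#' proportion of present sequences that came from a different specimen than
#' the terminal's reference specimen. Summarizes the percentage of terminals
#' with a complete marker complement, the percentage entirely non-chimeric,
#' and the mean chimerism ratio among chimeric sets.
#'
#' @param table data.frame with one row per terminal taxon: a `species`
#'   column, one `<marker>_id` column per marker (`NA`/empty = absent) and a
#'   matching `<marker>_chimeric` logical column per marker.
#' @param markers character vector of marker names (default: inferred from
#'   `_id` columns).
#' @return list `per_terminal` (data.frame with `completeness` and
#'   `chimerism` per row), `pct_complete`, `pct_nonchimeric`,
#'   `mean_chimerism_chimeric` (NA when no set is chimeric), `n_terminals`.
#' @export
sequence_set_stats <- function(table, markers = NULL) {
  if (!nrow(table)) stop("sequence-set table is empty")
  if (is.null(markers)) {
    markers <- sub("_id$", "", grep("_id$", names(table), value = TRUE))
  }
  if (!length(markers)) stop("no marker columns found")
  present <- sapply(markers, function(m) {
    v <- table[[paste0(m, "_id")]]
    !is.na(v) & nzchar(as.character(v))
  })
  chim <- sapply(markers, function(m) {
    v <- table[[paste0(m, "_chimeric")]]
    if (is.null(v)) rep(FALSE, nrow(table)) else as.logical(v) %in% TRUE
  })
  present <- matrix(present, nrow = nrow(table))
  chim <- matrix(chim, nrow = nrow(table)) & present
  n_present <- rowSums(present)
  if (any(n_present == 0)) {
    stop("terminal(s) with no sequence at all: rows ",
         paste(which(n_present == 0), collapse = ", "))
  }
  completeness <- n_present / length(markers)
  chimerism <- rowSums(chim) / n_present
  chimeric_set <- rowSums(chim) > 0
  list(
    per_terminal = data.frame(species = table$species,
                              completeness = completeness,
                              chimerism = chimerism,
                              stringsAsFactors = FALSE),
    pct_complete = 100 * mean(completeness == 1),
    pct_nonchimeric = 100 * mean(!chimeric_set),
    mean_chimerism_chimeric = if (any(chimeric_set))
      100 * mean(chimerism[chimeric_set]) else NA_real_,
    n_terminals = nrow(table)
  )
}
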