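# Diagnostic molecular characters: alignment columns whose most-parsimonious
# optimization places a state transformation on the stem branch of a species
# clade. Characters are categorized following the four-way synapomorphy
# scheme: ambiguous (stem transformation or derived state varies across
# MPRs), or unambiguous and then unique vs non-unique (derived state absent
# vs present outside the clade) and non-homoplastic vs homoplastic (single
# origin and no loss in every MPR, vs multiple origins or a reversal in
# some MPR).

CATEGORIES <- c("ambiguous", "unique_nonhomoplastic", "unique_homoplastic",
                "nonunique_homoplastic")

#' Identify and categorize diagnostic characters for one clade
#'
#' For every alignment position, asks whether some most-parsimonious
#' reconstruction places a state transformation on the stem branch of the
#' focal clade, ending in a derived state shared by the clade's crown
#' optimization. Unambiguous characters (stem transformation present with
#' the same derived state in every MPR) are sub-categorized by uniqueness
#' (derived state absent from all terminals outside the clade) and homoplasy
#' (in some MPR the state originates on more than one branch, or is lost on
#' some branch).
#'
#' @param tree an [annotated_tree()] (rooted; terminals must cover the
#'   alignment).
#' @param aln an [alignment_set()].
#' @param focal_clade character vector of terminal labels (the species
#'   clade). A single terminal is allowed when `single_terminal = TRUE`: its
#'   pendant edge is the stem.
#' @param single_terminal allow one-terminal clades (default `TRUE`).
#' @param max_mprs cap on enumerated reconstructions per column.
#' @return data.frame (`position` 0-based, `derived_state`, `category`) with
#'   attribute `"flag"` set to `"non_monophyletic"` (empty result) when the
#'   focal terminals are not monophyletic.
#' @export
classify_synapomorphies <- function(tree, aln, focal_clade,
                                    single_terminal = TRUE,
                                    max_mprs = 100000) {
  phy <- if (inherits(tree, "annotated_tree")) tree$phy else tree
  empty <- data.frame(position = integer(0), derived_state = character(0),
                      category = character(0), stringsAsFactors = FALSE)
  if (length(focal_clade) == 1 && !single_terminal) {
    attr(empty, "flag") <- "single_terminal"
    return(empty)
  }
  mono <- check_monophyly(phy, focal_clade)
  if (!mono$monophyletic) {
    attr(empty, "flag") <- "non_monophyletic"
    return(empty)
  }
  if (mono$mrca == root_node(phy)) {
    attr(empty, "flag") <- "clade_is_root"
    return(empty)
  }
  states <- aln$states[phy$tip.label, , drop = FALSE]
  outside <- setdiff(phy$tip.label, focal_clade)
  rows <- list()
  for (pos in seq_len(ncol(states))) {
    col <- states[, pos]
    if (Reduce(bitwAnd, col) != 0L) next  # a shared state: length 0
    ch <- classify_column(phy, col, mono$mrca, outside_states =
                            Reduce(bitwOr, col[outside]),
                          max_mprs = max_mprs)
    if (!is.null(ch)) {
      ch$position <- pos - 1L  # positions reported 0-based
      rows[[length(rows) + 1L]] <- ch
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)[, c("position", "derived_state", "category")]
  } else {
    empty
  }
  rownames(out) <- NULL
  out
}

# single-column categorization; NULL when no MPR has a stem transformation
classify_column <- function(phy, col, mrca, outside_states, max_mprs) {
  pairs <- edge_state_pairs(phy, stats::setNames(col, phy$tip.label), mrca)
  trans <- pairs[pairs$parent_state != pairs$child_state, , drop = FALSE]
  if (nrow(trans) == 0) return(NULL)
  always <- nrow(pairs) == nrow(trans)
  derived <- unique(trans$child_state)
  if (!always || length(derived) > 1) {
    return(data.frame(derived_state = NA_character_, category = "ambiguous",
                      stringsAsFactors = FALSE))
  }
  s <- derived
  s_bit <- STATE_BITS[[s]]
  unique_state <- bitwAnd(outside_states, s_bit) == 0L
  en <- enumerate_mprs(phy, stats::setNames(col, phy$tip.label),
                       max_nodes = phy$Nnode, max_mprs = max_mprs)
  homoplastic <- FALSE
  for (r in seq_len(nrow(en$labelings))) {
    h <- state_history(phy, en$labelings[r, ], s)
    if (h$origins != 1 || h$losses > 0) {
      homoplastic <- TRUE
      break
    }
  }
  category <- if (!homoplastic && unique_state) {
    "unique_nonhomoplastic"
  } else if (homoplastic && unique_state) {
    "unique_homoplastic"
  } else if (homoplastic) {
    "nonunique_homoplastic"
  } else {
    # single origin, no loss, yet present outside the clade: the outside
    # occurrences descend from the same origin, so the stem transformation
    # cannot be on the focal stem -- unreachable given a stem gain, but
    # guarded for safety
    "nonunique_homoplastic"
  }
  data.frame(derived_state = s, category = category, stringsAsFactors = FALSE)
}

#' Diagnose every species on every marker
#'
#' Runs the monophyly check and [classify_synapomorphies()] for each species
#' on each marker's tree and alignment, and assembles per-category counts
#' (the per-species count format of a concatenated-analysis figure) plus the
#' full per-position listing.
#'
#' @param trees named list of [annotated_tree()], one per marker.
#' @param alns named list of [alignment_set()], same names.
#' @param species optional character vector of species to diagnose (default:
#'   all species appearing in any alignment's species map).
#' @param single_terminal allow single-terminal species (default `TRUE`).
#' @param max_mprs cap on enumerated reconstructions per column.
#' @return object of class `diagnostic_report`: `$characters` (species,
#'   marker, position, derived_state, category), `$counts` (species, marker,
#'   one column per category, `N`, `flag`).
#' @export
diagnose_all <- function(trees, alns, species = NULL,
                         single_terminal = TRUE, max_mprs = 100000) {
  markers <- names(alns)
  if (is.null(markers) || !setequal(markers, names(trees))) {
    stop("'trees' and 'alns' must be named lists over the same markers")
  }
  if (is.null(species)) {
    species <- sort(unique(unlist(lapply(alns, function(a) a$species_map))))
  }
  chars <- list()
  counts <- list()
  for (m in markers) {
    aln <- alns[[m]]
    tree <- trees[[m]]
    extra <- setdiff(tree$phy$tip.label, rownames(aln$chars))
    if (length(extra)) {
      stop("marker ", m, ": terminals missing from alignment: ",
           paste(extra, collapse = ", "))
    }
    for (sp in species) {
      terms <- intersect(species_terminals(aln, sp), tree$phy$tip.label)
      if (length(terms) == 0) {
        counts[[length(counts) + 1L]] <-
          count_row(sp, m, NULL, flag = "marker_absent")
        next
      }
      res <- classify_synapomorphies(tree, aln, terms,
                                     single_terminal = single_terminal,
                                     max_mprs = max_mprs)
      flag <- attr(res, "flag")
      counts[[length(counts) + 1L]] <-
        count_row(sp, m, res, flag = if (is.null(flag)) "" else flag)
      if (nrow(res)) {
        res$species <- sp
        res$marker <- m
        chars[[length(chars) + 1L]] <- res
      }
    }
  }
  characters <- if (length(chars)) {
    do.call(rbind, chars)[, c("species", "marker", "position",
                              "derived_state", "category")]
  } else {
    data.frame(species = character(0), marker = character(0),
               position = integer(0), derived_state = character(0),
               category = character(0), stringsAsFactors = FALSE)
  }
  structure(list(characters = characters,
                 counts = do.call(rbind, counts)),
            class = "diagnostic_report")
}

count_row <- function(sp, m, res, flag = "") {
  tab <- stats::setNames(rep(0L, length(CATEGORIES)), CATEGORIES)
  if (!is.null(res) && nrow(res)) {
    tb <- table(res$category)
    tab[names(tb)] <- as.integer(tb)
  }
  out <- data.frame(species = sp, marker = m, t(tab),
                    N = sum(tab), flag = flag, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("diagnostic_report: %d species x marker entries, %d characters\n",
              nrow(x$counts), nrow(x$characters)))
  print(utils::head(x$counts, 10))
  invisible(x)
}

#' Write a diagnostic report to TSV/JSON
#'
#' @param report a [diagnose_all()] result.
#' @param characters_path TSV path for the per-position listing.
#' @param counts_path optional JSON path for the per-category counts.
#' @export
write_diagnostic_report <- function(report, characters_path,
                                    counts_path = NULL) {
  utils::write.table(report$characters, characters_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(counts_path)) {
    jsonlite::write_json(report$counts, counts_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(characters_path)
}
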