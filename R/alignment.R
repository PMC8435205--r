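# Five-state molecular alphabet: A, C, G, T and the gap '-' as a fifth,
# potentially diagnostic, state. Columns are held as bitmask state sets so
# IUPAC ambiguity codes become polymorphic subsets and '?'/'N' full ambiguity.

STATE_CHARS <- c("A", "C", "G", "T", "-")
STATE_BITS <- stats::setNames(as.integer(2^(0:4)), STATE_CHARS)
FULL_SET <- 31L

iupac_masks <- function() {
  m <- c(
    A = "A", C = "C", G = "G", T = "T", U = "T", `-` = "-",
    R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
    B = "CGT", D = "AGT", H = "ACT", V = "ACG"
  )
  out <- vapply(m, function(s) {
    sum(STATE_BITS[strsplit(s, "")[[1]]])
  }, integer(1))
  out[["N"]] <- FULL_SET
  out[["?"]] <- FULL_SET
  out
}
IUPAC_MASK <- iupac_masks()

#' Encode aligned sequence characters as state-set bitmasks
#'
#' Maps A/C/G/T/- to singleton sets, IUPAC ambiguity codes to polymorphic
#' subsets, and '?'/'N' to the full five-state set (gap included).
#'
#' @param chars character vector or matrix of single characters.
#' @return integer bitmask(s) over bits A=1, C=2, G=4, T=8, gap=16.
#' @export
encode_states <- function(chars) {
  up <- toupper(chars)
  mask <- IUPAC_MASK[up]
  if (anyNA(mask)) {
    bad <- unique(up[is.na(mask)])
    stop("unrecognized sequence character(s): ", paste(bad, collapse = " "))
  }
  out <- as.integer(mask)
  if (is.matrix(chars)) {
    out <- matrix(out, nrow(chars), ncol(chars), dimnames = dimnames(chars))
  } else {
    names(out) <- names(chars)
  }
  out
}

decode_state <- function(mask) {
  vapply(mask, function(m) {
    if (is.na(m)) return(NA_character_)
    paste(STATE_CHARS[bitwAnd(m, STATE_BITS) > 0], collapse = "")
  }, character(1))
}

#' Aligned sequence set for one genetic marker
#'
#' @param seqs character matrix (terminals x positions) of aligned sequence
#'   characters, or a named character vector of equal-length strings.
#' @param marker marker name (e.g. "16S", "COI", "ITS1", "28S").
#' @param species_map named character vector mapping terminal labels to
#'   species labels; must cover every terminal.
#' @return object of class `alignment_set` with `$chars` (character matrix),
#'   `$states` (bitmask matrix), `$marker`, `$species_map`.
#' @export
alignment_set <- function(seqs, marker = "marker", species_map = NULL) {
  if (!is.matrix(seqs)) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) stop("sequences have unequal lengths")
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(seqs) <- names(lens)
  } else {
    seqs <- toupper(seqs)
  }
  if (is.null(rownames(seqs))) stop("terminals must be labelled")
  if (is.null(species_map)) {
    species_map <- stats::setNames(rownames(seqs), rownames(seqs))
  }
  missing_terms <- setdiff(rownames(seqs), names(species_map))
  if (length(missing_terms)) {
    stop("species_map lacks terminal(s): ",
         paste(missing_terms, collapse = ", "))
  }
  structure(list(
    chars = seqs,
    states = encode_states(seqs),
    marker = marker,
    species_map = species_map[rownames(seqs)]
  ), class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set '%s': %d terminals x %d positions, %d species\n",
              x$marker, nrow(x$chars), ncol(x$chars),
              length(unique(x$species_map))))
  invisible(x)
}

#' Read a FASTA alignment into an alignment set
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @param marker marker name.
#' @param species_map named character vector (terminal -> species) or the
#'   path of a two-column CSV (`terminal_id`, `species`).
#' @return an [alignment_set()].
#' @export
read_alignment_fasta <- function(path, marker = "marker",
                                 species_map = NULL) {
  dna <- ape::read.FASTA(path)
  chars <- toupper(do.call(rbind, as.character(dna)))
  rownames(chars) <- names(dna)
  if (is.character(species_map) && length(species_map) == 1 &&
      file.exists(species_map)) {
    species_map <- read_species_map(species_map)
  }
  alignment_set(chars, marker = marker, species_map = species_map)
}

#' Read a terminal-to-species map CSV
#'
#' @param path CSV with columns `terminal_id` and `species`.
#' @return named character vector.
#' @export
read_species_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("terminal_id", "species") %in% names(df))) {
    stop("species map CSV needs columns terminal_id, species")
  }
  stats::setNames(df$species, df$terminal_id)
}

#' Write an alignment set to FASTA
#'
#' @param aln an [alignment_set()].
#' @param path output path.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln$chars))) {
    writeLines(c(paste0(">", rownames(aln$chars)[i]),
                 paste(aln$chars[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Terminals belonging to one species
#'
#' @param aln an [alignment_set()].
#' @param species species label.
#' @return character vector of terminal labels.
#' @export
species_terminals <- function(aln, species) {
  names(aln$species_map)[aln$species_map == species]
}
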