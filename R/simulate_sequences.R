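# Synthetic alignments evolved on a known species tree, with diagnostic
# sites of each synapomorphy category planted by construction (not evolved),
# so the classifier can be scored against exact ground truth. Also a
# composition generator for concatenated-matrix sequence-set bookkeeping.

#' Specification for the sequence simulator
#'
#' The default species tree has eight ingroup species and an outgroup, with
#' one shallow sister pair (total tip-to-tip path close to 0.02
#' substitutions/site, emulating the ~2% divergence seen between recently
#' separated congeners) and deeper splits up to ~0.2. Each species is represented by a
#' pectinate clade of terminals with very short internal branches.
#'
#' @param tree_newick species tree (Newick with branch lengths; tip labels
#'   are species names). The tip named `outgroup` (if present) stays a
#'   single terminal.
#' @param n_per_species terminals per species (>= 4 allows every planted
#'   category).
#' @param length alignment length in sites.
#' @param rate background substitution rate per unit branch length (0 =
#'   noiseless).
#' @param within_bl branch length used inside the per-species terminal
#'   clades.
#' @param planted data.frame `species`, `category`, `count` of diagnostic
#'   sites to plant (categories from the four-way scheme).
#' @param gb,bootstrap simulated support values written on every internal
#'   node.
#' @param seed integer RNG seed.
#' @return list of class `seq_sim_spec`.
#' @export
seq_sim_spec <- function(tree_newick = default_species_tree(),
                         n_per_species = 4,
                         length = 600,
                         rate = 1,
                         within_bl = 0.001,
                         planted = default_planted_sites(),
                         gb = 10, bootstrap = 100,
                         seed = 1) {
  if (!all(planted$category %in% CATEGORIES)) {
    stop("unknown planted category; use one of: ",
         paste(CATEGORIES, collapse = ", "))
  }
  if (sum(planted$count) > length) stop("more planted sites than positions")
  structure(list(tree_newick = tree_newick, n_per_species = n_per_species,
                 length = length, rate = rate, within_bl = within_bl,
                 planted = planted, gb = gb, bootstrap = bootstrap,
                 seed = seed),
            class = "seq_sim_spec")
}

#' Default synthetic species tree
#'
#' @return Newick string; see [seq_sim_spec()].
#' @export
default_species_tree <- function() {
  paste0("(((((smithsoniana:0.009,cebimarensis:0.009):0.09,",
         "(coerulea:0.05,aurita:0.05):0.05):0.04,",
         "(labiata:0.08,solida:0.08):0.06):0.04,",
         "(limbata:0.12,relicta:0.12):0.06):0.06,outgroup:0.3);")
}

#' Default planted diagnostic sites
#'
#' Three unique non-homoplastic, two unique homoplastic and one non-unique
#' homoplastic site for each of the two shallow sister species.
#'
#' @return data.frame `species`, `category`, `count`.
#' @export
default_planted_sites <- function() {
  data.frame(
    species = rep(c("smithsoniana", "cebimarensis"), each = 3),
    category = rep(c("unique_nonhomoplastic", "unique_homoplastic",
                     "nonunique_homoplastic"), 2),
    count = rep(c(3, 2, 1), 2),
    stringsAsFactors = FALSE
  )
}

# expand each species tip into a pectinate clade of labelled terminals
expand_species_tips <- function(newick, n_per_species, within_bl) {
  phy <- ape::read.tree(text = newick)
  spp <- phy$tip.label
  sub <- vapply(spp, function(sp) {
    if (sp == "outgroup" || n_per_species == 1) {
      return(sp)
    }
    labs <- paste0(sp, "_t", seq_len(n_per_species))
    # pectinate: (t1,(t2,(t3,t4))) so ladder order is t1..tn
    inner <- sprintf("%s:%g", labs[n_per_species], within_bl)
    for (i in rev(seq_len(n_per_species - 1))) {
      stem <- if (i == 1) "" else sprintf(":%g", within_bl)
      inner <- sprintf("(%s:%g,%s)%s", labs[i], within_bl, inner, stem)
    }
    inner
  }, character(1))
  out <- newick
  for (sp in spp) {
    # word-boundary match so species names that prefix others are safe
    out <- gsub(sprintf("(?<![A-Za-z0-9_.])%s:", sp),
                sprintf("SUBTREE%s:", sp), out, perl = TRUE)
  }
  for (sp in spp) {
    out <- sub(paste0("SUBTREE", sp, ":"), paste0(sub[[sp]], ":"), out,
               fixed = TRUE)
  }
  ape::read.tree(text = out)
}

# terminals of one species in ladder order (t1 shallowest)
ladder_terminals <- function(species, n) paste0(species, "_t", seq_len(n))

#' Simulate an alignment on a known species tree with planted diagnostics
#'
#' Background sites evolve under an equal-rates substitution process along
#' the tree (each site on each branch changes with probability
#' `1 - exp(-rate * bl)` to a uniformly drawn different base). Planted
#' diagnostic sites are then constructed explicitly: `unique_nonhomoplastic`
#' puts the derived state on every focal terminal and the ancestral state
#' elsewhere; `unique_homoplastic` additionally reverts the second-deepest
#' terminal of the focal ladder (requires >= 4 terminals per species);
#' `nonunique_homoplastic` additionally places the derived state on the most
#' distant non-focal terminal; `ambiguous` puts the derived state on the two
#' shallowest focal terminals only (requires >= 3).
#'
#' @param spec a [seq_sim_spec()].
#' @param marker marker name for the resulting alignment set.
#' @param seed optional override of `spec$seed`.
#' @return list `aln` ([alignment_set()]), `tree` ([annotated_tree()] with
#'   simulated supports on every internal node), `truth` (data.frame
#'   `position` 1-based, `position0` 0-based, `species`, `category`,
#'   `derived_state`, `ancestral_state`).
#' @export
simulate_alignment <- function(spec = seq_sim_spec(), marker = "marker",
                               seed = NULL) {
  if (!inherits(spec, "seq_sim_spec")) stop("'spec' must be a seq_sim_spec")
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  phy <- expand_species_tips(spec$tree_newick, spec$n_per_species,
                             spec$within_bl)
  phy$node.label <- rep(sprintf("%g/%g", spec$gb, spec$bootstrap), phy$Nnode)
  n_tip <- length(phy$tip.label)
  L <- spec$length
  # background evolution, preorder from a uniform root sequence
  seqs <- matrix(NA_integer_, max(phy$edge), L)
  root <- root_node(phy)
  seqs[root, ] <- sample.int(4, L, replace = TRUE)
  pre_edges <- ape::reorder.phylo(phy, "cladewise")$edge
  pre_lens <- ape::reorder.phylo(phy, "cladewise")$edge.length
  for (e in seq_len(nrow(pre_edges))) {
    par <- pre_edges[e, 1]
    chd <- pre_edges[e, 2]
    child_seq <- seqs[par, ]
    if (spec$rate > 0) {
      q <- 1 - exp(-spec$rate * pre_lens[e])
      hit <- which(stats::runif(L) < q)
      if (length(hit)) {
        shift <- sample.int(3, length(hit), replace = TRUE)
        child_seq[hit] <- 1L + (child_seq[hit] - 1L + shift) %% 4L
      }
    }
    seqs[chd, ] <- child_seq
  }
  chars <- matrix(STATE_CHARS[seqs[seq_len(n_tip), , drop = FALSE]],
                  n_tip, L, dimnames = list(phy$tip.label, NULL))
  # plant diagnostic sites on dedicated positions
  plan <- spec$planted
  n_plant <- sum(plan$count)
  positions <- if (n_plant) sample.int(L, n_plant) else integer(0)
  truth <- list()
  pos_i <- 1L
  species_of <- sub("_t[0-9]+$", "", phy$tip.label)
  for (k in seq_len(nrow(plan))) {
    sp <- plan$species[k]
    cat_k <- plan$category[k]
    focal <- phy$tip.label[species_of == sp]
    if (!length(focal)) stop("planted species not in tree: ", sp)
    for (r in seq_len(plan$count[k])) {
      pos <- positions[pos_i]
      pos_i <- pos_i + 1L
      anc_der <- sample.int(4, 2)
      a <- STATE_CHARS[anc_der[1]]
      s <- STATE_CHARS[anc_der[2]]
      chars[, pos] <- a
      chars[focal, pos] <- s
      if (cat_k == "unique_homoplastic") {
        if (length(focal) < 4) {
          stop("unique_homoplastic plants need >= 4 terminals per species")
        }
        revert <- ladder_terminals(sp, spec$n_per_species)[
          spec$n_per_species - 1]
        chars[revert, pos] <- a
      } else if (cat_k == "nonunique_homoplastic") {
        distant <- distant_terminal(phy, focal)
        chars[distant, pos] <- s
      } else if (cat_k == "ambiguous") {
        if (length(focal) < 3) {
          stop("ambiguous plants need >= 3 terminals per species")
        }
        lad <- ladder_terminals(sp, spec$n_per_species)
        chars[, pos] <- a
        chars[lad[1:2], pos] <- s
      }
      truth[[length(truth) + 1L]] <- data.frame(
        position = pos, position0 = pos - 1L, species = sp,
        category = cat_k, derived_state = s, ancestral_state = a,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(position = integer(0), position0 = integer(0),
               species = character(0), category = character(0),
               derived_state = character(0), ancestral_state = character(0),
               stringsAsFactors = FALSE)
  species_map <- stats::setNames(species_of, phy$tip.label)
  aln <- alignment_set(chars, marker = marker, species_map = species_map)
  list(aln = aln, tree = annotated_tree(phy), truth = truth, seed = seed)
}

# Non-focal terminal suitable for planting an independent origin: the
# cheapest single-origin labeling connecting the candidate to the focal
# clade (every node on the joining path derived, one loss per off-path
# subtree, plus a gain unless the path crosses the root) must cost more
# than the intended two-origin reconstruction (cost 2), otherwise the stem
# transformation would be ambiguous. Among valid candidates the most
# expensive-to-connect one is chosen.
distant_terminal <- function(phy, focal) {
  outside <- setdiff(phy$tip.label, focal)
  mrca <- if (length(focal) == 1) {
    match(focal, phy$tip.label)
  } else {
    ape::getMRCA(phy, focal)
  }
  kids <- children_list(phy)
  alt_cost <- vapply(outside, function(t) {
    tip <- match(t, phy$tip.label)
    path <- ape::nodepath(phy, tip, mrca)
    inner <- setdiff(path, c(tip, mrca))
    penalty <- sum(vapply(inner, function(u) {
      sum(!kids[[u]] %in% path)
    }, numeric(1)))
    top <- path[which(!path %in% unlist(kids[path]))]  # path MRCA
    gain <- as.numeric(!identical(top, root_node(phy)))
    penalty + gain
  }, numeric(1))
  ok <- alt_cost >= 3
  if (!any(ok)) {
    stop("no outside terminal is separated enough to plant an unambiguous ",
         "independent origin")
  }
  outside[ok][which.max(alt_cost[ok])]
}

#' Construct a synthetic concatenated-matrix sequence-set table
#'
#' Builds, by construction rather than sampling, a table of terminal taxa
#' with a prescribed composition of marker completeness and chimerism: each
#' block contributes `count` terminals carrying `k_present` marker sequences
#' of which `n_chimeric` come from a different specimen. The default
#' composition (100 terminals over 28 species, 4 markers) emulates a
#' concatenated matrix in which 30% of terminals are complete, 49% are
#' non-chimeric, and chimeric sets are on average ~60% chimeric.
#'
#' @param composition data.frame `count`, `k_present`, `n_chimeric`.
#' @param n_species number of species labels to cycle terminals over.
#' @param markers marker names.
#' @param seed RNG seed (marker subsets for incomplete rows are drawn at
#'   random; the composition itself is fixed).
#' @return data.frame with `species`, `<marker>_id`, `<marker>_chimeric`
#'   columns, one row per terminal taxon.
#' @export
simulate_sequence_sets <- function(composition = default_seqset_composition(),
                                   n_species = 28,
                                   markers = c("16S", "COI", "ITS1", "28S"),
                                   seed = 1) {
  set.seed(seed)
  if (any(composition$n_chimeric > composition$k_present)) {
    stop("n_chimeric cannot exceed k_present")
  }
  if (any(composition$k_present > length(markers)) ||
      any(composition$k_present < 1)) {
    stop("k_present must be between 1 and the number of markers")
  }
  n_total <- sum(composition$count)
  species <- sprintf("species_%02d", rep_len(seq_len(n_species), n_total))
  rows <- list()
  term_i <- 0L
  for (b in seq_len(nrow(composition))) {
    for (r in seq_len(composition$count[b])) {
      term_i <- term_i + 1L
      k <- composition$k_present[b]
      nc <- composition$n_chimeric[b]
      present <- sort(sample.int(length(markers), k))
      chim_markers <- present[sample.int(k, nc)]
      row <- list(species = species[term_i])
      for (mi in seq_along(markers)) {
        m <- markers[mi]
        if (mi %in% present) {
          row[[paste0(m, "_id")]] <- sprintf("seq_%04d_%s", term_i, m)
          row[[paste0(m, "_chimeric")]] <- mi %in% chim_markers
        } else {
          row[[paste0(m, "_id")]] <- NA_character_
          row[[paste0(m, "_chimeric")]] <- FALSE
        }
      }
      rows[[term_i]] <- as.data.frame(row, stringsAsFactors = FALSE,
                                      check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default sequence-set composition
#'
#' 100 terminals: 30 complete (6 non-chimeric, 12 half-chimeric, 12
#' three-quarter-chimeric) and 70 incomplete (43 non-chimeric with 1-3
#' markers, 15 two-marker sets with one chimera, 12 three-marker sets with
#' two chimeras).
#'
#' @return data.frame `count`, `k_present`, `n_chimeric`.
#' @export
default_seqset_composition <- function() {
  data.frame(
    count      = c(6, 12, 12, 15, 14, 14, 15, 12),
    k_present  = c(4,  4,  4,  1,  2,  3,  2,  3),
    n_chimeric = c(0,  2,  3,  0,  0,  0,  1,  2),
    stringsAsFactors = FALSE
  )
}
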