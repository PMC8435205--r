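# Monophyly checks, hypothesis screening and sequence-set bookkeeping

test_that("monophyly boundary cases behave", {
  phy <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(check_monophyly(phy, "A")$monophyletic)
  expect_true(check_monophyly(phy, c("A", "B", "C", "D"))$monophyletic)
  bad <- check_monophyly(phy, c("A", "C"))
  expect_false(bad$monophyletic)
  expect_setequal(bad$intruders, c("B", "D"))
  expect_error(check_monophyly(phy, c("A", "Z")), "unknown terminal")
})

test_that("monophyly agrees with the node-scan oracle and ape", {
  for (s in 1:30) {
    set.seed(s)
    n <- sample(6:16, 1)
    phy <- ape::rtree(n)
    tips <- sample(phy$tip.label, sample(2:(n - 1), 1))
    got <- check_monophyly(phy, tips)$monophyletic
    expect_equal(got, monophyly_oracle(phy, tips))
    expect_equal(got, ape::is.monophyletic(phy, tips))
  }
})

make_marker_tree <- function(newick) annotated_tree(ape::read.tree(text = newick))

test_that("screening applies both thresholds on at least one marker", {
  # sp1 passes on m1; sp2 is monophyletic everywhere but weakly supported
  m1 <- make_marker_tree(
    "(out,((s1a,s1b)5/98,(s2a,s2b)1/99)10/100)root;")
  m2 <- make_marker_tree(
    "(out,((s1a,s1b)0/50,(s2a,s2b)1/80)10/100)root;")
  sm <- c(s1a = "sp1", s1b = "sp1", s2a = "sp2", s2b = "sp2", out = "out")
  scr <- screen_hypotheses(list(m1 = m1, m2 = m2), sm)
  status <- attr(scr, "status")
  expect_equal(unname(status["sp1"]), "primary")
  expect_equal(unname(status["sp2"]), "untestable")
  # species with no terminals in any tree
  sm2 <- c(sm, ghost = "sp3")
  scr2 <- screen_hypotheses(list(m1 = m1, m2 = m2), sm2)
  expect_equal(unname(attr(scr2, "status")["sp3"]), "untestable")
})

test_that("missing support at the clade node fails and is noted", {
  m <- make_marker_tree("(out,((s1a,s1b),(s2a,s2b)5/98));")
  sm <- c(s1a = "sp1", s1b = "sp1", s2a = "sp2", s2b = "sp2", out = "out")
  scr <- screen_hypotheses(list(m = m), sm)
  row <- scr[scr$species == "sp1", ]
  expect_false(row$passes)
  expect_match(row$note, "support missing")
  expect_equal(unname(attr(scr, "status")["sp2"]), "primary")
})

test_that("screening is monotone in both thresholds", {
  sim <- simulate_alignment(seq_sim_spec(length = 60), seed = 14)
  # perturb supports so thresholds bite differently per species
  tree <- sim$tree
  set.seed(15)
  tree$support$gb <- sample(0:6, nrow(tree$support), replace = TRUE)
  tree$support$bootstrap <- sample(c(50, 70, 80, 95, 100),
                                   nrow(tree$support), replace = TRUE)
  sm <- sim$aln$species_map
  n_primary <- function(gb, bs) {
    sum(attr(screen_hypotheses(list(m = tree), sm, gb_min = gb,
                               boot_min = bs), "status") == "primary")
  }
  for (gb in c(0, 2, 4, 6)) {
    for (bs in c(50, 75, 95)) {
      expect_gte(n_primary(gb, bs), n_primary(gb + 1, bs))
      expect_gte(n_primary(gb, bs), n_primary(gb, bs + 5))
    }
  }
})

test_that("screening statuses match a planted pass/fail pattern", {
  # five species, supports planted so that exactly sp1, sp3, sp5 pass
  nwk <- paste0("(out,((s1a,s1b)9/99,((s2a,s2b)1/99,((s3a,s3b)4/80,",
                "((s4a,s4b)9/60,(s5a,s5b)2/75)2/90)5/95)8/99)9/99);")
  tr <- make_marker_tree(nwk)
  sm <- stats::setNames(rep(paste0("sp", 1:5), each = 2),
                        paste0("s", rep(1:5, each = 2), c("a", "b")))
  scr <- screen_hypotheses(list(m = tr), sm)
  status <- attr(scr, "status")
  expect_equal(unname(status[paste0("sp", 1:5)]),
               c("primary", "untestable", "primary", "untestable", "primary"))
})

test_that("consolidation corroborates, rejects and records stem lengths", {
  m1 <- make_marker_tree(
    "(out,((s1a,s1b)5/98,((s2a,s2b)3/90,(s3a,s3b)4/92)2/80)9/99);")
  sm <- c(s1a = "sp1", s1b = "sp1", s2a = "sp2", s2b = "sp2",
          s3a = "sp3", s3b = "sp3", out = "out")
  scr <- screen_hypotheses(list(m1 = m1), sm)
  # concatenated tree: sp1 strongly supported, sp2 broken up, sp3 weak
  concat <- annotated_tree(ape::read.tree(text = paste0(
    "(out:0.3,((s1a:0.01,s1b:0.01)10/100:0.2,((s2a:0.1,s3a:0.1)9/99:0.05,",
    "(s2b:0.1,s3b:0.1)9/99:0.05)9/99:0.05)9/99:0.02);")))
  res <- consolidate(concat, scr, sm)
  expect_equal(res$status[res$species == "sp1"], "corroborated")
  expect_equal(res$stem_length[res$species == "sp1"], 0.2)
  expect_equal(res$stem_rank[res$species == "sp1"], 1L)
  expect_equal(res$status[res$species == "sp2"], "rejected")
  expect_match(res$conflicting_terminals[res$species == "sp2"], "s3")
  expect_equal(res$status[res$species == "sp3"], "rejected")
})

test_that("sequence-set statistics match hand counts", {
  tab <- data.frame(
    species = c("x", "x", "y", "z"),
    m1_id = c("a", "b", "c", "d"), m1_chimeric = c(FALSE, TRUE, FALSE, FALSE),
    m2_id = c("e", NA, "f", "g"), m2_chimeric = c(FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  st <- sequence_set_stats(tab)
  expect_equal(st$pct_complete, 75)      # 3 of 4 have both markers
  expect_equal(st$pct_nonchimeric, 50)   # rows 1 and 4
  expect_equal(st$mean_chimerism_chimeric, 100 * mean(c(1, 1 / 2)))
  all_clean <- data.frame(species = "x", m1_id = "a", m1_chimeric = FALSE,
                          stringsAsFactors = FALSE)
  st2 <- sequence_set_stats(all_clean)
  expect_equal(st2$pct_complete, 100)
  expect_equal(st2$pct_nonchimeric, 100)
  expect_true(is.na(st2$mean_chimerism_chimeric))
  expect_error(sequence_set_stats(all_clean[0, ]), "empty")
})

test_that("the default synthetic composition reproduces its planted ratios", {
  tab <- simulate_sequence_sets(seed = 3)
  st <- sequence_set_stats(tab)
  expect_equal(st$n_terminals, 100)
  expect_equal(st$pct_complete, 30)
  expect_equal(st$pct_nonchimeric, 49)
  expect_equal(st$mean_chimerism_chimeric, 100 * 30.5 / 51, tolerance = 1e-10)
})
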