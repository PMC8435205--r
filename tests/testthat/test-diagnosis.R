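# Synapomorphy identification and categorization

test_that("a clean quartet stem gain is unique and non-homoplastic", {
  # rooted on the (C,D) side so the focal stem is unambiguous
  phy <- ape::read.tree(text = "(C,(D,(A,B)));")
  tr <- annotated_tree(phy)
  aln <- alignment_set(c(A = "T", B = "T", C = "G", D = "G"))
  res <- classify_synapomorphies(tr, aln, c("A", "B"))
  expect_equal(nrow(res), 1)
  expect_equal(res$position, 0L)
  expect_equal(res$derived_state, "T")
  expect_equal(res$category, "unique_nonhomoplastic")
})

test_that("invariant columns yield no diagnostic characters", {
  phy <- ape::read.tree(text = "(C,(D,(A,B)));")
  aln <- alignment_set(c(A = "AAA", B = "AAA", C = "AAA", D = "AAA"))
  res <- classify_synapomorphies(annotated_tree(phy), aln, c("A", "B"))
  expect_equal(nrow(res), 0)
})

test_that("independent origin in a distant terminal makes the state non-unique", {
  # F carries the derived state but sits three subtrees away, so a single
  # connected origin would cost more than two independent gains
  phy <- ape::read.tree(text = "(out,(E,((A,B),(C,(D,F)))));")
  aln <- alignment_set(c(A = "T", B = "T", C = "G", D = "G", E = "G",
                         F = "T", out = "G"))
  res <- classify_synapomorphies(annotated_tree(phy), aln, c("A", "B"))
  expect_equal(res$category, "nonunique_homoplastic")
  expect_equal(res$derived_state, "T")
  # when the derived terminal is adjacent to the root instead, the stem
  # transformation is genuinely ambiguous
  phy2 <- ape::read.tree(text = "(F,(E,((A,B),(C,D))));")
  aln2 <- alignment_set(c(A = "T", B = "T", C = "G", D = "G", E = "G",
                          F = "T"))
  res2 <- classify_synapomorphies(annotated_tree(phy2), aln2, c("A", "B"))
  expect_equal(res2$category, "ambiguous")
})

test_that("a reversal inside the clade makes a unique state homoplastic", {
  # pectinate focal clade (t1,(t2,(t3,t4))) with t3 reverted
  phy <- ape::read.tree(text = "(out1,(out2,(t1,(t2,(t3,t4)))));")
  aln <- alignment_set(c(t1 = "T", t2 = "T", t3 = "A", t4 = "T",
                         out1 = "A", out2 = "A"))
  res <- classify_synapomorphies(annotated_tree(phy), aln,
                                 c("t1", "t2", "t3", "t4"))
  expect_equal(res$category, "unique_homoplastic")
})

test_that("stem transformations that vary across MPRs are ambiguous", {
  # two shallow focal terminals derived, the rest ancestral: the gain can
  # sit on the stem (with a loss inside) or on two inner branches
  phy <- ape::read.tree(text = "(out1,(out2,(t1,(t2,t3))));")
  aln <- alignment_set(c(t1 = "T", t2 = "T", t3 = "A",
                         out1 = "A", out2 = "A"))
  res <- classify_synapomorphies(annotated_tree(phy), aln,
                                 c("t1", "t2", "t3"))
  expect_equal(res$category, "ambiguous")
  expect_true(is.na(res$derived_state))
})

test_that("non-monophyletic focal sets are flagged empty, not an error", {
  phy <- ape::read.tree(text = "((A,C),(B,D));")
  aln <- alignment_set(c(A = "T", B = "T", C = "G", D = "G"))
  res <- classify_synapomorphies(annotated_tree(phy), aln, c("A", "B"))
  expect_equal(nrow(res), 0)
  expect_equal(attr(res, "flag"), "non_monophyletic")
})

test_that("single-terminal species diagnose on their pendant edge", {
  phy <- ape::read.tree(text = "(C,(D,(A,B)));")
  aln <- alignment_set(c(A = "T", B = "G", C = "G", D = "G"))
  res <- classify_synapomorphies(annotated_tree(phy), aln, "A")
  expect_equal(res$category, "unique_nonhomoplastic")
  res_off <- classify_synapomorphies(annotated_tree(phy), aln, "A",
                                     single_terminal = FALSE)
  expect_equal(nrow(res_off), 0)
})

test_that("noiseless planted fixtures are recovered with exact categories", {
  plan <- data.frame(
    species = rep(c("smithsoniana", "aurita"), each = 4),
    category = rep(c("unique_nonhomoplastic", "unique_homoplastic",
                     "nonunique_homoplastic", "ambiguous"), 2),
    count = rep(c(3, 2, 1, 2), 2))
  sim <- simulate_alignment(seq_sim_spec(rate = 0, length = 150,
                                         planted = plan), seed = 4)
  rep_out <- diagnose_all(list(mk = sim$tree), list(mk = sim$aln))
  got <- rep_out$characters
  # precision and recall 1 against the plant, category by category
  for (k in seq_len(nrow(sim$truth))) {
    row <- sim$truth[k, ]
    hit <- got[got$position == row$position0 & got$species == row$species, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$category, row$category)
    if (row$category != "ambiguous") {
      expect_equal(hit$derived_state, row$derived_state)
    }
  }
  planted_sp <- got$species %in% c("smithsoniana", "aurita")
  expect_equal(nrow(got[planted_sp, ]), nrow(sim$truth))
})

test_that("unique non-homoplastic plants keep recall 1 under background noise", {
  sim <- simulate_alignment(seq_sim_spec(rate = 1, length = 400), seed = 6)
  rep_out <- diagnose_all(list(mk = sim$tree), list(mk = sim$aln))
  truth_black <- sim$truth[sim$truth$category == "unique_nonhomoplastic", ]
  got <- rep_out$characters
  for (k in seq_len(nrow(truth_black))) {
    row <- truth_black[k, ]
    hit <- got[got$position == row$position0 & got$species == row$species, ]
    expect_equal(hit$category, "unique_nonhomoplastic")
  }
  # planted homoplastic constructions must never be called non-homoplastic
  truth_h <- sim$truth[grepl("homoplastic", sim$truth$category) &
                         sim$truth$category != "unique_nonhomoplastic", ]
  for (k in seq_len(nrow(truth_h))) {
    row <- truth_h[k, ]
    hit <- got[got$position == row$position0 & got$species == row$species, ]
    expect_false(identical(hit$category, "unique_nonhomoplastic"))
  }
})

test_that("diagnosis reports are invariant under terminal relabeling", {
  fix <- toy_diagnosis_fixture()
  res1 <- classify_synapomorphies(fix$tree, fix$aln, c("A1", "A2"))
  relab <- c(out = "x_out", A1 = "x_A1", A2 = "x_A2", B1 = "x_B1",
             B2 = "x_B2")
  phy2 <- fix$tree$phy
  phy2$tip.label <- unname(relab[phy2$tip.label])
  chars2 <- fix$aln$chars
  rownames(chars2) <- unname(relab[rownames(chars2)])
  sm2 <- stats::setNames(fix$aln$species_map, relab[names(fix$aln$species_map)])
  res2 <- classify_synapomorphies(annotated_tree(phy2),
                                  alignment_set(chars2, species_map = sm2),
                                  c("x_A1", "x_A2"))
  expect_identical(res1, res2)
})

test_that("diagnose_all flags absent markers and non-monophyletic species", {
  fix <- toy_diagnosis_fixture()
  # second marker lacks species B entirely
  chars2 <- fix$aln$chars[c("out", "A1", "A2"), 1:3]
  aln2 <- alignment_set(chars2, marker = "m2",
                        species_map = fix$aln$species_map)
  tr2 <- annotated_tree(ape::read.tree(text = "(out,(A1,A2));"))
  rep_out <- diagnose_all(list(m1 = fix$tree, m2 = tr2),
                          list(m1 = fix$aln, m2 = aln2))
  cnt <- rep_out$counts
  expect_equal(cnt$flag[cnt$species == "B" & cnt$marker == "m2"],
               "marker_absent")
  expect_equal(cnt$N[cnt$species == "B" & cnt$marker == "m2"], 0)
  expect_true(all(cnt$N == rowSums(
    cnt[, c("ambiguous", "unique_nonhomoplastic", "unique_homoplastic",
            "nonunique_homoplastic")])))
  # force a non-monophyletic species map on marker 1
  sm_bad <- c(out = "out", A1 = "mix", A2 = "A", B1 = "mix", B2 = "B")
  aln_bad <- alignment_set(fix$aln$chars, species_map = sm_bad)
  rep_bad <- diagnose_all(list(m1 = fix$tree), list(m1 = aln_bad))
  row <- rep_bad$counts[rep_bad$counts$species == "mix", ]
  expect_equal(row$flag, "non_monophyletic")
  expect_equal(row$N, 0)
})
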