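test_that("drugs associate with pathways through their targets", {
  pw <- a_pathway_set(P1 = c("g1", "g2"), P2 = "g3")
  expect_equal(drug_pathways(a_drug("d", "g1"), pw), "P1")
  expect_equal(drug_pathways(a_drug("d", "g9"), pw), character(0))
  expect_setequal(drug_pathways(a_drug("d", c("g1", "g3")), pw),
                  c("P1", "P2"))
})

test_that("pathway pairs classify with the documented precedence", {
  pw <- a_pathway_set(P1 = c("g1", "g2"), P2 = c("g2", "g5"),
                      P3 = "g5", P4 = "g7", P5 = c("g1", "g2"))
  net <- named_graph(c("g1","g5", "g2","g5"))
  expect_equal(classify_pathway_pair("P1", "P1", pw, net), "IDENTICAL")
  expect_equal(classify_pathway_pair("P1", "P2", pw, net), "CROSS_TALKING")
  expect_equal(classify_pathway_pair("P1", "P3", pw, net), "INTERACTING")
  expect_equal(classify_pathway_pair("P3", "P4", pw, net), "PARALLEL")
  # shared gene wins over a bridging edge (P1 and P2 overlap AND g1-g5 bridges)
  expect_equal(classify_pathway_pair("P1", "P2", pw, net), "CROSS_TALKING")
  # equal gene sets under different ids are cross-talking, not identical
  expect_equal(classify_pathway_pair("P1", "P5", pw, net), "CROSS_TALKING")
})

test_that("classification is symmetric", {
  set.seed(8)
  genes <- paste0("g", 1:20)
  pw <- a_pathway_set(A = sample(genes, 5), B = sample(genes, 5),
                      C = sample(genes, 4), D = sample(genes, 6))
  net <- igraph::sample_gnm(20, 25)
  igraph::V(net)$name <- genes
  ids <- names(pw)
  for (a in ids) for (b in ids) {
    expect_equal(classify_pathway_pair(a, b, pw, net),
                 classify_pathway_pair(b, a, pw, net))
  }
})

test_that("combination profiles enumerate pathway pairs across member pairs", {
  pw <- a_pathway_set(P1 = "g1", P2 = "g2", P3 = c("g3", "g1x"))
  net <- named_graph(c("g1","g3"))
  drugs <- a_drug_set(a_drug("A", "g1"), a_drug("B", "g1"),
                      a_drug("C", c("g2", "g3")), a_drug("D", "g2"))

  # both drugs hit only P1: one IDENTICAL pair
  p1 <- combination_profile(a_combo_set("X", list(c("A", "B")))[1, ],
                            drugs, pw, net)
  expect_equal(p1$n_pairs, 1)
  expect_equal(p1$prop_identical, 1)

  # A -> {P1}; C -> {P2, P3}: (P1,P2) parallel, (P1,P3) interacting
  p2 <- combination_profile(a_combo_set("Y", list(c("A", "C")))[1, ],
                            drugs, pw, net)
  expect_equal(p2$n_pairs, 2)
  expect_equal(p2$prop_interacting, 0.5)
  expect_equal(p2$prop_parallel, 0.5)

  # 3-drug combo with one pathway per drug: 3 member pairs -> 3 pathway pairs
  one_each <- a_drug_set(a_drug("A", "g1"), a_drug("B", "g2"),
                         a_drug("D", "g3"))
  p3 <- combination_profile(a_combo_set("Z", list(c("A", "B", "D")))[1, ],
                            one_each, pw, net)
  expect_equal(p3$n_pairs, 3)
})

test_that("profile counts sum to the product of pathway set sizes", {
  set.seed(15)
  genes <- paste0("g", 1:30)
  pw <- structure(lapply(1:6, function(i) sample(genes, 5)),
                  names = paste0("P", 1:6), class = "pathway_set")
  net <- igraph::sample_gnm(30, 40)
  igraph::V(net)$name <- genes
  drugs <- a_drug_set(a_drug("A", sample(genes, 3)),
                      a_drug("B", sample(genes, 3)),
                      a_drug("C", sample(genes, 3)))
  combos <- a_combo_set("T", list(c("A", "B", "C")))
  pws <- lapply(drugs, function(d) drug_pathways(d, pw))
  if (all(lengths(pws) > 0)) {
    expected <- length(pws$A) * length(pws$B) +
      length(pws$A) * length(pws$C) + length(pws$B) * length(pws$C)
    prof <- combination_profile(combos[1, ], drugs, pw, net)
    expect_equal(prof$n_pairs, expected)
    expect_equal(prof$prop_identical + prof$prop_cross_talking +
                   prof$prop_interacting + prof$prop_parallel, 1)
  }
})

test_that("a member with no pathway empties the profile with a message", {
  pw <- a_pathway_set(P1 = "g1")
  net <- named_graph(c("g1","g2"))
  drugs <- a_drug_set(a_drug("A", "g1"), a_drug("B", "g9"))
  expect_message(
    prof <- combination_profile(a_combo_set("W", list(c("A", "B")))[1, ],
                                drugs, pw, net),
    "no associated pathway")
  expect_equal(prof$n_pairs, 0)
  expect_true(is.na(prof$prop_interacting))
})

test_that("removing all edges turns INTERACTING into PARALLEL and nothing else", {
  set.seed(31)
  genes <- paste0("g", 1:25)
  pw <- structure(lapply(1:8, function(i) sample(genes, 4)),
                  names = paste0("P", 1:8), class = "pathway_set")
  net <- igraph::sample_gnm(25, 35)
  igraph::V(net)$name <- genes
  bare <- igraph::delete_edges(net, igraph::E(net))
  for (a in names(pw)) for (b in names(pw)) {
    with_edges <- classify_pathway_pair(a, b, pw, net)
    without <- classify_pathway_pair(a, b, pw, bare)
    if (with_edges == "INTERACTING") {
      expect_equal(without, "PARALLEL")
    } else {
      expect_equal(without, with_edges)
    }
  }
})

test_that("interacting-targeter selection is strictly greater than", {
  prof <- data.frame(combo_id = paste0("C", 1:5),
                     prop_interacting = c(0, 0.39, 0.4, 0.41, 1))
  expect_setequal(select_interacting_targeters(prof, 0.4), c("C4", "C5"))
  prof$prop_interacting[3] <- NA  # empty profile never qualifies
  expect_setequal(select_interacting_targeters(prof, 0.4), c("C4", "C5"))
})
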