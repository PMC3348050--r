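test_that("shortest-path distances match hops, identity and unreachability", {
  g <- named_graph(c("g1","g2", "g2","g3"))
  idx <- distance_index(g)
  expect_equal(shortest_path_distance(idx, "g1", "g3"), 2)
  expect_equal(shortest_path_distance(idx, "g2", "g2"), 0)
  expect_equal(shortest_path_distance(idx, "gX", "gX"), 0)  # absent gene, self
  expect_equal(shortest_path_distance(idx, "g1", "gX"), Inf)
})

test_that("the distance index agrees with a Floyd-Warshall oracle", {
  set.seed(12)
  g <- igraph::sample_gnm(12, 16)
  igraph::V(g)$name <- paste0("g", 1:12)
  idx <- distance_index(g)
  D <- fw_distances(g)
  for (a in rownames(D)) {
    for (b in colnames(D)) {
      expect_equal(shortest_path_distance(idx, a, b), D[a, b])
    }
  }
})

test_that("drug distance is the minimum over target pairs", {
  g <- named_graph(c("g1","g2", "g2","g3"))
  idx <- distance_index(g)
  expect_equal(drug_distance(idx, a_drug("i", "g1"), a_drug("j", "g3")), 2)
  expect_equal(drug_distance(idx, a_drug("i", c("g1", "g9")),
                             a_drug("j", c("g1", "g3"))), 0)  # shared target
  expect_error(drug_distance(idx, a_drug("i", character(0)),
                             a_drug("j", "g1")), "empty target set")
})

test_that("drug distance equals exhaustive enumeration on a 10-node fixture", {
  set.seed(4)
  g <- igraph::sample_gnm(10, 14)
  igraph::V(g)$name <- paste0("g", 1:10)
  idx <- distance_index(g)
  D <- fw_distances(g)
  ti <- c("g1", "g9")
  tj <- c("g3", "g4")
  expect_equal(drug_distance(idx, ti, tj),
               min(D[ti, tj]))
  # symmetry and the single-pair upper bound
  expect_equal(drug_distance(idx, tj, ti), drug_distance(idx, ti, tj))
  for (a in ti) for (b in tj) {
    expect_lte(drug_distance(idx, ti, tj), D[a, b])
  }
})

test_that("adding an edge never increases a drug distance", {
  set.seed(21)
  for (rep in 1:10) {
    g <- igraph::sample_gnm(15, 20)
    igraph::V(g)$name <- paste0("g", 1:15)
    ti <- sample(igraph::V(g)$name, 2)
    tj <- sample(setdiff(igraph::V(g)$name, ti), 2)
    before <- drug_distance(distance_index(g), ti, tj)
    ends <- sample(igraph::V(g)$name, 2)
    g2 <- igraph::add_edges(g, ends)
    g2 <- igraph::simplify(g2)
    after <- drug_distance(distance_index(g2), ti, tj)
    expect_lte(after, before)
  }
})

test_that("effect radius averages the available pair distances", {
  # chain g1-g2 plus chain g3-g4-g5-g6 in a second component:
  # A={g1,g3}, B={g2}, C={g6} gives pair distances {1, 3, unreachable}
  g <- named_graph(c("g1","g2", "g3","g4", "g4","g5", "g5","g6"))
  idx <- distance_index(g)
  drugs <- a_drug_set(a_drug("A", c("g1", "g3")), a_drug("B", "g2"),
                      a_drug("C", "g6"))
  combo <- a_combo_set("T1", list(c("A", "B", "C")))
  r <- effect_radius(idx, combo[1, ], drugs)
  expect_equal(r$radius, 2)  # mean of {1, 3}
  expect_equal(r$n_pairs_used, 2)
  expect_equal(r$n_pairs_unreachable, 1)

  pair <- effect_radius(idx, a_combo_set("T2", list(c("A", "C")))[1, ], drugs)
  expect_equal(pair$radius, 3)
  expect_equal(pair$n_pairs_used, 1)

  shared <- a_drug_set(a_drug("A", "g1"), a_drug("B", c("g1", "g2")),
                       a_drug("C", c("g1", "g6")))
  r0 <- effect_radius(idx, a_combo_set("T3", list(c("A", "B", "C")))[1, ],
                      shared)
  expect_equal(r0$radius, 0)  # all three pairs share g1

  expect_error(effect_radius(idx, a_combo_set("T4", list("A"))[1, ], drugs),
               "fewer than 2")
})

test_that("radius with no reachable pair is undefined", {
  g <- named_graph(c("g1","g2"))
  idx <- distance_index(g)
  drugs <- a_drug_set(a_drug("A", "g1"), a_drug("B", "gX"))
  r <- effect_radius(idx, a_combo_set("T1", list(c("A", "B")))[1, ], drugs)
  expect_true(is.na(r$radius))
  expect_equal(r$n_pairs_unreachable, 1)
})

test_that("radius distributions bin right-closed and sum to one", {
  res <- data.frame(combo_id = paste0("C", 1:4), radius = c(1, 2, 2, 5),
                    n_pairs_used = 1, n_pairs_unreachable = 0)
  h <- radius_distribution(res, breaks = 3)
  expect_equal(unname(h), c(0.75, 0.25))
  expect_equal(sum(h), 1)

  one <- radius_distribution(res[4, ], breaks = 3)
  expect_equal(unname(one), c(0, 1))

  withna <- rbind(res, data.frame(combo_id = "C5", radius = NA,
                                  n_pairs_used = 0, n_pairs_unreachable = 1))
  expect_message(h2 <- radius_distribution(withna, breaks = 3), "excluding 1")
  expect_equal(h2, h)

  allna <- data.frame(combo_id = "C1", radius = NA_real_,
                      n_pairs_used = 0, n_pairs_unreachable = 1)
  expect_error(suppressMessages(radius_distribution(allna)), "no defined radii")
})

test_that("radius strata are inclusive on the left boundary", {
  res <- data.frame(combo_id = paste0("C", 1:2), radius = c(3, 3.0001),
                    n_pairs_used = 1, n_pairs_unreachable = 0)
  s <- stratify_by_radius(res, threshold = 3)
  expect_equal(s$low, "C1")
  expect_equal(s$high, "C2")

  eq <- data.frame(combo_id = paste0("C", 1:3), radius = c(3, 3, 3),
                   n_pairs_used = 1, n_pairs_unreachable = 0)
  expect_length(stratify_by_radius(eq, 3)$high, 0)

  mix <- data.frame(combo_id = paste0("C", 1:5), radius = c(0, 1, 2, 4, 5),
                    n_pairs_used = 1, n_pairs_unreachable = 0)
  s2 <- stratify_by_radius(mix, 3)
  expect_equal(c(length(s2$low), length(s2$high)), c(3, 2))
})
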