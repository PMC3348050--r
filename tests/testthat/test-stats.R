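test_that("small-sample rank-sum p-values are exact", {
  r <- rank_sum_test(c(1, 2), c(3, 4), alternative = "two_sided")
  expect_true(r$exact)
  # the observed split is 1 of C(4,2)=6 equally likely; two-sided doubles 1/6
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$p_value, brute_rank_sum_p(c(1, 2), c(3, 4), "two_sided"))
})

test_that("degenerate identical samples give p = 1 with a warning", {
  expect_warning(r <- rank_sum_test(rep(2, 5), rep(2, 7)), "degenerate")
  expect_equal(r$p_value, 1)
  same <- c(1, 5, 9, 2)
  r2 <- rank_sum_test(same, same, alternative = "two_sided")
  expect_gt(r2$p_value, 0.99)
})

test_that("exact p-values match brute-force enumeration on random samples", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    m <- sample(2:5, 1)
    v <- sample(1:100, n + m)  # distinct -> no ties
    x <- v[seq_len(n)]
    y <- v[-seq_len(n)]
    for (alt in c("two_sided", "real_less", "real_greater")) {
      expect_equal(rank_sum_test(x, y, alternative = alt)$p_value,
                   brute_rank_sum_p(x, y, alt),
                   tolerance = 1e-12)
    }
  }
})

test_that("one-sided p-values are antisymmetric under sample swap", {
  x <- c(3, 9, 17)
  y <- c(5, 11, 20)
  expect_equal(rank_sum_test(x, y, alternative = "real_less")$p_value,
               rank_sum_test(y, x, alternative = "real_greater")$p_value)
})

test_that("p-values respect sidedness and shift invariance", {
  set.seed(9)
  x <- rnorm(8)
  y <- rnorm(8)
  p2 <- rank_sum_test(x, y, "two_sided")$p_value
  expect_gte(p2, min(rank_sum_test(x, y, "real_less")$p_value,
                     rank_sum_test(x, y, "real_greater")$p_value))
  expect_equal(rank_sum_test(x + 100, y + 100, "two_sided")$p_value, p2)
})

test_that("radius comparisons pool nulls and honor the pooling mode", {
  real <- data.frame(combo_id = paste0("C", 1:4),
                     radius = c(0, 1, 1, NA), n_pairs_used = c(1, 1, 1, 0),
                     n_pairs_unreachable = c(0, 0, 0, 1))
  nulls <- lapply(1:3, function(r) {
    data.frame(combo_id = paste0("N", 1:4), radius = c(2, 3, 4, NA) + r / 10,
               n_pairs_used = 1, n_pairs_unreachable = 0)
  })
  res <- compare_radius(real, nulls, alternative = "real_less")
  expect_equal(res$n_x, 3)   # NA radius excluded
  expect_equal(res$n_y, 9)   # pooled, NAs excluded
  expect_lt(res$p_value, 0.05)
  expect_equal(res$pooling, "pooled")

  res_m <- compare_radius(real, nulls, alternative = "real_less",
                          pooling = "replicate_mean")
  expect_equal(res_m$n_y, 3)

  # identical real and null pools are not significant
  same <- compare_radius(real, list(real), alternative = "two_sided")
  expect_gt(same$p_value, 0.9)
})

test_that("pathway-proportion comparisons work per category", {
  mk <- function(p_int, ids) {
    data.frame(combo_id = ids, n_pairs = 10,
               prop_identical = 0, prop_cross_talking = 1 - p_int,
               prop_interacting = p_int, prop_parallel = 0)
  }
  real <- mk(c(0.8, 0.9, 0.7, 0.85), paste0("C", 1:4))
  nulls <- lapply(1:3, function(r) mk(c(0.1, 0.2, 0.15, 0.05), paste0("N", 1:4)))
  res <- compare_pathway_proportion(real, nulls, "INTERACTING",
                                    alternative = "real_greater")
  expect_lt(res$p_value, 0.01)
  res_ct <- compare_pathway_proportion(real, nulls, "CROSS_TALKING",
                                       alternative = "real_less")
  expect_lt(res_ct$p_value, 0.01)
  # all-zero proportions on both sides are degenerate
  z <- mk(0, paste0("C", 1:3))
  expect_warning(
    res0 <- compare_pathway_proportion(z, list(mk(0, paste0("N", 1:3))),
                                       "INTERACTING"),
    "degenerate")
  expect_equal(res0$p_value, 1)
})

test_that("category tallies count incidences as documented", {
  drugs <- a_drug_set(a_drug("d1", "g1", atc = "C01AA05"),
                      a_drug("d2", "g2", atc = "N05AH02"),
                      a_drug("d3", c("g3", "g4"),
                             atc = c("C07AB02", "N02BA01")))
  combos <- a_combo_set(c("C1", "C2", "C3"),
                        list(c("d1", "d2"), c("d1", "d3"), c("d2", "d3")),
                        types = c("synergistic", "synergistic", "additive"))

  t1 <- tally_categories("C1", drugs, combos, "atc_level1")
  expect_equal(t1$counts, c(C = 1L, N = 1L))

  # a drug with ATC codes in two classes contributes to both
  t2 <- tally_categories("C2", drugs, combos, "atc_level1")
  expect_equal(t2$counts, c(C = 2L, N = 1L))

  # incidence counting: d1 counts once per combination membership
  t3 <- tally_categories(c("C1", "C2"), drugs, combos, "atc_level1")
  expect_equal(sum(t3$counts), 5)

  t4 <- tally_categories(combos$combo_id, drugs, combos, "combo_type")
  expect_equal(unname(t4$proportions[c("synergistic", "additive")]),
               c(2 / 3, 1 / 3))
  expect_equal(sum(t4$proportions), 1)

  ann <- c(g1 = "GPCR", g3 = "kinase")
  t5 <- tally_categories("C2", drugs, combos, "target_function",
                         annotation = ann)
  expect_equal(t5$counts, c(GPCR = 1L, kinase = 1L, unclassified = 1L))
  expect_error(tally_categories("C1", drugs, combos, "target_function"),
               "annotation")

  # invariant to combination ordering
  t6 <- tally_categories(rev(combos$combo_id), drugs, combos, "atc_level1")
  t7 <- tally_categories(combos$combo_id, drugs, combos, "atc_level1")
  expect_identical(t6$counts, t7$counts)
})
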