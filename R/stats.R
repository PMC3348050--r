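#' Wilcoxon rank-sum comparison of two samples
#'
#' Thin, explicit wrapper around the Mann-Whitney/Wilcoxon rank-sum test.
#' Ties are handled by midranks. The exact null distribution is used when the
#' pooled sample has at most 12 observations and no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. When every pooled value is identical the comparison is degenerate:
#' a warning is raised and the two-sided p-value is 1.
#'
#' @param x,y Non-empty numeric samples. By convention `x` holds the real
#'   combinations and `y` the null sample, so `alternative = "real_less"`
#'   tests whether `x` is stochastically smaller than `y`.
#' @param alternative One of `"two_sided"` (default), `"real_less"`,
#'   `"real_greater"`.
#' @param statistic_name Label carried into the result (e.g.
#'   `"effect_radius"`).
#' @return A `rank_sum_result`: list with `statistic_name`, `n_x`, `n_y`,
#'   `rank_sum_statistic` (the Mann-Whitney U for `x`), `p_value`,
#'   `alternative`, `exact` (logical), and `rank_biserial` (effect size,
#'   printed for context).
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two_sided", "real_less", "real_greater"),
                          statistic_name = "statistic") {
  alternative <- match.arg(alternative)
  stopifnot(length(x) > 0, length(y) > 0, is.numeric(x), is.numeric(y))
  alt <- switch(alternative, two_sided = "two.sided", real_less = "less",
                real_greater = "greater")
  pooled <- c(x, y)
  u <- sum(rank(pooled)[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  degenerate <- length(unique(pooled)) == 1
  if (degenerate) {
    warning("rank_sum_test: all pooled values identical; comparison is degenerate",
            call. = FALSE)
    p <- 1
  } else {
    exact <- (length(x) + length(y) <= 12) && !anyDuplicated(pooled)
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alt, exact = exact,
                         correct = TRUE)$p.value)
  }
  exact <- !degenerate && (length(x) + length(y) <= 12) && !anyDuplicated(pooled)
  structure(list(statistic_name = statistic_name,
                 n_x = length(x), n_y = length(y),
                 rank_sum_statistic = unname(u),
                 p_value = p, alternative = alternative, exact = exact,
                 rank_biserial = unname(2 * u / (length(x) * length(y)) - 1)),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: %s (n_x=%d, n_y=%d, %s)\n  U = %g, p = %g (%s), rank-biserial = %.3f\n",
              x$statistic_name, x$n_x, x$n_y,
              if (x$exact) "exact" else "normal approximation",
              x$rank_sum_statistic, x$p_value, x$alternative,
              x$rank_biserial))
  invisible(x)
}

# Pool a per-replicate list of numeric vectors according to `pooling`:
# "pooled" concatenates all replicates into one sample; "replicate_mean"
# summarizes each replicate by its mean first.
pool_null <- function(values_per_replicate, pooling) {
  if (pooling == "pooled") {
    unlist(values_per_replicate, use.names = FALSE)
  } else {
    vapply(values_per_replicate, mean, numeric(1))
  }
}

#' Compare real effect radii against the null ensemble
#'
#' Runs [rank_sum_test()] on the defined (non-NA) radii of the real
#' combinations against the null radii. Null radii from all replicates are
#' pooled into one sample by default; `pooling = "replicate_mean"` instead
#' summarizes each replicate by its mean radius. The pooling mode is recorded
#' in the result.
#'
#' @param real Output of [effect_radii()] on the real combinations.
#' @param null_per_replicate A list of [effect_radii()] outputs, one per null
#'   replicate (or a single data frame, treated as one pooled replicate).
#' @param alternative Test sidedness (default `"real_less"`: real radii
#'   smaller than null).
#' @param pooling `"pooled"` (default) or `"replicate_mean"`.
#' @return A `rank_sum_result` with a `pooling` field.
#' @export
compare_radius <- function(real, null_per_replicate,
                           alternative = "real_less", pooling = c("pooled", "replicate_mean")) {
  pooling <- match.arg(pooling)
  if (is.data.frame(null_per_replicate)) {
    null_per_replicate <- list(null_per_replicate)
  }
  rx <- real$radius[!is.na(real$radius)]
  ny <- pool_null(lapply(null_per_replicate,
                         function(d) d$radius[!is.na(d$radius)]), pooling)
  res <- rank_sum_test(rx, ny, alternative = alternative,
                       statistic_name = "effect_radius")
  res$pooling <- pooling
  res
}

#' Compare a pathway-pair proportion against the null ensemble
#'
#' Runs [rank_sum_test()] on the per-combination proportion of the named
#' pathway-pair category (real vs null), excluding combinations with empty
#' profiles. Pooling as in [compare_radius()].
#'
#' @param real_profiles Output of [combination_profiles()] on the real
#'   combinations.
#' @param null_profiles A list of per-replicate profile data frames (or one
#'   data frame).
#' @param category One of `"IDENTICAL"`, `"CROSS_TALKING"`, `"INTERACTING"`,
#'   `"PARALLEL"`.
#' @param alternative Test sidedness (default `"real_greater"`).
#' @param pooling `"pooled"` (default) or `"replicate_mean"`.
#' @return A `rank_sum_result` with a `pooling` field.
#' @export
compare_pathway_proportion <- function(real_profiles, null_profiles,
                                       category = "INTERACTING",
                                       alternative = "real_greater",
                                       pooling = c("pooled", "replicate_mean")) {
  pooling <- match.arg(pooling)
  category <- match.arg(category, PATHWAY_RELATIONS)
  col <- paste0("prop_", tolower(category))
  if (is.data.frame(null_profiles)) null_profiles <- list(null_profiles)
  rx <- real_profiles[[col]][!is.na(real_profiles[[col]])]
  ny <- pool_null(lapply(null_profiles,
                         function(d) d[[col]][!is.na(d[[col]])]), pooling)
  res <- rank_sum_test(rx, ny, alternative = alternative,
                       statistic_name = paste0("prop_", tolower(category)))
  res$pooling <- pooling
  res
}

#' Tally drugs or combinations over category labels
#'
#' Reproduces the descriptive tallies of the analysis:
#' \describe{
#'   \item{atc_level1}{each (combination membership, drug, ATC level-1 class)
#'     incidence over the member drugs of the selected combinations. A drug
#'     appearing in several selected combinations counts once per membership;
#'     a drug with ATC codes in several level-1 classes counts in each.}
#'   \item{combo_type}{selected combinations counted by their combination
#'     type.}
#'   \item{target_function}{target genes of the member drugs counted by a
#'     supplied gene -> function-class map; unmapped genes count as
#'     "unclassified".}
#' }
#'
#' @param combo_ids Ids of the selected combinations.
#' @param drugs A `drug_set`.
#' @param combos The `combo_set` the ids refer to.
#' @param grouping One of `"atc_level1"`, `"combo_type"`,
#'   `"target_function"`.
#' @param annotation Named character vector mapping gene id to function label
#'   (required for `grouping = "target_function"`).
#' @return A `category_tally`: list with `grouping`, `counts` (named integer)
#'   and `proportions` (named numeric summing to 1).
#' @export
tally_categories <- function(combo_ids, drugs, combos,
                             grouping = c("atc_level1", "combo_type", "target_function"),
                             annotation = NULL) {
  grouping <- match.arg(grouping)
  sel <- combos[combos$combo_id %in% combo_ids, , drop = FALSE]
  labels <- switch(grouping,
    atc_level1 = unlist(lapply(sel$members, function(m) {
      unlist(lapply(m, function(d) {
        unique(substr(drugs[[d]]$atc_codes, 1, 1))
      }))
    })),
    combo_type = sel$combo_type,
    target_function = {
      if (is.null(annotation)) {
        stop("grouping 'target_function' requires an annotation map",
             call. = FALSE)
      }
      unlist(lapply(sel$members, function(m) {
        unlist(lapply(m, function(d) {
          g <- drugs[[d]]$targets
          lab <- unname(annotation[g])
          lab[is.na(lab)] <- "unclassified"
          lab
        }))
      }))
    })
  counts <- table(labels)
  counts <- setNames(as.integer(counts), names(counts))
  props <- if (sum(counts) > 0) counts / sum(counts) else numeric(0)
  structure(list(grouping = grouping, counts = counts, proportions = props),
            class = "category_tally")
}

#' @export
print.category_tally <- function(x, ...) {
  cat(sprintf("Category tally (%s):\n", x$grouping))
  for (l in names(x$counts)) {
    cat(sprintf("  %-16s %6d  (%.1f%%)\n", l, x$counts[[l]],
                100 * x$proportions[[l]]))
  }
  invisible(x)
}

#' Serialize a comparison result or tally to JSON
#'
#' @param x A `rank_sum_result` or `category_tally`.
#' @param path Output path.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
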