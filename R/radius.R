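#' Build a shortest-path distance index over a gene network
#'
#' Wraps a genetic interaction network for repeated unweighted shortest-path
#' queries. Distances are computed by breadth-first search from each queried
#' source gene and cached, so scoring many combinations against the same
#' network touches each source gene once.
#'
#' @param net An undirected igraph over gene nodes.
#' @return A `distance_index` object.
#' @export
distance_index <- function(net) {
  structure(list(net = net, nodes = igraph::V(net)$name,
                 cache = new.env(parent = emptyenv())),
            class = "distance_index")
}

# Cached BFS distance row from `gene` to all network nodes (named numeric,
# Inf across components). Returns NULL for genes absent from the network.
index_row <- function(index, gene) {
  if (!gene %in% index$nodes) return(NULL)
  row <- index$cache[[gene]]
  if (is.null(row)) {
    row <- igraph::distances(index$net, v = gene, to = igraph::V(index$net),
                             weights = NA)[1, ]
    names(row) <- index$nodes
    index$cache[[gene]] <- row
  }
  row
}

#' Shortest-path hop distance between two genes
#'
#' Unweighted shortest-path length in the indexed network. Genes absent from
#' the network are unreachable from everything except themselves;
#' `dist(g, g)` is 0 for any gene. Unreachable pairs return `Inf`.
#'
#' @param index A `distance_index`.
#' @param a,b Gene identifiers.
#' @return A non-negative hop count, or `Inf` if unreachable.
#' @export
shortest_path_distance <- function(index, a, b) {
  if (a == b) return(0)
  row <- index_row(index, a)
  if (is.null(row) || !b %in% index$nodes) return(Inf)
  unname(row[[b]])
}

#' Distance between two drugs over the genetic interaction network
#'
#' The drug-drug distance is the minimum, over all pairs of one target of
#' each drug, of the gene-gene shortest-path distance. A shared target gives
#' distance 0; the distance is `Inf` iff every target pair is unreachable.
#'
#' @param index A `distance_index`.
#' @param drug_i,drug_j Drug records (lists with a `targets` field) or plain
#'   character vectors of target genes. Empty target sets are an error:
#'   combinations must pass [filter_combinations()] first.
#' @return A non-negative hop count or `Inf`.
#' @export
drug_distance <- function(index, drug_i, drug_j) {
  ti <- if (is.list(drug_i)) drug_i$targets else drug_i
  tj <- if (is.list(drug_j)) drug_j$targets else drug_j
  if (length(ti) == 0 || length(tj) == 0) {
    stop("drug_distance: drug with empty target set (filter upstream)",
         call. = FALSE)
  }
  if (length(intersect(ti, tj)) > 0) return(0)
  ti_in <- ti[ti %in% index$nodes]
  tj_in <- tj[tj %in% index$nodes]
  if (length(ti_in) == 0 || length(tj_in) == 0) return(Inf)
  best <- Inf
  for (g in ti_in) {
    row <- index_row(index, g)
    best <- min(best, min(row[tj_in]))
  }
  best
}

#' Effect radius of a drug combination
#'
#' The effect radius R of a combination with members \eqn{1..k} is the mean,
#' over the set D of all unordered member pairs (|D| = C(k,2)), of the
#' drug-drug distance dis(i,j), restricted to the pairs where that distance
#' is available: unreachable pairs are excluded from both numerator and
#' denominator and reported in `n_pairs_unreachable`. R is undefined (NA)
#' when no pair is reachable.
#'
#' @param index A `distance_index`.
#' @param combo One row of a `combo_set` (a list/data frame row with
#'   `combo_id` and `members`).
#' @param drugs A `drug_set` lookup.
#' @return A one-row data frame: `combo_id`, `radius` (NA if undefined),
#'   `n_pairs_used`, `n_pairs_unreachable`.
#' @export
effect_radius <- function(index, combo, drugs) {
  members <- if (is.data.frame(combo)) combo$members[[1]] else combo$members
  combo_id <- if (is.data.frame(combo)) combo$combo_id[[1]] else combo$combo_id
  if (length(members) < 2) {
    stop(sprintf("combination '%s' has fewer than 2 members", combo_id),
         call. = FALSE)
  }
  prs <- utils::combn(members, 2)
  d <- vapply(seq_len(ncol(prs)), function(k) {
    drug_distance(index, drugs[[prs[1, k]]], drugs[[prs[2, k]]])
  }, numeric(1))
  used <- is.finite(d)
  data.frame(combo_id = combo_id,
             radius = if (any(used)) mean(d[used]) else NA_real_,
             n_pairs_used = sum(used),
             n_pairs_unreachable = sum(!used),
             stringsAsFactors = FALSE)
}

#' Effect radii for a whole combination set
#'
#' @inheritParams effect_radius
#' @param combos A `combo_set`.
#' @return A data frame with one [effect_radius()] row per combination.
#' @export
effect_radii <- function(index, combos, drugs) {
  n <- nrow(combos)
  radius <- numeric(n)
  used <- integer(n)
  unreach <- integer(n)
  for (i in seq_len(n)) {
    members <- combos$members[[i]]
    if (length(members) < 2) {
      stop(sprintf("combination '%s' has fewer than 2 members",
                   combos$combo_id[i]), call. = FALSE)
    }
    prs <- utils::combn(members, 2)
    d <- vapply(seq_len(ncol(prs)), function(k) {
      drug_distance(index, drugs[[prs[1, k]]], drugs[[prs[2, k]]])
    }, numeric(1))
    fin <- is.finite(d)
    radius[i] <- if (any(fin)) mean(d[fin]) else NA_real_
    used[i] <- sum(fin)
    unreach[i] <- sum(!fin)
  }
  data.frame(combo_id = as.character(combos$combo_id), radius = radius,
             n_pairs_used = used, n_pairs_unreachable = unreach,
             stringsAsFactors = FALSE)
}

#' Distribution of effect radii over bins
#'
#' Proportions of defined radii falling in right-closed bins `(b[i], b[i+1]]`
#' defined by `breaks` (with implicit leading -Inf and trailing Inf bounds),
#' so `breaks = 3` yields the two strata `<=3` and `>3`. Undefined radii are
#' excluded with a message; all-undefined input is an error.
#'
#' @param results Output of [effect_radii()].
#' @param breaks Increasing numeric upper bin bounds (default `0:9`, giving
#'   integer bins plus a terminal `>9` bin).
#' @return A named numeric vector of proportions summing to 1.
#' @export
radius_distribution <- function(results, breaks = 0:9) {
  r <- results$radius
  if (anyNA(r)) {
    message(sprintf("radius_distribution: excluding %d undefined radii",
                    sum(is.na(r))))
    r <- r[!is.na(r)]
  }
  if (length(r) == 0) stop("no defined radii", call. = FALSE)
  edges <- unique(c(-Inf, breaks, Inf))
  cuts <- cut(r, breaks = edges, right = TRUE, include.lowest = TRUE)
  props <- as.numeric(table(cuts)) / length(r)
  names(props) <- levels(cuts)
  props
}

#' Stratify combinations by effect radius
#'
#' Partitions the combinations with a defined radius into those with radius
#' at or below the threshold and those above it (the boundary falls in the
#' lower stratum, matching the `<=3` / `>3` split used downstream).
#'
#' @param results Output of [effect_radii()].
#' @param threshold Stratum boundary (default 3).
#' @return A list with character vectors `low` (R <= threshold) and `high`
#'   (R > threshold).
#' @export
stratify_by_radius <- function(results, threshold = 3) {
  def <- results[!is.na(results$radius), , drop = FALSE]
  list(low = def$combo_id[def$radius <= threshold],
       high = def$combo_id[def$radius > threshold])
}

#' Write effect-radius results as TSV
#'
#' @param results Output of [effect_radii()].
#' @param path Output path.
#' @export
write_radius_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
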