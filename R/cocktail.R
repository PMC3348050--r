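#' Build the drug cocktail network from effective combinations
#'
#' Nodes are drugs; an edge joins every pair of drugs that appear together in
#' at least one combination. Multi-drug combinations contribute all their
#' unordered member pairs (a clique); a pair recurring in several
#' combinations yields a single edge.
#'
#' @param combos A filtered `combo_set` (see [filter_combinations()]).
#' @return An undirected simple [igraph::igraph] over drug nodes.
#' @export
build_cocktail_network <- function(combos) {
  if (nrow(combos) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  pairs <- do.call(rbind, lapply(combos$members, function(m) {
    t(utils::combn(sort(m), 2))
  }))
  nodes <- sort(unique(c(pairs)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2], stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes))
  igraph::simplify(g)
}

#' Degree-preserving edge shuffle
#'
#' Randomizes the edges of a simple undirected network by repeated
#' double-edge swaps (pick edges (a,b) and (c,d); rewire to (a,d) and (c,b))
#' while rejecting any swap that would create a self-loop or multi-edge, so
#' every node keeps its exact degree. Deterministic given `seed`.
#'
#' @param net A simple undirected igraph with at least 2 edges.
#' @param seed Integer seed controlling the swap sequence.
#' @param n_swaps_per_edge Attempted swaps per edge; total attempt budget is
#'   `n_swaps_per_edge * ecount(net)` (default 10, enough to decorrelate the
#'   edge set from the input on sparse graphs).
#' @return A simple undirected igraph on the same nodes with the same degree
#'   sequence. If the attempt budget produces no change (e.g. the degree
#'   sequence admits a unique simple graph, as for a star), the input is
#'   returned with a warning.
#' @export
shuffle_preserving_degree <- function(net, seed, n_swaps_per_edge = 10) {
  if (igraph::ecount(net) < 2) {
    stop("shuffle_preserving_degree requires a network with >= 2 edges",
         call. = FALSE)
  }
  niter <- n_swaps_per_edge * igraph::ecount(net)
  out <- withr::with_seed(as.integer(seed), {
    igraph::rewire(net, igraph::keeping_degseq(loops = FALSE, niter = niter))
  })
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r"))
  }
  if (identical(key(out), key(net))) {
    warning("shuffle left the network unchanged (no valid swap applied)",
            call. = FALSE)
  }
  out
}

#' Generate a degree-preserving null ensemble
#'
#' Produces `n_replicates` independent degree-preserving shuffles of `net`;
#' replicate r uses seed `seed + r`, so the full ensemble is reproducible
#' from a single integer. The reference analysis used 1,000 replicates.
#'
#' @inheritParams shuffle_preserving_degree
#' @param n_replicates Number of shuffled replicates (>= 1).
#' @return A `null_ensemble`: list with `replicates` (list of igraphs),
#'   `seed`, `n_replicates`, `n_swaps_per_edge`.
#' @export
generate_null_ensemble <- function(net, n_replicates, seed,
                                   n_swaps_per_edge = 10) {
  stopifnot(n_replicates >= 1)
  reps <- lapply(seq_len(n_replicates), function(r) {
    shuffle_preserving_degree(net, seed = seed + r,
                              n_swaps_per_edge = n_swaps_per_edge)
  })
  structure(list(replicates = reps, seed = seed,
                 n_replicates = n_replicates,
                 n_swaps_per_edge = n_swaps_per_edge),
            class = "null_ensemble")
}

#' Turn each null-ensemble edge into a pairwise random combination
#'
#' Each edge (di, dj) of each replicate becomes a 2-member combination with
#' `combo_type` and `status` "unknown", so the shuffled networks can be
#' scored by the same radius and pathway machinery as the real combinations.
#'
#' @param ens A `null_ensemble`.
#' @return A list (one element per replicate) of `combo_set` data frames.
#' @export
null_edges_as_combinations <- function(ens) {
  stopifnot(inherits(ens, "null_ensemble"))
  lapply(seq_along(ens$replicates), function(r) {
    el <- igraph::as_edgelist(ens$replicates[[r]])
    n <- nrow(el)
    out <- data.frame(
      combo_id = if (n) sprintf("null_r%d_e%d", r, seq_len(n)) else character(0),
      combo_type = rep("unknown", n), status = rep("unknown", n),
      stringsAsFactors = FALSE)
    out$members <- if (n) {
      lapply(seq_len(n), function(i) sort(c(el[i, 1], el[i, 2])))
    } else {
      list()
    }
    class(out) <- c("combo_set", "data.frame")
    out
  })
}

#' Persist a null ensemble as edge-list TSVs plus a JSON manifest
#'
#' @param ens A `null_ensemble`.
#' @param dir Output directory (created if needed). Writes
#'   `replicate_<r>.tsv` per replicate and `manifest.json` recording the
#'   seed, replicate count and swap budget.
#' @export
write_null_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(ens$replicates)) {
    write_gene_network(ens$replicates[[r]],
                       file.path(dir, sprintf("replicate_%d.tsv", r)))
  }
  jsonlite::write_json(
    list(seed = ens$seed, n_replicates = ens$n_replicates,
         n_swaps_per_edge = ens$n_swaps_per_edge),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
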