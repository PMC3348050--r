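# Independent oracles and fixture builders. The oracles deliberately avoid
# the package's own code paths (igraph BFS, wilcox.test).

# Floyd-Warshall all-pairs hop distances via the triple loop.
fw_distances <- function(g) {
  n <- igraph::vcount(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  for (i in seq_len(nrow(el))) {
    D[el[i, 1], el[i, 2]] <- 1
    D[el[i, 2], el[i, 1]] <- 1
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  rownames(D) <- colnames(D) <- igraph::V(g)$name
  D
}

# Brute-force rank-sum p-value by enumerating every assignment of the pooled
# values to the two groups.
brute_rank_sum_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(length(pooled), n)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  pl <- mean(us <= u_obs)
  pg <- mean(us >= u_obs)
  switch(alternative,
         real_less = pl,
         real_greater = pg,
         two_sided = min(1, 2 * min(pl, pg)))
}

# A named undirected graph from a flat character vector of edge endpoints.
named_graph <- function(edges, isolated = character(0)) {
  g <- igraph::make_graph(edges, directed = FALSE)
  if (length(isolated) > 0) g <- igraph::add_vertices(g, length(isolated),
                                                      name = isolated)
  g
}

a_drug <- function(id, targets, atc = "C01AA01") {
  structure(list(drug_id = id, targets = targets, atc_codes = atc),
            class = "drug_record")
}

a_drug_set <- function(...) {
  ds <- list(...)
  structure(stats::setNames(ds, vapply(ds, `[[`, "", "drug_id")),
            class = "drug_set")
}

a_combo_set <- function(ids, members, types = "unknown", status = "unknown") {
  out <- data.frame(combo_id = ids,
                    combo_type = rep_len(types, length(ids)),
                    status = rep_len(status, length(ids)),
                    stringsAsFactors = FALSE)
  out$members <- members
  class(out) <- c("combo_set", "data.frame")
  out
}

a_pathway_set <- function(...) {
  structure(list(...), class = "pathway_set")
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

sorted_edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
}
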