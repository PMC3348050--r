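PATHWAY_RELATIONS <- c("IDENTICAL", "CROSS_TALKING", "INTERACTING", "PARALLEL")

#' Pathways associated with a drug
#'
#' A drug is associated with every pathway whose gene set contains at least
#' one of the drug's target proteins.
#'
#' @param drug A drug record (list with a `targets` field) or a character
#'   vector of target genes.
#' @param pathways A `pathway_set` (named list of gene vectors).
#' @return Character vector of pathway ids (possibly empty).
#' @export
drug_pathways <- function(drug, pathways) {
  targets <- if (is.list(drug)) drug$targets else drug
  hit <- vapply(pathways, function(g) any(targets %in% g), logical(1))
  names(pathways)[hit]
}

#' Classify the relation between two pathways
#'
#' Categories, in precedence order when several definitions apply:
#' \describe{
#'   \item{IDENTICAL}{the same pathway id on both sides;}
#'   \item{CROSS_TALKING}{the gene sets share at least one gene;}
#'   \item{INTERACTING}{at least one genetic-interaction edge joins a gene of
#'     one pathway to a gene of the other;}
#'   \item{PARALLEL}{none of the above (unrelated pathways).}
#' }
#' Sharing a gene is treated as the stronger relation than being bridged by
#' an edge, so overlapping pathways that also have cross edges classify as
#' CROSS_TALKING. Two distinct ids with equal gene sets are CROSS_TALKING,
#' not IDENTICAL (identity is by id). Symmetric in `id_a`/`id_b`.
#'
#' @param id_a,id_b Pathway ids (names in `pathways`).
#' @param pathways A `pathway_set`.
#' @param net The filtered genetic interaction network (igraph).
#' @return One of `"IDENTICAL"`, `"CROSS_TALKING"`, `"INTERACTING"`,
#'   `"PARALLEL"`.
#' @export
classify_pathway_pair <- function(id_a, id_b, pathways, net) {
  if (id_a == id_b) return("IDENTICAL")
  ga <- pathways[[id_a]]
  gb <- pathways[[id_b]]
  if (is.null(ga) || is.null(gb)) {
    stop("unknown pathway id", call. = FALSE)
  }
  if (length(intersect(ga, gb)) > 0) return("CROSS_TALKING")
  nodes <- igraph::V(net)$name
  va <- ga[ga %in% nodes]
  vb <- gb[gb %in% nodes]
  if (length(va) > 0 && length(vb) > 0) {
    # any edge with one endpoint in each pathway
    inc <- igraph::as_edgelist(net)
    bridging <- (inc[, 1] %in% va & inc[, 2] %in% vb) |
      (inc[, 1] %in% vb & inc[, 2] %in% va)
    if (any(bridging)) return("INTERACTING")
  }
  "PARALLEL"
}

# Memoizing classifier over unordered pathway-id pairs; precomputes the edge
# list once. Used by combination_profiles where the same pair recurs often.
pathway_pair_classifier <- function(pathways, net) {
  cache <- new.env(parent = emptyenv())
  el <- igraph::as_edgelist(net)
  nodes <- igraph::V(net)$name
  function(id_a, id_b) {
    if (id_a == id_b) return("IDENTICAL")
    key <- paste(sort(c(id_a, id_b)), collapse = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ga <- pathways[[id_a]]
    gb <- pathways[[id_b]]
    lab <- if (length(intersect(ga, gb)) > 0) {
      "CROSS_TALKING"
    } else {
      va <- ga[ga %in% nodes]
      vb <- gb[gb %in% nodes]
      bridging <- length(va) > 0 && length(vb) > 0 &&
        any((el[, 1] %in% va & el[, 2] %in% vb) |
              (el[, 1] %in% vb & el[, 2] %in% va))
      if (bridging) "INTERACTING" else "PARALLEL"
    }
    cache[[key]] <- lab
    lab
  }
}

profile_row <- function(combo_id, counts) {
  total <- sum(counts)
  props <- if (total > 0) counts / total else rep(NA_real_, 4)
  out <- data.frame(combo_id = combo_id, n_pairs = total,
                    stringsAsFactors = FALSE)
  for (i in seq_along(PATHWAY_RELATIONS)) {
    out[[paste0("n_", tolower(PATHWAY_RELATIONS[i]))]] <- counts[i]
    out[[paste0("prop_", tolower(PATHWAY_RELATIONS[i]))]] <- props[i]
  }
  out
}

#' Pathway-pair profile of one drug combination
#'
#' For every unordered pair of member drugs, every pathway associated with
#' one drug is paired with every pathway associated with the other, each pair
#' is classified with [classify_pathway_pair()], and the counts are
#' aggregated over member pairs. Proportions normalize the counts. If any
#' member drug has no associated pathway the profile is empty (zero pairs,
#' NA proportions) and a message is logged.
#'
#' @param combo One row of a `combo_set`.
#' @param drugs A `drug_set`.
#' @param pathways A `pathway_set`.
#' @param net The genetic interaction network.
#' @param classifier Optional memoized classifier from an enclosing
#'   [combination_profiles()] call (internal).
#' @return A one-row data frame: `combo_id`, `n_pairs`, and a count and
#'   proportion column per relation category.
#' @export
combination_profile <- function(combo, drugs, pathways, net,
                                classifier = NULL) {
  members <- if (is.data.frame(combo)) combo$members[[1]] else combo$members
  combo_id <- if (is.data.frame(combo)) combo$combo_id[[1]] else combo$combo_id
  if (is.null(classifier)) classifier <- pathway_pair_classifier(pathways, net)
  pw <- lapply(members, function(m) drug_pathways(drugs[[m]], pathways))
  counts <- setNames(rep(0L, 4), PATHWAY_RELATIONS)
  if (any(lengths(pw) == 0)) {
    message(sprintf(
      "combination_profile: '%s' skipped (member with no associated pathway)",
      combo_id))
    return(profile_row(combo_id, counts))
  }
  prs <- utils::combn(seq_along(members), 2)
  for (k in seq_len(ncol(prs))) {
    for (pa in pw[[prs[1, k]]]) {
      for (pb in pw[[prs[2, k]]]) {
        lab <- classifier(pa, pb)
        counts[lab] <- counts[lab] + 1L
      }
    }
  }
  profile_row(combo_id, counts)
}

#' Pathway-pair profiles for a whole combination set
#'
#' @inheritParams combination_profile
#' @param combos A `combo_set`.
#' @return A data frame with one [combination_profile()] row per combination.
#' @export
combination_profiles <- function(combos, drugs, pathways, net,
                                 classifier = NULL) {
  cls <- if (is.null(classifier)) pathway_pair_classifier(pathways, net) else classifier
  n <- nrow(combos)
  counts <- matrix(0L, n, 4, dimnames = list(NULL, PATHWAY_RELATIONS))
  pw_cache <- new.env(parent = emptyenv())
  pw_for <- function(d) {
    hit <- pw_cache[[d]]
    if (is.null(hit)) {
      hit <- drug_pathways(drugs[[d]], pathways)
      pw_cache[[d]] <- hit
    }
    hit
  }
  n_skipped <- 0
  for (i in seq_len(n)) {
    members <- combos$members[[i]]
    pw <- lapply(members, pw_for)
    if (any(lengths(pw) == 0)) {
      n_skipped <- n_skipped + 1
      next
    }
    prs <- utils::combn(seq_along(members), 2)
    for (k in seq_len(ncol(prs))) {
      for (pa in pw[[prs[1, k]]]) {
        for (pb in pw[[prs[2, k]]]) {
          lab <- cls(pa, pb)
          counts[i, lab] <- counts[i, lab] + 1L
        }
      }
    }
  }
  if (n_skipped > 0) {
    message(sprintf(
      "combination_profiles: %d combination(s) skipped (member with no associated pathway)",
      n_skipped))
  }
  total <- rowSums(counts)
  out <- data.frame(combo_id = as.character(combos$combo_id), n_pairs = total,
                    stringsAsFactors = FALSE)
  for (rel in PATHWAY_RELATIONS) {
    out[[paste0("n_", tolower(rel))]] <- counts[, rel]
    out[[paste0("prop_", tolower(rel))]] <- ifelse(total > 0,
                                                   counts[, rel] / total,
                                                   NA_real_)
  }
  out
}

#' Select combinations that target interacting pathways
#'
#' Returns the combinations whose proportion of INTERACTING pathway pairs is
#' strictly greater than the threshold (default 0.4, so a proportion of
#' exactly 0.4 is excluded). Combinations with empty profiles never qualify.
#'
#' @param profiles Output of [combination_profiles()].
#' @param threshold Strict lower bound on the INTERACTING proportion.
#' @return Character vector of combo ids.
#' @export
select_interacting_targeters <- function(profiles, threshold = 0.4) {
  ok <- !is.na(profiles$prop_interacting) &
    profiles$prop_interacting > threshold
  profiles$combo_id[ok]
}

#' Write pathway profiles as TSV
#'
#' @param profiles Output of [combination_profiles()].
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
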