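#' @importFrom utils read.delim write.table count.fields
#' @importFrom stats setNames
NULL

COMBO_TYPES <- c("synergistic", "additive", "antagonistic", "potentiative", "unknown")
COMBO_STATUS <- c("approved", "clinical", "preclinical", "unknown")

# Validate that every line of a TSV has the expected field count; errors name
# the offending line (1-based, header included).
check_tsv_shape <- function(path, n_fields) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != n_fields)
  if (length(bad) > 0) {
    stop(sprintf("malformed row in '%s': line %d has %d fields, expected %d",
                 path, bad[1], nf[bad[1]], n_fields), call. = FALSE)
  }
  invisible(TRUE)
}

read_tsv_strict <- function(path, n_fields, col_names) {
  check_tsv_shape(path, n_fields)
  df <- read.delim(path, sep = "\t", quote = "", comment.char = "",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(df), col_names)) {
    stop(sprintf("'%s': expected header %s, found %s", path,
                 paste(col_names, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a genetic interaction network from a TSV edge list
#'
#' Reads a three-column TSV (`gene_a`, `gene_b`, `p_value`) of candidate
#' genetic interactions and keeps only edges with `p_value` strictly below
#' `p_threshold`. Duplicate gene pairs (in either orientation) are collapsed
#' to a single edge retaining the minimum p-value; self-loops are dropped
#' with a warning but their gene is kept as an isolated node.
#'
#' @param path Path to the TSV file. A header row is required.
#' @param p_threshold Retention threshold; an interaction is kept iff its
#'   p-value is strictly less than this (default `1e-7`).
#' @return An undirected [igraph::igraph] with vertex names and an edge
#'   attribute `p_value`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_a\tgene_b\tp_value", "g1\tg2\t1e-9", "g2\tg3\t1e-6"), tf)
#' net <- read_genetic_interactions(tf)
#' igraph::ecount(net)  # 1: the g2-g3 row fails the strict p < 1e-7 filter
#' @export
read_genetic_interactions <- function(path, p_threshold = 1e-7) {
  stopifnot(is.numeric(p_threshold), length(p_threshold) == 1,
            p_threshold > 0, p_threshold <= 1)
  df <- read_tsv_strict(path, 3, c("gene_a", "gene_b", "p_value"))
  p <- suppressWarnings(as.numeric(df$p_value))
  if (anyNA(p)) {
    bad <- which(is.na(p))[1]
    stop(sprintf("malformed row in '%s': line %d has non-numeric p_value '%s'",
                 path, bad + 1L, df$p_value[bad]), call. = FALSE)
  }
  df$p_value <- p
  keep <- df$p_value < p_threshold
  df <- df[keep, , drop = FALSE]

  loops <- df$gene_a == df$gene_b
  loop_nodes <- character(0)
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop interaction(s); node(s) retained",
                    sum(loops)), call. = FALSE)
    loop_nodes <- unique(df$gene_a[loops])
    df <- df[!loops, , drop = FALSE]
  }

  # collapse duplicates (either orientation) keeping the minimum p
  a <- pmin(df$gene_a, df$gene_b)
  b <- pmax(df$gene_a, df$gene_b)
  key <- paste(a, b, sep = "\r")
  pmin_by_key <- tapply(df$p_value, key, min)
  keys <- names(pmin_by_key)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                      gene_b = vapply(parts, `[`, "", 2L),
                      p_value = as.numeric(pmin_by_key),
                      stringsAsFactors = FALSE)
  nodes <- unique(c(edges$gene_a, edges$gene_b, loop_nodes))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g
}

#' Write a gene (or drug) network back to its TSV edge-list format
#'
#' Inverse of [read_genetic_interactions()]: emits `gene_a`, `gene_b`,
#' `p_value` columns. Networks without a `p_value` edge attribute (e.g. the
#' drug cocktail network) are written with `p_value` 0 so the file round-trips
#' through any strict threshold.
#'
#' @param net An undirected igraph with vertex names.
#' @param path Output path.
#' @export
write_gene_network <- function(net, path) {
  el <- igraph::as_edgelist(net)
  p <- if ("p_value" %in% igraph::edge_attr_names(net)) {
    igraph::E(net)$p_value
  } else {
    rep(0, nrow(el))
  }
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                   p_value = formatC(p, format = "e", digits = 10),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read drug records from target and ATC tables
#'
#' Builds one record per drug appearing in either file. Targets and ATC codes
#' are deduplicated sets; a drug present in only one file gets an empty set
#' for the other field (such drugs are removed later by
#' [filter_combinations()] if a combination relies on them).
#'
#' @param targets_path TSV with header `drug_id`, `gene_id`.
#' @param atc_path TSV with header `drug_id`, `atc_code`.
#' @return A named list of drug records (class `drug_set`); each record is a
#'   list with `drug_id`, `targets` and `atc_codes` character vectors.
#' @export
read_drugs <- function(targets_path, atc_path) {
  tg <- read_tsv_strict(targets_path, 2, c("drug_id", "gene_id"))
  at <- read_tsv_strict(atc_path, 2, c("drug_id", "atc_code"))
  ids <- sort(unique(c(tg$drug_id, at$drug_id)))
  tg_split <- split(tg$gene_id, factor(tg$drug_id, levels = ids))
  at_split <- split(at$atc_code, factor(at$drug_id, levels = ids))
  drugs <- lapply(ids, function(id) {
    structure(list(drug_id = id,
                   targets = sort(unique(tg_split[[id]])),
                   atc_codes = sort(unique(at_split[[id]]))),
              class = "drug_record")
  })
  structure(setNames(drugs, ids), class = "drug_set")
}

#' Read a drug combination table
#'
#' @param path TSV with header `combo_id`, `drug_ids` (semicolon-separated
#'   member drugs), `combo_type`, `status`. Types and statuses must come from
#'   the closed vocabularies (synergistic/additive/antagonistic/potentiative/
#'   unknown; approved/clinical/preclinical/unknown).
#' @return A data frame (class `combo_set`) with columns `combo_id`,
#'   `members` (list of character vectors), `combo_type`, `status`.
#' @export
read_combinations <- function(path) {
  df <- read_tsv_strict(path, 4, c("combo_id", "drug_ids", "combo_type", "status"))
  members <- lapply(strsplit(df$drug_ids, ";", fixed = TRUE),
                    function(m) sort(unique(m)))
  n_mem <- lengths(members)
  if (any(n_mem < 2)) {
    stop(sprintf("combination '%s' has fewer than 2 distinct members",
                 df$combo_id[which(n_mem < 2)[1]]), call. = FALSE)
  }
  if (anyDuplicated(df$combo_id)) {
    stop("duplicate combo_id in combination table", call. = FALSE)
  }
  bad_t <- !df$combo_type %in% COMBO_TYPES
  if (any(bad_t)) {
    stop(sprintf("unknown combo_type '%s'", df$combo_type[which(bad_t)[1]]),
         call. = FALSE)
  }
  bad_s <- !df$status %in% COMBO_STATUS
  if (any(bad_s)) {
    stop(sprintf("unknown status '%s'", df$status[which(bad_s)[1]]),
         call. = FALSE)
  }
  out <- data.frame(combo_id = df$combo_id, combo_type = df$combo_type,
                    status = df$status, stringsAsFactors = FALSE)
  out$members <- members
  class(out) <- c("combo_set", "data.frame")
  out
}

#' Discard combinations with unannotated member drugs
#'
#' Keeps exactly the combinations all of whose member drugs have a non-empty
#' target set and at least one ATC code. Members absent from the drug table
#' count as unannotated; the combination is discarded with a warning rather
#' than raising an error. Idempotent.
#'
#' @param combos A `combo_set` from [read_combinations()].
#' @param drugs A `drug_set` from [read_drugs()].
#' @return The filtered `combo_set`. Retained/discarded counts are reported
#'   via [message()].
#' @export
filter_combinations <- function(combos, drugs) {
  unknown_hit <- FALSE
  ok <- vapply(combos$members, function(m) {
    known <- m %in% names(drugs)
    if (!all(known)) {
      unknown_hit <<- TRUE
      return(FALSE)
    }
    all(vapply(drugs[m], function(d) {
      length(d$targets) > 0 && length(d$atc_codes) > 0
    }, logical(1)))
  }, logical(1))
  if (unknown_hit) {
    warning("one or more combinations reference drugs absent from the drug table; discarded",
            call. = FALSE)
  }
  message(sprintf("filter_combinations: retained %d, discarded %d",
                  sum(ok), sum(!ok)))
  out <- combos[ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("combo_set", "data.frame")
  out
}

#' Read pathway gene sets from a GMT file
#'
#' Standard GMT: tab-separated, field 1 the set name, field 2 a description
#' (ignored), fields 3+ gene identifiers. Duplicate set names and lines with
#' fewer than three fields are errors.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (class `pathway_set`).
#' @export
read_pathways <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", which(nf < 3)[1]),
         call. = FALSE)
  }
  ids <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate pathway_id '%s' in GMT", ids[duplicated(ids)][1]),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) sort(unique(f[-(1:2)])))
  if (any(lengths(sets) == 0)) {
    stop("GMT line with empty gene list", call. = FALSE)
  }
  structure(setNames(sets, ids), class = "pathway_set")
}

#' Write pathway gene sets to GMT
#'
#' @param pathways A `pathway_set`.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions (recycled).
#' @export
write_pathways <- function(pathways, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(pathways))
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
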