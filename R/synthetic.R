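ATC_LEVEL1 <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R",
                "S", "V")

#' Configuration for the synthetic input generator
#'
#' Describes a complete synthetic study: a sparse gene-gene interaction
#' graph, pathway gene sets with tunable overlap, drugs with small target
#' sets, and a list of "true" combinations into which signal can be planted.
#' A planted combination receives (with probability `planted_radius_bias`)
#' targets within `d_plant` hops of each other, and (with probability
#' `planted_crosstalk_bias`) targets placed in two disjoint pathways bridged
#' by an interaction edge, so true combinations have shorter effect radii and
#' higher interacting-pathway proportions than degree-matched random pairs.
#'
#' @param n_genes Number of genes (default 300).
#' @param interaction_density Expected interaction edges per gene; total
#'   edges = `round(n_genes * interaction_density)` (default 2).
#' @param n_pathways Number of pathway gene sets (default 30).
#' @param pathway_size_range Min/max pathway size (default c(6, 12)); sized
#'   so that random pathway pairs are mostly parallel, leaving headroom for
#'   the planted relations.
#' @param pathway_overlap_prob Probability a pathway gene is recruited from a
#'   previously built pathway, creating overlap (default 0.1).
#' @param n_drugs Number of drugs (default 250).
#' @param targets_per_drug_range Min/max targets per drug (default c(1, 4)).
#' @param n_true_combos Number of true pairwise combinations (default 100).
#' @param planted_radius_bias Probability a true combination gets targets
#'   within `d_plant` hops (default 0.8).
#' @param d_plant Hop radius of the planted proximity (default 1).
#' @param planted_crosstalk_bias Probability a true combination gets targets
#'   in edge-bridged disjoint pathways (default 0.8).
#' @param decoy_fraction Fraction (of the kept edge count) of extra
#'   interaction rows with p-values above the retention threshold, written to
#'   exercise the strict filter (default 0.2).
#' @param unannotated_fraction Fraction of drugs deliberately lacking ATC
#'   codes or targets (default 0.05).
#' @param n_decoy_combos Combinations touching an unannotated drug, to
#'   exercise [filter_combinations()] (default 5).
#' @param p_threshold Retention threshold the bundle is calibrated to
#'   (default 1e-7): kept edges get p-values below it, decoys above.
#' @param graph_model `"erdos_renyi"` (default) or
#'   `"preferential_attachment"` for a heavy-tailed degree distribution.
#' @param seed Master seed; generation is deterministic given the config.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_genes = 300, interaction_density = 2,
                             n_pathways = 30, pathway_size_range = c(6, 12),
                             pathway_overlap_prob = 0.1, n_drugs = 250,
                             targets_per_drug_range = c(1, 4),
                             n_true_combos = 100, planted_radius_bias = 0.8,
                             d_plant = 1, planted_crosstalk_bias = 0.8,
                             decoy_fraction = 0.2, unannotated_fraction = 0.05,
                             n_decoy_combos = 5, p_threshold = 1e-7,
                             graph_model = c("erdos_renyi", "preferential_attachment"),
                             seed = 1) {
  graph_model <- match.arg(graph_model)
  cfg <- list(n_genes = n_genes, interaction_density = interaction_density,
              n_pathways = n_pathways, pathway_size_range = pathway_size_range,
              pathway_overlap_prob = pathway_overlap_prob, n_drugs = n_drugs,
              targets_per_drug_range = targets_per_drug_range,
              n_true_combos = n_true_combos,
              planted_radius_bias = planted_radius_bias, d_plant = d_plant,
              planted_crosstalk_bias = planted_crosstalk_bias,
              decoy_fraction = decoy_fraction,
              unannotated_fraction = unannotated_fraction,
              n_decoy_combos = n_decoy_combos, p_threshold = p_threshold,
              graph_model = graph_model, seed = seed)
  counts <- c(n_genes, n_pathways, n_drugs, n_true_combos)
  if (any(counts < 1)) stop("all counts must be positive", call. = FALSE)
  probs <- c(pathway_overlap_prob, planted_radius_bias,
             planted_crosstalk_bias, decoy_fraction, unannotated_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (rng in list(pathway_size_range, targets_per_drug_range)) {
    if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 1) {
      stop("ranges must be (min, max) with 1 <= min <= max", call. = FALSE)
    }
  }
  if (pathway_size_range[2] > n_genes) {
    stop("pathway sizes exceed n_genes", call. = FALSE)
  }
  if (targets_per_drug_range[2] > n_genes) {
    stop("targets per drug exceed n_genes", call. = FALSE)
  }
  if (d_plant < 0) stop("d_plant must be >= 0", call. = FALSE)
  structure(cfg, class = "generator_config")
}

fmt_p <- function(p) formatC(p, format = "e", digits = 10)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Generate a complete synthetic input bundle on disk
#'
#' Writes `interactions.tsv`, `targets.tsv`, `atc.tsv`, `combinations.tsv`,
#' `pathways.gmt` and a `manifest.json` (config echo) in the package's input
#' formats. Deterministic given the config seed: the same config writes
#' byte-identical files. See [generator_config()] for the planted structure.
#'
#' @param cfg A `generator_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the written file paths plus the in-memory
#'   bundle (`$bundle`, as returned by [read_bundle()]).
#' @export
generate_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "generator_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(as.integer(cfg$seed), {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    n_edges <- round(cfg$n_genes * cfg$interaction_density)
    g <- switch(cfg$graph_model,
      erdos_renyi = igraph::sample_gnm(cfg$n_genes, n_edges),
      preferential_attachment = igraph::sample_pa(
        cfg$n_genes, m = max(1, round(cfg$interaction_density)),
        directed = FALSE))
    g <- igraph::simplify(g)
    igraph::V(g)$name <- genes

    el <- igraph::as_edgelist(g)
    kept_p <- 10^stats::runif(nrow(el), -12, log10(cfg$p_threshold) - 0.05)
    inter <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                        p_value = fmt_p(kept_p), stringsAsFactors = FALSE)
    n_decoy <- round(cfg$decoy_fraction * nrow(el))
    if (n_decoy > 0) {
      da <- sample(genes, n_decoy, replace = TRUE)
      db <- sample(genes, n_decoy, replace = TRUE)
      ok <- da != db
      decoy_p <- 10^stats::runif(n_decoy, log10(cfg$p_threshold) + 0.05, -2)
      inter <- rbind(inter, data.frame(gene_a = da[ok], gene_b = db[ok],
                                       p_value = fmt_p(decoy_p[ok]),
                                       stringsAsFactors = FALSE))
    }

    # pathways: recruit from already-used genes with the overlap probability
    used <- character(0)
    pathways <- list()
    for (i in seq_len(cfg$n_pathways)) {
      size <- sample(cfg$pathway_size_range[1]:cfg$pathway_size_range[2], 1)
      pick <- character(0)
      while (length(pick) < size) {
        from_used <- length(used) > 0 &&
          stats::runif(1) < cfg$pathway_overlap_prob
        cand <- if (from_used) sample(used, 1) else sample(genes, 1)
        pick <- union(pick, cand)
      }
      pathways[[sprintf("P%03d", i)]] <- pick
      used <- union(used, pick)
    }

    # drugs: a leading block is left unannotated to exercise the filters
    drug_ids <- sprintf("d%04d", seq_len(cfg$n_drugs))
    n_unann <- round(cfg$unannotated_fraction * cfg$n_drugs)
    unann <- drug_ids[seq_len(n_unann)]
    annotated <- setdiff(drug_ids, unann)
    targets <- lapply(drug_ids, function(d) {
      k <- sample(cfg$targets_per_drug_range[1]:cfg$targets_per_drug_range[2], 1)
      sample(genes, k)
    })
    names(targets) <- drug_ids
    atc <- vapply(drug_ids, function(d) {
      paste0(sample(ATC_LEVEL1, 1), sprintf("%02d", sample(0:99, 1)),
             paste(sample(LETTERS, 2, replace = TRUE), collapse = ""),
             sprintf("%02d", sample(0:99, 1)))
    }, "")
    # half the unannotated drugs lose their ATC codes, half their targets
    if (n_unann > 0) {
      drop_atc <- unann[seq_len(ceiling(n_unann / 2))]
      drop_tgt <- setdiff(unann, drop_atc)
      atc <- atc[!names(atc) %in% drop_atc]
      targets[drop_tgt] <- list(character(0))
    }

    # candidate (edge, pathway, pathway) triples for crosstalk planting:
    # disjoint pathway pairs bridged by an interaction edge
    pw_of <- function(gene) {
      names(pathways)[vapply(pathways, function(s) gene %in% s, logical(1))]
    }
    plant_crosstalk <- function(a, b) {
      for (try in seq_len(50)) {
        e <- el[sample(nrow(el), 1), ]
        pa <- pw_of(e[1])
        pb <- pw_of(e[2])
        for (p1 in pa) {
          for (p2 in pb) {
            if (p1 != p2 &&
                length(intersect(pathways[[p1]], pathways[[p2]])) == 0) {
              # concentrate the partners on the bridged pathway pair: every
              # resulting pathway pair is bridged by this edge, so the
              # combination's interacting proportion is pushed up
              targets[[a]] <<- e[1]
              targets[[b]] <<- e[2]
              return(TRUE)
            }
          }
        }
      }
      FALSE
    }

    # true combinations: disjoint drug pairs when the pool allows it
    if (2 * cfg$n_true_combos <= length(annotated)) {
      pool <- sample(annotated, 2 * cfg$n_true_combos)
      pairs <- matrix(pool, ncol = 2)
    } else {
      pairs <- t(replicate(cfg$n_true_combos, sample(annotated, 2)))
    }
    crosstalk_failures <- 0
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]
      b <- pairs[i, 2]
      # crosstalk planting replaces the targets, so apply it first; radius
      # planting then adds a close target pair on top
      if (stats::runif(1) < cfg$planted_crosstalk_bias) {
        if (!plant_crosstalk(a, b)) crosstalk_failures <- crosstalk_failures + 1
      }
      if (stats::runif(1) < cfg$planted_radius_bias) {
        t1 <- sample(genes, 1)
        near <- names(igraph::ego(g, order = cfg$d_plant, nodes = t1)[[1]])
        targets[[a]] <- union(targets[[a]], t1)
        targets[[b]] <- union(targets[[b]], sample(near, 1))
      }
    }
    if (crosstalk_failures > 0) {
      warning(sprintf("crosstalk planting failed for %d combination(s)",
                      crosstalk_failures), call. = FALSE)
    }
    combos <- data.frame(
      combo_id = sprintf("C%04d", seq_len(nrow(pairs))),
      drug_ids = paste(pairs[, 1], pairs[, 2], sep = ";"),
      combo_type = sample(c("synergistic", "additive", "antagonistic",
                            "potentiative"), nrow(pairs), replace = TRUE,
                          prob = c(0.5, 0.25, 0.1, 0.15)),
      status = sample(c("approved", "clinical", "preclinical"), nrow(pairs),
                      replace = TRUE),
      stringsAsFactors = FALSE)
    if (cfg$n_decoy_combos > 0 && n_unann > 0) {
      decoys <- data.frame(
        combo_id = sprintf("X%04d", seq_len(cfg$n_decoy_combos)),
        drug_ids = paste(sample(unann, cfg$n_decoy_combos, replace = TRUE),
                         sample(annotated, cfg$n_decoy_combos),
                         sep = ";"),
        combo_type = rep("unknown", cfg$n_decoy_combos),
        status = rep("unknown", cfg$n_decoy_combos),
        stringsAsFactors = FALSE)
      combos <- rbind(combos, decoys)
    }

    tg_rows <- data.frame(
      drug_id = rep(names(targets), lengths(targets)),
      gene_id = unlist(targets, use.names = FALSE),
      stringsAsFactors = FALSE)
    atc_rows <- data.frame(drug_id = names(atc), atc_code = unname(atc),
                           stringsAsFactors = FALSE)

    paths <- list(interactions = file.path(dir, "interactions.tsv"),
                  targets = file.path(dir, "targets.tsv"),
                  atc = file.path(dir, "atc.tsv"),
                  combinations = file.path(dir, "combinations.tsv"),
                  pathways = file.path(dir, "pathways.gmt"),
                  manifest = file.path(dir, "manifest.json"))
    write_tsv(inter, paths$interactions)
    write_tsv(tg_rows, paths$targets)
    write_tsv(atc_rows, paths$atc)
    write_tsv(combos, paths$combinations)
    write_pathways(structure(pathways, class = "pathway_set"), paths$pathways)
    jsonlite::write_json(list(config = unclass(cfg)), paths$manifest,
                         auto_unbox = TRUE, digits = NA)
    out <- paths
    out$bundle <- read_bundle(dir, p_threshold = cfg$p_threshold)
    invisible(out)
  })
}

#' Read a bundle directory back into memory
#'
#' Convenience loader over the individual readers for a directory written by
#' [generate_bundle()] or [worked_toy_bundle()].
#'
#' @param dir Bundle directory.
#' @param p_threshold Passed to [read_genetic_interactions()].
#' @return A list with `net`, `drugs`, `combos`, `pathways`.
#' @export
read_bundle <- function(dir, p_threshold = 1e-7) {
  list(net = read_genetic_interactions(file.path(dir, "interactions.tsv"),
                                       p_threshold = p_threshold),
       drugs = read_drugs(file.path(dir, "targets.tsv"),
                          file.path(dir, "atc.tsv")),
       combos = read_combinations(file.path(dir, "combinations.tsv")),
       pathways = read_pathways(file.path(dir, "pathways.gmt")))
}

#' A hand-computed worked toy bundle
#'
#' Writes a small fixture bundle (12 genes, 4 pathways, 9 drugs, 8
#' combinations) whose every downstream value — radii, pathway-pair labels,
#' profile proportions, stratum assignments and tallies — was computed by
#' hand and recorded in the returned manifest (also written as
#' `manifest.json`). The fixture deliberately contains the boundary cases:
#' a combination filtered for a missing ATC code, an undefined radius
#' (isolated target gene), a radius of exactly 3 (inside the `<= 3` stratum)
#' and an interacting proportion of exactly 0.4 (excluded by the strict
#' `> 0.4` selection), plus a decoy interaction row above the p threshold.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list: the file `paths` and the `expected` manifest of
#'   hand-computed values.
#' @export
worked_toy_bundle <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inter <- data.frame(
    gene_a = c("g1", "g2", "g3", "g4", "g6", "g10", "g8"),
    gene_b = c("g2", "g3", "g4", "g5", "g7", "g11", "g9"),
    p_value = c(rep("1.0e-09", 6), "1.0e-06"),  # g8-g9 fails p < 1e-7
    stringsAsFactors = FALSE)
  targets <- data.frame(
    drug_id = c("d1", "d2", "d2", "d3", "d4", "d5", "d6", "d7", "d7", "d8"),
    gene_id = c("g1", "g1", "g4", "g3", "g10", "g6", "g12", "g5", "g6", "g2"),
    stringsAsFactors = FALSE)
  atc <- data.frame(
    drug_id = c("d1", "d2", "d3", "d4", "d6", "d7", "d8"),  # d5 lacks ATC
    atc_code = c("C01AA05", "C03BA08", "N05AH02", "L01XX05", "N02BA01",
                 "A01AB03", "C07AB02"),
    stringsAsFactors = FALSE)
  combos <- data.frame(
    combo_id = paste0("C", 1:8),
    drug_ids = c("d1;d2", "d1;d3", "d2;d5", "d4;d6", "d2;d3", "d1;d7",
                 "d7;d8", "d1;d3;d7"),
    combo_type = c("synergistic", "additive", "potentiative", "synergistic",
                   "synergistic", "synergistic", "additive", "synergistic"),
    status = c("approved", "clinical", "preclinical", "approved", "approved",
               "clinical", "approved", "preclinical"),
    stringsAsFactors = FALSE)
  pathways <- structure(list(P1 = c("g1", "g2", "g7"),
                             P2 = c("g2", "g5", "g6"),
                             P3 = c("g3", "g6"),
                             P4 = c("g10", "g12")),
                        class = "pathway_set")

  expected <- list(
    filtered_out = "C3",  # d5 has targets but no ATC code
    radii = list(C1 = 0, C2 = 2, C4 = NA_real_, C5 = 1, C6 = 4, C7 = 3,
                 C8 = 8 / 3),
    n_pairs_used = list(C1 = 1, C2 = 1, C4 = 0, C5 = 1, C6 = 1, C7 = 1,
                        C8 = 3),
    n_pairs_unreachable = list(C1 = 0, C2 = 0, C4 = 1, C5 = 0, C6 = 0,
                               C7 = 0, C8 = 0),
    pair_classes = list(`P1|P2` = "CROSS_TALKING", `P1|P3` = "INTERACTING",
                        `P1|P4` = "PARALLEL", `P2|P3` = "CROSS_TALKING",
                        `P2|P4` = "PARALLEL", `P3|P4` = "PARALLEL"),
    profiles = list(
      C1 = list(IDENTICAL = 1, CROSS_TALKING = 0, INTERACTING = 0, PARALLEL = 0),
      C2 = list(IDENTICAL = 0, CROSS_TALKING = 0, INTERACTING = 1, PARALLEL = 0),
      C4 = list(IDENTICAL = 1, CROSS_TALKING = 0, INTERACTING = 0, PARALLEL = 0),
      C5 = list(IDENTICAL = 0, CROSS_TALKING = 0, INTERACTING = 1, PARALLEL = 0),
      C6 = list(IDENTICAL = 0, CROSS_TALKING = 0.5, INTERACTING = 0.5, PARALLEL = 0),
      C7 = list(IDENTICAL = 0.25, CROSS_TALKING = 0.5, INTERACTING = 0.25, PARALLEL = 0),
      C8 = list(IDENTICAL = 0.2, CROSS_TALKING = 0.4, INTERACTING = 0.4, PARALLEL = 0)),
    strata = list(low = c("C1", "C2", "C5", "C7", "C8"), high = "C6"),
    selected_interacting = c("C2", "C5", "C6"),
    annotation = c(g1 = "GPCR", g3 = "kinase"),
    tallies = list(
      atc_low_stratum = c(A = 2, C = 6, N = 3),
      combo_type_selected = c(additive = 1, synergistic = 2),
      target_function_selected = c(GPCR = 3, kinase = 2, unclassified = 3)),
    gene_distances = list(`g1|g3` = 2, `g1|g5` = 4, `g2|g5` = 3,
                          `g1|g6` = "unreachable", `g10|g12` = "unreachable"))

  paths <- list(interactions = file.path(dir, "interactions.tsv"),
                targets = file.path(dir, "targets.tsv"),
                atc = file.path(dir, "atc.tsv"),
                combinations = file.path(dir, "combinations.tsv"),
                pathways = file.path(dir, "pathways.gmt"),
                manifest = file.path(dir, "manifest.json"))
  write_tsv(inter, paths$interactions)
  write_tsv(targets, paths$targets)
  write_tsv(atc, paths$atc)
  write_tsv(combos, paths$combinations)
  write_pathways(pathways, paths$pathways)
  jsonlite::write_json(expected, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(paths = paths, expected = expected))
}
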