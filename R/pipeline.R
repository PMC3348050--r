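#' Pipeline run configuration
#'
#' Bundles the input paths and analysis parameters of a full run. Defaults
#' mirror the reference analysis: interactions kept at p < 1e-7, 1,000
#' degree-preserving null replicates, the radius strata split at 3
#' (inclusive below) and the interacting-pathway selection at a strict 0.4.
#'
#' @param interactions,targets,atc,combinations,pathways Input file paths
#'   (see the `read_*` readers for formats).
#' @param outdir Output directory.
#' @param p_threshold Strict retention threshold for interaction p-values.
#' @param n_null_replicates Size of the degree-preserving null ensemble.
#' @param seed Master seed for all randomness in the run.
#' @param radius_stratum_threshold Radius strata boundary (default 3).
#' @param interacting_proportion_threshold Strict selection threshold on the
#'   INTERACTING proportion (default 0.4).
#' @param alternative Sidedness for the rank-sum tests (default
#'   `"two_sided"`).
#' @param pooling Null pooling mode, `"pooled"` or `"replicate_mean"`.
#' @param n_swaps_per_edge Swap budget per edge in each shuffle.
#' @return A validated `run_config` list.
#' @export
run_config <- function(interactions, targets, atc, combinations, pathways,
                       outdir, p_threshold = 1e-7, n_null_replicates = 1000,
                       seed = 1, radius_stratum_threshold = 3,
                       interacting_proportion_threshold = 0.4,
                       alternative = c("two_sided", "real_less", "real_greater"),
                       pooling = c("pooled", "replicate_mean"),
                       n_swaps_per_edge = 10) {
  alternative <- match.arg(alternative)
  pooling <- match.arg(pooling)
  if (!is.numeric(n_null_replicates) || n_null_replicates < 1) {
    stop("config error: n_null_replicates must be >= 1", call. = FALSE)
  }
  if (p_threshold <= 0 || p_threshold > 1) {
    stop("config error: p_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (interacting_proportion_threshold < 0 ||
      interacting_proportion_threshold > 1) {
    stop("config error: interacting_proportion_threshold must lie in [0, 1]",
         call. = FALSE)
  }
  structure(list(interactions = interactions, targets = targets, atc = atc,
                 combinations = combinations, pathways = pathways,
                 outdir = outdir, p_threshold = p_threshold,
                 n_null_replicates = as.integer(n_null_replicates),
                 seed = as.integer(seed),
                 radius_stratum_threshold = radius_stratum_threshold,
                 interacting_proportion_threshold = interacting_proportion_threshold,
                 alternative = alternative, pooling = pooling,
                 n_swaps_per_edge = n_swaps_per_edge),
            class = "run_config")
}

#' Run the full combination-analysis pipeline
#'
#' Ingest -> filter -> cocktail network -> degree-preserving null ensemble ->
#' effect radii and pathway profiles for real and null combinations ->
#' rank-sum comparisons, strata and tallies -> TSV/JSON outputs plus a
#' plain-text summary. Fully deterministic given the config seed.
#'
#' Outputs written under `cfg$outdir`: `radii.tsv`, `profiles.tsv`,
#' `comparisons.json`, `tally_atc_low.tsv`, `tally_atc_high.tsv`,
#' `tally_combo_type_selected.tsv`, `summary.txt`.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with every intermediate and final result
#'   (`drugs`, `combos`, `net`, `cocktail`, `ensemble`, `radii`,
#'   `null_radii`, `profiles`, `null_profiles`, `comparisons`, `strata`,
#'   `selected`, `tallies`, `counts`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  net <- stage("ingest", read_genetic_interactions(cfg$interactions,
                                                   cfg$p_threshold))
  drugs <- stage("ingest", read_drugs(cfg$targets, cfg$atc))
  combos_raw <- stage("ingest", read_combinations(cfg$combinations))
  pathways <- stage("ingest", read_pathways(cfg$pathways))
  combos <- stage("filter", filter_combinations(combos_raw, drugs))
  if (nrow(combos) == 0) stop("[filter] no combinations retained", call. = FALSE)

  cocktail <- stage("cocktail", build_cocktail_network(combos))
  ens <- stage("null", generate_null_ensemble(
    cocktail, n_replicates = cfg$n_null_replicates, seed = cfg$seed,
    n_swaps_per_edge = cfg$n_swaps_per_edge))
  null_combos <- null_edges_as_combinations(ens)

  index <- distance_index(net)
  radii <- stage("radius", effect_radii(index, combos, drugs))
  null_radii <- stage("radius", lapply(null_combos, function(cs) {
    effect_radii(index, cs, drugs)
  }))
  profiles <- stage("pathways",
                    suppressMessages(combination_profiles(combos, drugs,
                                                          pathways, net)))
  cls <- pathway_pair_classifier(pathways, net)
  null_profiles <- stage("pathways", lapply(null_combos, function(cs) {
    suppressMessages(combination_profiles(cs, drugs, pathways, net,
                                          classifier = cls))
  }))

  comparisons <- stage("compare", list(
    radius = compare_radius(radii, null_radii, alternative = cfg$alternative,
                            pooling = cfg$pooling),
    cross_talking = compare_pathway_proportion(
      profiles, null_profiles, "CROSS_TALKING",
      alternative = cfg$alternative, pooling = cfg$pooling),
    interacting = compare_pathway_proportion(
      profiles, null_profiles, "INTERACTING",
      alternative = cfg$alternative, pooling = cfg$pooling)))

  strata <- stratify_by_radius(radii, cfg$radius_stratum_threshold)
  selected <- select_interacting_targeters(
    profiles, cfg$interacting_proportion_threshold)
  tallies <- list(
    atc_low = tally_categories(strata$low, drugs, combos, "atc_level1"),
    atc_high = tally_categories(strata$high, drugs, combos, "atc_level1"),
    combo_type_selected = tally_categories(selected, drugs, combos,
                                           "combo_type"))
  counts <- list(combos_read = nrow(combos_raw),
                 combos_retained = nrow(combos),
                 combos_discarded = nrow(combos_raw) - nrow(combos),
                 radii_undefined = sum(is.na(radii$radius)),
                 pairs_unreachable = sum(radii$n_pairs_unreachable),
                 n_selected_interacting = length(selected),
                 n_low_stratum = length(strata$low),
                 n_high_stratum = length(strata$high))

  write_radius_results(radii, file.path(cfg$outdir, "radii.tsv"))
  write_profiles(profiles, file.path(cfg$outdir, "profiles.tsv"))
  jsonlite::write_json(lapply(comparisons, unclass),
                       file.path(cfg$outdir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA)
  write_tally <- function(t, path) {
    write_tsv(data.frame(label = names(t$counts), count = unname(t$counts),
                         proportion = unname(t$proportions)), path)
  }
  write_tally(tallies$atc_low, file.path(cfg$outdir, "tally_atc_low.tsv"))
  write_tally(tallies$atc_high, file.path(cfg$outdir, "tally_atc_high.tsv"))
  write_tally(tallies$combo_type_selected,
              file.path(cfg$outdir, "tally_combo_type_selected.tsv"))

  summary_lines <- c(
    "Drug combination network analysis - run summary",
    sprintf("combinations read: %d, retained: %d, discarded: %d",
            counts$combos_read, counts$combos_retained,
            counts$combos_discarded),
    sprintf("null ensemble: %d degree-preserving replicates (seed %d)",
            cfg$n_null_replicates, cfg$seed),
    sprintf("radii undefined: %d; unreachable drug pairs: %d",
            counts$radii_undefined, counts$pairs_unreachable),
    sprintf("radius strata at %.3g: %d at or below, %d above",
            cfg$radius_stratum_threshold, counts$n_low_stratum,
            counts$n_high_stratum),
    sprintf("effect radius vs null: p = %.4g (%s, %s pooling)",
            comparisons$radius$p_value, cfg$alternative, cfg$pooling),
    sprintf("cross-talking proportion vs null: p = %.4g",
            comparisons$cross_talking$p_value),
    sprintf("interacting proportion vs null: p = %.4g",
            comparisons$interacting$p_value),
    sprintf("combinations with interacting proportion > %.3g: %d",
            cfg$interacting_proportion_threshold,
            counts$n_selected_interacting))
  writeLines(summary_lines, file.path(cfg$outdir, "summary.txt"))

  invisible(list(drugs = drugs, combos = combos, net = net,
                 cocktail = cocktail, ensemble = ens, radii = radii,
                 null_radii = null_radii, profiles = profiles,
                 null_profiles = null_profiles, comparisons = comparisons,
                 strata = strata, selected = selected, tallies = tallies,
                 counts = counts))
}
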