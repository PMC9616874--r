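# End-to-end orchestration: one config object, fixed seeds, every stage
# checkpointed to the output directory when one is given.

#' Pipeline configuration
#'
#' Collects every simulator parameter and analysis threshold of the
#' pipeline in one serializable object. Defaults are the demo-scale study
#' conditions: one sample type, both media, three dilution levels around
#' the informative middle of the series, triplicate plates, 40 taxa and 3
#' planted positive pairs.
#'
#' @param seed Master seed; every stage derives its seed from it.
#' @param n_species,lognormal_sigma,cells_per_ul Source community
#'   parameters (see [simulate_source()]).
#' @param sample_types,media,dilution_levels,replicates,n_wells Design grid.
#' @param read_depth Reads per occupied well.
#' @param n_planted_pairs,planted_effect,planted_sign Planted ground-truth
#'   interactions per sample type.
#' @param co_colonization,co_seed_sd Correlated-seeding (co-colonization)
#'   mode of [simulate_plate()]: the default study condition plants
#'   positive pairs as co-colonizers (shared per-well seeding factor,
#'   log-sd `co_seed_sd`) on top of the growth coupling, which is what
#'   brings the within-plate co-occurrence correlation of planted pairs to
#'   about 0.8 at the informative dilutions.
#' @param occupancy_band Expected per-well occupancy interval (at the
#'   median dilution level) from which planted taxa are drawn; interactions
#'   are planted between taxa of intermediate occupancy, where a
#'   co-occurrence signal is identifiable.
#' @param min_reads,min_grow_frac Growth scoring and effective-plate cutoff.
#' @param prevalence_min_frac Zotu prevalence cutoff within a plate.
#' @param rho_min,q_max Edge thresholds.
#' @param max_degree Degree-centrality cutoff for the sub-network.
#' @param fo_min Robust-pair FO cutoff.
#' @param k_top Pairs per group in the report.
#' @param n_isolates_per_zotu Synthetic isolates generated per reported
#'   Zotu for the matching stage.
#' @param identity_threshold,distance_cap Matching parameters
#'   (see [match_isolates()]).
#' @param epsilon Interaction-call threshold (log10-units/h).
#' @param assay_windows Windows for interaction calls (`NULL` = full range).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       n_species = 40, lognormal_sigma = 0.6,
                       cells_per_ul = 1e6,
                       sample_types = "roots", media = c("R2A", "TSB"),
                       dilution_levels = 3:5,
                       replicates = c("A", "B", "C"), n_wells = 96,
                       read_depth = 5000,
                       n_planted_pairs = 3, planted_effect = 1,
                       planted_sign = 1,
                       co_colonization = TRUE, co_seed_sd = 1.0,
                       occupancy_band = c(0.80, 0.95),
                       min_reads = 100, min_grow_frac = 0.30,
                       prevalence_min_frac = 0.30,
                       rho_min = 0.6, q_max = 0.01,
                       max_degree = 5, fo_min = 0.30, k_top = 3,
                       n_isolates_per_zotu = 2,
                       identity_threshold = 1.0, distance_cap = 0.03,
                       epsilon = 0.2, assay_windows = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$min_grow_frac >= 0, cfg$min_grow_frac <= 1,
            cfg$prevalence_min_frac >= 0, cfg$prevalence_min_frac <= 1,
            cfg$rho_min >= 0, cfg$rho_min <= 1,
            cfg$q_max > 0, cfg$max_degree >= 1, cfg$k_top >= 1)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Plant ground-truth pairs among intermediate-occupancy taxa
#'
#' Selects `n_pairs` disjoint taxon pairs whose expected per-well occupancy
#' `1 - exp(-lambda)` at the given dilution level falls inside
#' `occupancy_band`, and assigns them the configured sign and effect size.
#'
#' @param source A [simulate_source()] community.
#' @param dilution_level Focal dilution level of the band.
#' @param n_pairs Number of pairs to plant.
#' @param effect_size,sign Interaction parameters.
#' @param occupancy_band Occupancy interval for eligible taxa.
#' @param seed Integer seed.
#' @return An [interaction_truth()].
#' @export
plant_pairs <- function(source, dilution_level, n_pairs = 3,
                        effect_size = 3, sign = 1,
                        occupancy_band = c(0.80, 0.95), seed = 1) {
  des <- plate_design("roots", "R2A", dilution_level = dilution_level)
  lam <- expected_seeding(source, des)$expected_cells
  occ <- 1 - exp(-lam)
  eligible <- source$species_id[occ >= occupancy_band[1] &
                                  occ <= occupancy_band[2]]
  if (length(eligible) < 2 * n_pairs) {
    abort(sprintf(
      "only %d taxa fall in the occupancy band [%.2f, %.2f]; need %d.",
      length(eligible), occupancy_band[1], occupancy_band[2], 2 * n_pairs
    ))
  }
  chosen <- with_seed(seed, sample(eligible, 2 * n_pairs))
  interaction_truth(tibble(
    species_a = chosen[seq_len(n_pairs) * 2 - 1],
    species_b = chosen[seq_len(n_pairs) * 2],
    sign = sign, effect_size = effect_size
  ))
}

#' Run the full pipeline
#'
#' Simulates the plate array from the config's ground truth, scores growth,
#' keeps effective plates, infers one degree-filtered co-occurrence network
#' per plate, aggregates pair prevalence, retains robust pairs and the
#' top-k report, compares networks by Jaccard similarity, matches synthetic
#' isolates to the Zotus of the reported pairs, enumerates co-culture
#' combinations, and classifies simulated mono-/co-culture growth curves
#' for each combination. Fully deterministic given `config$seed`; every
#' intermediate is written to `out_dir` when one is given.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory for checkpoints.
#' @return A list of class `wellnets_run`: `config`, `truth`, `growth`
#'   (per-plate growth summary), `networks`, `network_summaries`,
#'   `prevalence`, `robust_pairs`, `top_pairs`, `jaccard`,
#'   `unique_pairs`, `matches`, `combinations`, `interaction_calls`, and
#'   `recovery` (planted-pair recall against ground truth).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  ckpt <- function(f, name) if (!is.null(out_dir)) f(file.path(out_dir, name))

  # --- simulate -------------------------------------------------------------
  mid_dil <- as.integer(round(median(config$dilution_levels)))
  sources <- list(); truths <- list(); plates <- list()
  for (si in seq_along(config$sample_types)) {
    st <- config$sample_types[si]
    src <- simulate_source(config$n_species,
                           lognormal_sigma = config$lognormal_sigma,
                           cells_per_ul = config$cells_per_ul,
                           seed = config$seed + 1000 * si)
    tr <- plant_pairs(src, mid_dil, n_pairs = config$n_planted_pairs,
                      effect_size = config$planted_effect,
                      sign = config$planted_sign,
                      occupancy_band = config$occupancy_band,
                      seed = config$seed + 1000 * si + 1)
    designs <- full_design(sample_types = st, media = config$media,
                           dilution_levels = config$dilution_levels,
                           replicates = config$replicates,
                           n_wells = config$n_wells)
    pl <- simulate_plate_array(src, designs, truth = tr,
                               read_depth = config$read_depth,
                               seed = config$seed + 1000 * si + 100,
                               co_colonization = config$co_colonization,
                               co_seed_sd = config$co_seed_sd)
    sources[[st]] <- src; truths[[st]] <- tr
    plates <- c(plates, pl)
  }
  truth_all <- map_dfr(names(truths), function(st) {
    truths[[st]] |> mutate(sample_type = st)
  })
  if (!is.null(out_dir)) {
    for (p in plates) {
      write_plate_table(p, file.path(out_dir, paste0(plate_id(p), ".tsv")),
                        file.path(out_dir, paste0(plate_id(p), ".json")))
    }
    readr::write_tsv(truth_all, file.path(out_dir, "truth_pairs.tsv"))
  }

  # --- filter ---------------------------------------------------------------
  growth <- growth_summary(plates, min_reads = config$min_reads)
  eff <- effective_plates(plates, min_reads = config$min_reads,
                          min_grow_frac = config$min_grow_frac)
  ckpt(function(p) readr::write_tsv(growth, p), "growth_summary.tsv")

  # --- infer ----------------------------------------------------------------
  networks <- map(eff, function(p) {
    fp <- prevalence_filter(p, min_frac = config$prevalence_min_frac,
                            min_reads = config$min_reads)
    nw <- build_network(fp, rho_min = config$rho_min, q_max = config$q_max)
    degree_filter(nw, max_degree = config$max_degree)
  })
  net_sum <- map_dfr(networks, network_summary)
  ckpt(function(p) readr::write_tsv(net_sum, p), "network_summaries.tsv")
  if (!is.null(out_dir)) {
    for (nw in networks) {
      write_edge_list(nw, file.path(out_dir, paste0(nw$plate_id, "_edges.tsv")))
    }
  }

  # --- ensemble -------------------------------------------------------------
  prevalence <- pair_prevalence(networks)
  robust <- retain_robust_pairs(prevalence, fo_min = config$fo_min)
  top <- top_pairs_report(prevalence, k = config$k_top)
  jac <- jaccard_matrix(networks)
  uniq <- unique_pair_count(networks)
  ckpt(function(p) readr::write_tsv(robust, p), "robust_pairs.tsv")
  ckpt(function(p) readr::write_tsv(top, p), "top_pairs.tsv")

  recovery <- pair_recovery(robust, top, truth_all, config)

  # --- match ----------------------------------------------------------------
  report_zotus <- unique(c(top$zotu_a, top$zotu_b))
  matches <- NULL; combos <- NULL
  if (length(report_zotus) >= 2) {
    all_species <- unique(unlist(map(sources, function(s) s$species_id)))
    zseqs <- simulate_zotu_seqs(all_species, seed = config$seed + 7)
    zseqs_rep <- zseqs |> filter(.data$id %in% report_zotus)
    isolates <- simulate_isolate_seqs(zseqs_rep,
                                      n_per_zotu = config$n_isolates_per_zotu,
                                      seed = config$seed + 8)
    matches <- match_isolates(zseqs_rep, isolates |> select("id", "sequence"),
                              identity_threshold = config$identity_threshold,
                              distance_cap = config$distance_cap)
    combos <- map_dfr(seq_len(nrow(top)), function(i) {
      tryCatch(
        enumerate_combinations(top$zotu_a[i], top$zotu_b[i], matches) |>
          mutate(sample_type = top$sample_type[i], medium = top$medium[i]),
        error = function(e) NULL
      )
    }) |> distinct()
    ckpt(function(p) write_match_table(matches, p), "isolate_matches.tsv")
    ckpt(function(p) readr::write_tsv(combos, p), "combinations.tsv")
  }

  # --- assay ----------------------------------------------------------------
  calls <- NULL
  if (!is.null(combos) && nrow(combos) > 0) {
    labels <- c("neutralism", "competition", "mutualism", "commensalism",
                "amensalism", "exploitation")
    true_labels <- with_seed(config$seed + 9,
                             sample(labels, nrow(combos), replace = TRUE))
    calls <- map_dfr(seq_len(nrow(combos)), function(i) {
      gc <- simulate_growth_curves(true_labels[i],
                                   seed = config$seed + 10 + i)
      classify_interaction(gc, windows = config$assay_windows,
                           epsilon = config$epsilon) |>
        mutate(isolate_1 = combos$isolate_1[i],
               isolate_2 = combos$isolate_2[i],
               true_label = true_labels[i])
    })
    ckpt(function(p) write_interaction_calls(calls, p), "interaction_calls.tsv")
  }

  structure(
    list(config = config, truth = truth_all, growth = growth,
         networks = networks, network_summaries = net_sum,
         prevalence = prevalence, robust_pairs = robust, top_pairs = top,
         jaccard = jac, unique_pairs = uniq, matches = matches,
         combinations = combos, interaction_calls = calls,
         recovery = recovery),
    class = "wellnets_run"
  )
}

pair_recovery <- function(robust, top, truth_all, config) {
  if (nrow(truth_all) == 0) return(NULL)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  truth_keys <- key(truth_all$species_a, truth_all$species_b)
  per_group <- robust |>
    group_by(.data$sample_type, .data$medium) |>
    summarise(
      n_robust = n(),
      n_planted_found = sum(key(.data$zotu_a, .data$zotu_b) %in% truth_keys),
      .groups = "drop"
    )
  found <- robust |>
    mutate(planted = key(.data$zotu_a, .data$zotu_b) %in% truth_keys)
  n_groups <- length(unique(paste(robust$sample_type, robust$medium)))
  n_expected <- nrow(truth_all) * length(config$media)
  recall <- sum(found$planted) / max(n_expected, 1)
  in_top <- top |>
    mutate(planted = key(.data$zotu_a, .data$zotu_b) %in% truth_keys)
  list(
    recall = recall,
    n_planted = nrow(truth_all),
    n_planted_edges_expected = n_expected,
    per_group = per_group,
    planted_in_top = sum(in_top$planted),
    median_fo_planted = median(found$fo[found$planted]),
    median_fo_unplanted = if (any(!found$planted)) {
      median(found$fo[!found$planted])
    } else NA_real_
  )
}

#' @export
print.wellnets_run <- function(x, ...) {
  cat("<wellnets_run>\n")
  cat(sprintf("  plates simulated: %d, effective networks: %d\n",
              nrow(x$growth), length(x$networks)))
  cat(sprintf("  unique pairs: %d, robust pairs: %d\n",
              x$unique_pairs, nrow(x$robust_pairs)))
  if (!is.null(x$recovery)) {
    cat(sprintf("  planted-pair recall: %.2f\n", x$recovery$recall))
  }
  invisible(x)
}

#' @importFrom utils str modifyList
NULL
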