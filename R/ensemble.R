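# Cross-network aggregation: the pair-prevalence statistic FO = Np/Ng,
# robust-pair retention, Jaccard comparison of edge sets, Table-style report.

edge_keys <- function(network) {
  if (nrow(network$edges) == 0) return(character())
  paste(network$edges$zotu_a, network$edges$zotu_b, sep = "--")
}

network_meta <- function(networks) {
  map_dfr(networks, function(nw) {
    tibble(plate_id = nw$plate_id,
           sample_type = nw$design$sample_type,
           medium = nw$design$medium)
  })
}

#' Pair prevalence across a network ensemble
#'
#' For every Zotu pair appearing as an edge in at least one network, counts
#' `Np`, the number of networks of the same (sample type, medium) group
#' containing that edge, against `Ng`, the total number of networks in the
#' group, and reports `FO = Np / Ng`. Dilution level and replicate are
#' intentionally pooled: the group key is exactly (sample type, medium).
#' `sign_consensus` is the majority edge sign across occurrences (ties
#' resolved by the sign of the mean rho) and `sign_conflict` flags pairs
#' observed with both signs.
#'
#' @param networks A non-empty list of `cooccur_network`s carrying their
#'   plate designs.
#' @return A tibble with one row per (pair, group): `sample_type`,
#'   `medium`, `zotu_a`, `zotu_b`, `np`, `ng`, `fo`, `mean_rho`,
#'   `sign_consensus`, `sign_conflict`.
#' @export
pair_prevalence <- function(networks) {
  if (length(networks) == 0) abort("empty network list.")
  meta <- network_meta(networks)
  ng <- meta |> count(.data$sample_type, .data$medium, name = "ng")
  edges_all <- map_dfr(networks, function(nw) {
    if (nrow(nw$edges) == 0) return(NULL)
    nw$edges |>
      mutate(plate_id = nw$plate_id,
             sample_type = nw$design$sample_type,
             medium = nw$design$medium)
  })
  if (is.null(edges_all) || nrow(edges_all) == 0) {
    return(tibble(sample_type = character(), medium = character(),
                  zotu_a = character(), zotu_b = character(),
                  np = integer(), ng = integer(), fo = double(),
                  mean_rho = double(), sign_consensus = integer(),
                  sign_conflict = logical()))
  }
  edges_all |>
    group_by(.data$sample_type, .data$medium, .data$zotu_a, .data$zotu_b) |>
    summarise(
      np = dplyr::n_distinct(.data$plate_id),
      mean_rho = mean(.data$rho),
      n_pos = sum(.data$sign > 0), n_neg = sum(.data$sign < 0),
      .groups = "drop"
    ) |>
    left_join(ng, by = c("sample_type", "medium")) |>
    mutate(
      fo = .data$np / .data$ng,
      sign_consensus = dplyr::case_when(
        .data$n_pos > .data$n_neg ~ 1L,
        .data$n_neg > .data$n_pos ~ -1L,
        .default = as.integer(base::sign(.data$mean_rho))
      ),
      sign_conflict = .data$n_pos > 0 & .data$n_neg > 0
    ) |>
    select(!c("n_pos", "n_neg")) |>
    select("sample_type", "medium", "zotu_a", "zotu_b", "np", "ng", "fo",
           "mean_rho", "sign_consensus", "sign_conflict")
}

#' Retain robust prevalent pairs
#'
#' Keeps pairs whose occurrence frequency across their group's networks is
#' strictly greater than `fo_min` (the study retains pairs with occurrence
#' frequency > 30%; rho/FDR thresholds are enforced upstream at edge
#' construction).
#'
#' @param prevalences Output of [pair_prevalence()].
#' @param fo_min Strict lower bound on FO (default 0.30).
#' @return The filtered tibble.
#' @export
retain_robust_pairs <- function(prevalences, fo_min = 0.30) {
  prevalences |> filter(.data$fo > fo_min)
}

#' Top-k prevalent pairs per group
#'
#' The Table-style report: within each (sample type, medium) group, the `k`
#' pairs with the highest FO, ties broken by higher mean `|rho|`, then by
#' lexicographic pair id. Applied to the unfiltered prevalence list (the
#' robust list is a separate output).
#'
#' @param prevalences Output of [pair_prevalence()].
#' @param k Pairs reported per group (default 3).
#' @return Tibble of at most `k` rows per group, ranked.
#' @export
top_pairs_report <- function(prevalences, k = 3) {
  if (k < 1) abort("`k` must be >= 1.")
  prevalences |>
    group_by(.data$sample_type, .data$medium) |>
    arrange(desc(.data$fo), desc(abs(.data$mean_rho)), .data$zotu_a,
            .data$zotu_b, .by_group = TRUE) |>
    slice_head(n = k) |>
    mutate(rank = row_number()) |>
    ungroup()
}

#' Jaccard similarity matrix of network edge sets
#'
#' `J(i, j) = |E_i intersect E_j| / |E_i union E_j|` over unordered edge
#' sets; a comparison of two empty edge sets is defined as 0 (and noted),
#' since 0/0 is undefined. The diagonal is 1 for non-empty edge sets.
#'
#' @param networks A list of `cooccur_network`s.
#' @return A symmetric matrix of class `jaccard_matrix` with plate ids as
#'   dimnames.
#' @export
jaccard_matrix <- function(networks) {
  if (length(networks) == 0) abort("empty network list.")
  keys <- map(networks, edge_keys)
  ids <- map_chr(networks, function(nw) nw$plate_id)
  n <- length(keys)
  J <- matrix(0, n, n, dimnames = list(ids, ids))
  both_empty <- FALSE
  for (i in seq_len(n)) {
    for (j in i:n) {
      u <- length(union(keys[[i]], keys[[j]]))
      if (u == 0) {
        both_empty <- TRUE
        J[i, j] <- J[j, i] <- 0
      } else {
        J[i, j] <- J[j, i] <- length(intersect(keys[[i]], keys[[j]])) / u
      }
    }
  }
  if (both_empty) inform("some network pairs had two empty edge sets; their Jaccard similarity was set to 0.")
  structure(J, class = c("jaccard_matrix", "matrix", "array"))
}

#' @export
tidy.jaccard_matrix <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.data.frame(as.table(m))) |>
    setNames(c("network_1", "network_2", "jaccard")) |>
    mutate(across(c("network_1", "network_2"), as.character))
}

#' @export
autoplot.jaccard_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$network_1, .data$network_2,
                                 fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Number of unique pairs across an ensemble
#'
#' Cardinality of the union of edge sets over all networks.
#'
#' @param networks A list of `cooccur_network`s.
#' @return Integer count.
#' @export
unique_pair_count <- function(networks) {
  length(unique(unlist(map(networks, edge_keys))))
}

#' Write the pair-prevalence report TSV
#'
#' Columns mirror the published table: group (sample type, medium), the
#' pair, `np`, `ng`, `fo`, consensus sign and mean rho.
#'
#' @param prevalences Output of [pair_prevalence()] or
#'   [top_pairs_report()].
#' @param path Output TSV path.
#' @export
write_pair_report <- function(prevalences, path) {
  readr::write_tsv(prevalences, path)
  invisible(path)
}
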