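# Per-plate co-occurrence network inference: prevalence filter, tie-corrected
# Spearman correlations, BH-FDR, rho/q thresholds, degree-centrality
# sub-network, topology summary.

#' Prevalence filter for a plate
#'
#' Restricts a plate to its growing wells and to the prevalent Zotus: a
#' Zotu is retained iff it is present (count > 0) in at least `min_frac` of
#' the growing wells (the study filters Zotus with occurrence frequency
#' below 30% of wells, so 29 of 96 wells is kept). By default the
#' denominator is the number of growing wells; `denominator = "all"` uses
#' every well of the plate instead.
#'
#' @param plate A `plate_tbl`.
#' @param growth Optional result of [detect_growth()]; computed with
#'   `min_reads` if missing.
#' @param min_frac Minimum occurrence fraction (default 0.30; `>=`
#'   comparison).
#' @param min_reads Growth threshold used when `growth` is not supplied.
#' @param denominator `"growing"` (default) or `"all"`.
#' @return A `plate_tbl` restricted to growing wells and prevalent Zotus.
#' @export
prevalence_filter <- function(plate, growth = NULL, min_frac = 0.30,
                              min_reads = 100,
                              denominator = c("growing", "all")) {
  denominator <- match.arg(denominator)
  if (min_frac < 0 || min_frac > 1) abort("`min_frac` must be in [0, 1].")
  if (is.null(growth)) growth <- detect_growth(plate, min_reads = min_reads)
  grew <- plate$well %in% growth$well[growth$grew]
  if (!any(grew)) {
    abort(paste0("empty plate: no growing wells in '", plate_id(plate), "'"))
  }
  m <- plate_counts(plate)
  denom <- if (denominator == "growing") sum(grew) else nrow(m)
  prev <- colSums(m[grew, , drop = FALSE] > 0) / denom
  keep <- prev >= min_frac
  tbl <- as_tibble(as.data.frame(plate))[grew,
    c("well", names(keep)[keep]), drop = FALSE]
  new_plate_tbl(tbl, plate_id = plate_id(plate),
                design = plate_design_of(plate))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes rho as the Pearson correlation of mid-ranks (average ranks for
#' ties) and the two-sided p-value from `t = rho * sqrt((n-2)/(1-rho^2))`
#' with `n - 2` degrees of freedom (`|rho| = 1` gives p = 0). Zero variance
#' in either rank vector yields `NA` with a warning: the pair is undefined
#' and should be skipped.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @return A one-row tibble with columns `rho` and `p_raw`.
#' @examples
#' spearman_rho(1:5, c(2, 4, 6, 8, 10))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 4) abort("need n >= 4 observations.")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warn("constant ranks: Spearman correlation undefined, returning NA.")
    return(tibble(rho = NA_real_, p_raw = NA_real_))
  }
  rho <- cor(rx, ry)
  tibble(rho = rho, p_raw = spearman_p(rho, n))
}

spearman_p <- function(rho, n) {
  p <- ifelse(abs(rho) >= 1, 0,
              2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2))
  pmin(p, 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q_i = min over p_(j) >= p_(i) of
#' p_(j) * m / rank(j)`, clipped to 1, returned in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @examples
#' bh_fdr(c(0.001, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Build the co-occurrence network of one plate
#'
#' Computes all pairwise Spearman correlations between Zotus across the
#' plate's wells (by default on per-well relative abundances), adjusts the
#' p-values by Benjamini-Hochberg over all tested pairs within the plate,
#' and keeps an edge iff `|rho| > rho_min` and `q < q_max` (both strict).
#' Zotus with constant ranks are recorded as skipped and excluded from pair
#' enumeration; the returned network may be edgeless.
#'
#' @param plate A `plate_tbl`, normally the output of [prevalence_filter()]
#'   (>= 2 Zotus, >= 4 wells).
#' @param rho_min Strict lower bound on `|rho|` (default 0.6).
#' @param q_max Strict upper bound on the FDR-adjusted p (default 0.01).
#' @param use_relative Correlate per-well relative abundances (total-sum
#'   scaling, the default) or raw counts.
#' @return An object of class `cooccur_network`: plate id, design, a
#'   `nodes` tibble (`zotu`, `degree`), an `edges` tibble (`zotu_a` <
#'   `zotu_b`, `rho`, `p_raw`, `q_fdr`, `sign`), thresholds, and the
#'   skipped-Zotu log.
#' @export
build_network <- function(plate, rho_min = 0.6, q_max = 0.01,
                          use_relative = TRUE) {
  m <- plate_counts(plate)
  if (ncol(m) < 2) abort("need >= 2 Zotus to build a network.")
  if (nrow(m) < 4) abort("need >= 4 wells to build a network.")
  x <- m * 1.0
  if (use_relative) {
    rs <- rowSums(x)
    x <- x / ifelse(rs == 0, 1, rs)
  }
  ranks <- apply(x, 2, rank)
  sds <- apply(ranks, 2, sd)
  valid <- sds > 0
  skipped <- tibble(zotu = colnames(m)[!valid],
                    reason = "constant ranks across wells")
  edges <- tibble(zotu_a = character(), zotu_b = character(),
                  rho = double(), p_raw = double(), q_fdr = double(),
                  sign = integer())
  if (sum(valid) >= 2) {
    r <- ranks[, valid, drop = FALSE]
    C <- cor(r)
    n <- nrow(r)
    idx <- which(upper.tri(C), arr.ind = TRUE)
    za <- colnames(C)[idx[, 1]]; zb <- colnames(C)[idx[, 2]]
    rho <- C[idx]
    all_pairs <- tibble(
      zotu_a = pmin(za, zb), zotu_b = pmax(za, zb),
      rho = rho, p_raw = spearman_p(rho, n)
    )
    all_pairs$q_fdr <- bh_fdr(all_pairs$p_raw)
    edges <- all_pairs |>
      filter(abs(.data$rho) > rho_min, .data$q_fdr < q_max) |>
      mutate(sign = as.integer(base::sign(.data$rho))) |>
      arrange(.data$zotu_a, .data$zotu_b)
  }
  new_cooccur_network(
    plate_id = plate_id(plate), design = plate_design_of(plate),
    zotus = colnames(m)[valid], edges = edges,
    thresholds = list(rho_min = rho_min, q_max = q_max),
    n_wells_used = nrow(m), skipped = skipped
  )
}

new_cooccur_network <- function(plate_id, design, zotus, edges, thresholds,
                                n_wells_used = NA_integer_,
                                skipped = NULL) {
  deg <- table(factor(c(edges$zotu_a, edges$zotu_b), levels = zotus))
  structure(
    list(
      plate_id = plate_id, design = design,
      nodes = tibble(zotu = zotus, degree = as.integer(deg)),
      edges = edges, thresholds = thresholds,
      n_wells_used = n_wells_used,
      skipped = skipped %||% tibble(zotu = character(), reason = character())
    ),
    class = "cooccur_network"
  )
}

#' @export
print.cooccur_network <- function(x, ...) {
  cat(sprintf("<cooccur_network> %s: %d nodes, %d edges (%d +, %d -)\n",
              x$plate_id, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Low-degree sub-network
#'
#' Retains the nodes whose degree in the input network is strictly below
#' `max_degree` (the study keeps nodes with degree centrality < 5) and the
#' edges whose two endpoints are both retained. The selection is a single
#' pass: degrees are taken from the input network and not recomputed
#' iteratively, though the returned node table reports the post-filter
#' degrees.
#'
#' @param network A `cooccur_network`.
#' @param max_degree Strict upper bound on input-network degree (default 5).
#' @return A `cooccur_network` sub-network.
#' @export
degree_filter <- function(network, max_degree = 5) {
  keep <- network$nodes$zotu[network$nodes$degree < max_degree]
  edges <- network$edges |>
    filter(.data$zotu_a %in% keep, .data$zotu_b %in% keep)
  out <- new_cooccur_network(
    plate_id = network$plate_id, design = network$design,
    zotus = keep, edges = edges,
    thresholds = c(network$thresholds, list(max_degree = max_degree)),
    n_wells_used = network$n_wells_used, skipped = network$skipped
  )
  out
}

#' Topology summary of a network
#'
#' @param network A `cooccur_network`.
#' @return A one-row tibble: `plate_id`, `n_nodes`, `n_edges`,
#'   `n_positive`, `n_negative`, `density` (2E / (N (N-1)); 0 when N < 2),
#'   `mean_degree`, `max_degree`.
#' @export
network_summary <- function(network) {
  nn <- nrow(network$nodes); ne <- nrow(network$edges)
  tibble(
    plate_id = network$plate_id,
    n_nodes = nn, n_edges = ne,
    n_positive = sum(network$edges$sign > 0),
    n_negative = sum(network$edges$sign < 0),
    density = if (nn >= 2) 2 * ne / (nn * (nn - 1)) else 0,
    mean_degree = if (nn > 0) mean(network$nodes$degree) else 0,
    max_degree = if (nn > 0) max(network$nodes$degree) else 0L
  )
}

#' @export
tidy.cooccur_network <- function(x, ...) x$edges

#' @export
glance.cooccur_network <- function(x, ...) network_summary(x)

#' Convert a network to igraph / export it
#'
#' `as_igraph()` returns an igraph graph with `rho`, `p_raw`, `q_fdr` and
#' `sign` edge attributes; `write_edge_list()` writes the edge TSV
#' (`zotu_a`, `zotu_b`, `rho`, `p_raw`, `q_fdr`, `sign`);
#' `write_graphml()` exports GraphML for external viewers.
#'
#' @param network A `cooccur_network`.
#' @param path Output path.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = as.data.frame(network$nodes)
  )
}

#' @rdname as_igraph
#' @export
write_edge_list <- function(network, path) {
  readr::write_tsv(network$edges, path)
  invisible(path)
}

#' @rdname as_igraph
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Network autoplot
#'
#' Fruchterman-Reingold layout with positive edges solid and negative edges
#' dashed.
#'
#' @param object A `cooccur_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cooccur_network <- function(object, ...) {
  g <- as_igraph(object)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(zotu = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(nodes, by = c(zotu_a = "zotu")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(nodes, by = c(zotu_b = "zotu"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y,
                   linetype = factor(.data$sign, c(1, -1), c("+", "-")))
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 2) +
    ggplot2::labs(title = object$plate_id, linetype = "sign") +
    ggplot2::theme_void()
}
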