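# Independent brute-force oracles and small fixture builders used across the
# suite. Everything here is deliberately naive: these implementations define
# the expected answers, the package code is checked against them.

# all permutations of 1..n as an (n!) x n matrix
perms_of <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    gen <- function(n) {
      if (n == 1) return(matrix(1L, 1, 1))
      sub <- gen(n - 1)
      do.call(rbind, lapply(1:n, function(k) {
        rest <- setdiff(1:n, k)
        cbind(k, matrix(rest[sub], nrow(sub), n - 1))
      }))
    }
    cache[[key]] <<- gen(n)
    cache[[key]]
  }
})

# Pearson correlation of mid-ranks, written out from the definition
rank_pearson_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# exact two-sided permutation p-value for Spearman's rho over all n! orderings
spearman_perm_p_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- rank_pearson_oracle(x, y)
  P <- perms_of(n)
  M <- matrix(ry[P], nrow(P), n)
  Mc <- M - rowMeans(M)
  dx <- rx - mean(rx)
  rhos <- as.vector(Mc %*% dx) / sqrt(rowSums(Mc^2) * sum(dx^2))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# BH step-up from its definition: q_i = min over {j : p_(j) >= p_i} of
# p_(j) * m / rank(j), clipped to 1
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  cand <- pmin(sp * m / seq_len(m), 1)
  vapply(p, function(pi) min(cand[sp >= pi - 1e-15]), numeric(1))
}

# random additive distance matrix from a random tree with known topology
random_additive <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.1, 1))
  })
  tr <- ape::unroot(tr)
  list(tree = tr, d = cophenetic(tr))
}

# build a plate_tbl directly from a count matrix (wells x taxa)
make_plate <- function(counts, design = plate_design("roots", "R2A", 4),
                       id = "test-plate") {
  tbl <- tibble::as_tibble(as.data.frame(counts))
  tbl <- dplyr::bind_cols(
    tibble::tibble(well = rownames(counts) %||% well_ids(nrow(counts))),
    tbl
  )
  wellnets:::new_plate_tbl(tbl, plate_id = id, design = design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a cooccur_network directly from an edge data frame
make_net <- function(edges, zotus = NULL,
                     design = plate_design("roots", "R2A", 4),
                     id = design_id(design)) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges)) {
    a <- pmin(edges$zotu_a, edges$zotu_b)
    b <- pmax(edges$zotu_a, edges$zotu_b)
    edges$zotu_a <- a; edges$zotu_b <- b
    if (!"rho" %in% names(edges)) edges$rho <- 0.9
    if (!"p_raw" %in% names(edges)) edges$p_raw <- 1e-6
    if (!"q_fdr" %in% names(edges)) edges$q_fdr <- 1e-5
    edges$sign <- as.integer(sign(edges$rho))
  } else {
    edges <- tibble::tibble(zotu_a = character(), zotu_b = character(),
                            rho = double(), p_raw = double(),
                            q_fdr = double(), sign = integer())
  }
  zotus <- zotus %||% sort(unique(c(edges$zotu_a, edges$zotu_b)))
  wellnets:::new_cooccur_network(
    plate_id = id, design = design, zotus = zotus, edges = edges,
    thresholds = list(rho_min = 0.6, q_max = 0.01)
  )
}

# a group of n networks with distinct plate ids, same (sample_type, medium)
make_group <- function(edge_sets, sample_type = "roots", medium = "TSB") {
  reps <- c("A", "B", "C")
  lapply(seq_along(edge_sets), function(i) {
    d <- plate_design(sample_type, medium,
                      dilution_level = ((i - 1) %/% 3) + 1,
                      replicate = reps[((i - 1) %% 3) + 1])
    make_net(edge_sets[[i]], design = d, id = design_id(d))
  })
}

edges_df <- function(...) {
  pairs <- list(...)
  tibble::tibble(
    zotu_a = vapply(pairs, `[`, character(1), 1),
    zotu_b = vapply(pairs, `[`, character(1), 2)
  )
}
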