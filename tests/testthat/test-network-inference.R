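test_that("prevalence filter keeps Zotus at >= 30% of growing wells", {
  # 96 growing wells; Z1 present in 29 (0.302 -> kept), Z2 in 28 (dropped),
  # Z3 everywhere (kept)
  counts <- matrix(0L, 96, 3, dimnames = list(well_ids(96),
                                              c("Z1", "Z2", "Z3")))
  counts[, 3] <- 150L
  counts[1:29, 1] <- 5L
  counts[1:28, 2] <- 5L
  p <- make_plate(counts)
  fp <- prevalence_filter(p, min_reads = 100)
  expect_setequal(zotu_ids(fp), c("Z1", "Z3"))
  expect_equal(nrow(fp), 96)
  # min_frac = 1 keeps only ubiquitous Zotus
  expect_identical(zotu_ids(prevalence_filter(p, min_frac = 1)), "Z3")
  # wells without growth are removed before correlation
  counts[40:96, 3] <- 0L
  p2 <- make_plate(counts)
  fp2 <- prevalence_filter(p2, min_reads = 100)
  expect_equal(nrow(fp2), 39)
  # zero growing wells is an error
  expect_error(prevalence_filter(p, min_reads = 1e6), "no growing wells")
})

test_that("spearman_rho handles perfect monotone and hand-ranked tied cases", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10)),
               tibble::tibble(rho = 1, p_raw = 0))
  expect_equal(spearman_rho(1:5, c(5, 4, 3, 2, 1)),
               tibble::tibble(rho = -1, p_raw = 0))
  # mid-ranks: x -> (1, 2.5, 2.5, 4), y -> (2, 1, 3.5, 3.5)
  out <- spearman_rho(c(1, 2, 2, 4), c(3, 1, 4, 4))
  expect_equal(out$rho, rank_pearson_oracle(c(1, 2, 2, 4), c(3, 1, 4, 4)))
  rx <- c(1, 2.5, 2.5, 4); ry <- c(2, 1, 3.5, 3.5)
  expect_equal(out$rho, cor(rx, ry))
  expect_error(spearman_rho(1:3, 1:3), "n >= 4")
  expect_error(spearman_rho(1:5, 1:4), "equal length")
  expect_warning(res <- spearman_rho(rep(2, 5), 1:5), "constant ranks")
  expect_true(is.na(res$rho))
})

test_that("spearman_rho is invariant to strictly monotone transforms", {
  withr::with_seed(42, {
    for (i in 1:20) {
      x <- rnorm(15); y <- rnorm(15)
      base <- spearman_rho(x, y)
      expect_equal(spearman_rho(exp(x), y), base)
      expect_equal(spearman_rho(x, exp(y)), base)
    }
  })
})

test_that("t-approximation p-values track the exact permutation distribution", {
  withr::with_seed(7, {
    # at n >= 6 the t-approximation sits within 0.05 of the exact
    # permutation p; at the smallest sample sizes its known small-n
    # inaccuracy grows, so the agreement band is wider there
    for (i in 1:40) {
      n <- sample(6:8, 1)
      x <- runif(n); y <- runif(n)
      got <- spearman_rho(x, y)
      expect_equal(got$rho, rank_pearson_oracle(x, y), tolerance = 1e-12)
      expect_lt(abs(got$p_raw - spearman_perm_p_oracle(x, y)), 0.05)
    }
    for (i in 1:20) {
      n <- sample(4:5, 1)
      x <- runif(n); y <- runif(n)
      got <- spearman_rho(x, y)
      expect_lt(abs(got$p_raw - spearman_perm_p_oracle(x, y)), 0.16)
    }
  })
})

test_that("bh_fdr reproduces the step-up definition", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.03, 0.04)),
               c(0.004, 0.04, 0.04, 0.04))
  expect_equal(bh_fdr(rep(0.37, 6)), rep(0.37, 6))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
  withr::with_seed(11, {
    for (i in 1:50) {
      p <- runif(sample(2:40, 1))
      q <- bh_fdr(p)
      expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-12)
      expect_true(all(q >= p))                      # pointwise inflation
      expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in sorted order
    }
  })
})

test_that("build_network keeps only strict rho/q-threshold edges", {
  # Z1 and Z2 perfectly monotone across 20 wells; Z3 constant (skipped)
  counts <- cbind(Z1 = 1:20, Z2 = (1:20)^2, Z3 = rep(7L, 20))
  storage.mode(counts) <- "integer"
  rownames(counts) <- well_ids(20)
  nw <- build_network(make_plate(counts), use_relative = FALSE)
  expect_equal(nrow(nw$edges), 1)
  expect_equal(nw$edges$zotu_a, "Z1")
  expect_equal(nw$edges$zotu_b, "Z2")
  expect_equal(nw$edges$sign, 1L)
  expect_equal(nw$edges$rho, 1)
  expect_identical(nw$skipped$zotu, "Z3")

  # rho = 0.6 exactly (sum of squared rank differences = 8 at n = 5) is
  # excluded by the strict inequality; rho = 0.7 passes
  at_boundary <- cbind(Z1 = 1:5, Z2 = c(1L, 2L, 5L, 4L, 3L))
  rownames(at_boundary) <- well_ids(5)
  nw <- build_network(make_plate(at_boundary), rho_min = 0.6, q_max = 0.9999,
                      use_relative = FALSE)
  expect_equal(nrow(nw$edges), 0)
  above <- cbind(Z1 = 1:5, Z2 = c(1L, 2L, 5L, 3L, 4L))
  rownames(above) <- well_ids(5)
  nw <- build_network(make_plate(above), rho_min = 0.6, q_max = 0.9999,
                      use_relative = FALSE)
  expect_equal(nrow(nw$edges), 1)
  expect_equal(nw$edges$rho, 0.7)
})

test_that("a planted strong pair is detected and false edges respect the FDR", {
  src <- simulate_source(40, lognormal_sigma = 0, cells_per_ul = 1e6, seed = 21)
  des <- plate_design("roots", "R2A", dilution_level = 3)
  tr <- interaction_truth(data.frame(species_a = "Zotu001",
                                     species_b = "Zotu002",
                                     sign = 1, effect_size = 1))
  found <- 0; false_edges <- 0; n_pairs_total <- 0
  for (s in 1:10) {
    p <- simulate_plate(src, des, truth = tr, read_depth = 5000,
                        seed = 900 + s, co_colonization = TRUE,
                        co_seed_sd = 1.0)
    nw <- build_network(prevalence_filter(p))
    planted <- nw$edges$zotu_a == "Zotu001" & nw$edges$zotu_b == "Zotu002"
    found <- found + any(planted)
    false_edges <- false_edges + sum(!planted)
    k <- nrow(nw$nodes)
    n_pairs_total <- n_pairs_total + k * (k - 1) / 2
  }
  expect_gte(found, 9)
  expect_lte(false_edges, 0.01 * n_pairs_total)
})

test_that("degree filter removes hubs in a single pass", {
  star <- make_net(edges_df(c("hub", "l1"), c("hub", "l2"), c("hub", "l3"),
                            c("hub", "l4"), c("hub", "l5"), c("hub", "l6")))
  sub <- degree_filter(star, max_degree = 5)
  expect_setequal(sub$nodes$zotu, paste0("l", 1:6))  # leaves kept, isolated
  expect_equal(nrow(sub$edges), 0)
  expect_true(all(sub$nodes$degree == 0))

  path <- make_net(edges_df(c("a", "b"), c("b", "c"), c("c", "d"),
                            c("d", "e")))
  expect_equal(degree_filter(path, 5)$edges, path$edges)
  expect_setequal(degree_filter(path, 5)$nodes$zotu, path$nodes$zotu)

  withr::with_seed(5, {
    for (i in 1:10) {
      nodes <- paste0("z", 1:12)
      all_pairs <- t(combn(nodes, 2))
      pick <- all_pairs[runif(nrow(all_pairs)) < 0.3, , drop = FALSE]
      nw <- make_net(tibble::tibble(zotu_a = pick[, 1], zotu_b = pick[, 2]),
                     zotus = nodes)
      sub <- degree_filter(nw, max_degree = 4)
      expect_true(all(sub$nodes$degree < 4))
    }
  })
})

test_that("network summaries match brute-force pair counting", {
  tri <- make_net(edges_df(c("a", "b"), c("b", "c"), c("a", "c")))
  s <- network_summary(tri)
  expect_equal(s$n_nodes, 3)
  expect_equal(s$n_edges, 3)
  expect_equal(s$density, 1)
  expect_equal(s$n_positive, 3)

  empty <- make_net(edges_df(), zotus = c("a", "b", "c"))
  s <- network_summary(empty)
  expect_equal(s$density, 0)
  expect_equal(s$mean_degree, 0)

  withr::with_seed(8, {
    nodes <- paste0("z", 1:9)
    all_pairs <- t(combn(nodes, 2))
    pick <- all_pairs[runif(nrow(all_pairs)) < 0.4, , drop = FALSE]
    nw <- make_net(tibble::tibble(zotu_a = pick[, 1], zotu_b = pick[, 2]),
                   zotus = nodes)
    s <- network_summary(nw)
    # brute force: count connected node pairs over all pairs
    keys <- paste(pmin(pick[, 1], pick[, 2]), pmax(pick[, 1], pick[, 2]))
    hits <- sum(paste(all_pairs[, 1], all_pairs[, 2]) %in% keys)
    expect_equal(s$density, hits / nrow(all_pairs))
    expect_equal(s$n_edges, s$n_positive + s$n_negative)
    expect_equal(s$mean_degree, 2 * s$n_edges / s$n_nodes)
  })
})

test_that("networks are invariant to Zotu column permutation", {
  src <- simulate_source(12, lognormal_sigma = 0.4, cells_per_ul = 1e6,
                         seed = 31)
  des <- plate_design("sediments", "TSB", dilution_level = 4)
  p <- simulate_plate(src, des, read_depth = 3000, seed = 32)
  fp <- prevalence_filter(p)
  nw1 <- build_network(fp, rho_min = 0.2, q_max = 0.5)
  perm <- withr::with_seed(1, sample(zotu_ids(fp)))
  tbl <- tibble::as_tibble(as.data.frame(fp))[, c("well", perm)]
  fp2 <- wellnets:::new_plate_tbl(tbl, plate_id = plate_id(fp),
                                  design = plate_design_of(fp))
  nw2 <- build_network(fp2, rho_min = 0.2, q_max = 0.5)
  expect_equal(dplyr::arrange(nw1$edges, zotu_a, zotu_b),
               dplyr::arrange(nw2$edges, zotu_a, zotu_b))
})

test_that("edge lists and GraphML export round-trip through igraph", {
  nw <- make_net(edges_df(c("a", "b"), c("b", "c")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(nw, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$zotu_a, nw$edges$zotu_a)
  g <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(nw, g)
  reread <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::gsize(reread), 2)
  expect_equal(igraph::vcount(reread), 3)
})
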