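FWD <- "GTGYCAGCMGCCGCGGTAA"
REV <- "GGACTACNVGGGTWTCTAAT"
rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

test_that("extract_v4 recovers the exact insert between primer sites", {
  insert <- strrep("ACGT", 60)
  seq <- paste0("TTAACC", "GTGTCAGCAGCCGCGGTAA", insert, rc(REV), "GGTTAA")
  expect_equal(extract_v4(seq, FWD, REV), insert)
  expect_equal(nchar(extract_v4(seq, FWD, REV)), 240)
  # the extracted insert is identical to the embedded one
  expect_equal(pairwise_identity(extract_v4(seq, FWD, REV), insert), 1)
})

test_that("extract_v4 signals missing amplicons and honours the mismatch budget", {
  insert <- strrep("GATC", 50)
  no_rev <- paste0("GTGTCAGCAGCCGCGGTAA", insert)
  expect_true(is.na(extract_v4(no_rev, FWD, REV)))
  # one mismatch in the forward site is within the default budget
  fwd_mut <- "GTGTCAGCAGCCGCGGTCA"
  seq <- paste0(fwd_mut, insert, rc(REV))
  expect_equal(extract_v4(seq, FWD, REV, max_mismatch = 1), insert)
  expect_true(is.na(extract_v4(seq, FWD, REV, max_mismatch = 0)))
  # two forward sites: leftmost used, with a warning
  twice <- paste0("GTGTCAGCAGCCGCGGTAA", "AAAA", "GTGTCAGCAGCCGCGGTAA",
                  insert, rc(REV))
  expect_warning(out <- extract_v4(twice, FWD, REV), "leftmost")
  expect_equal(out, paste0("AAAA", "GTGTCAGCAGCCGCGGTAA", insert))
})

test_that("pairwise identity follows the global-alignment scoring scheme", {
  s <- strrep("ACGTTGCA", 32)  # 256 nt
  expect_equal(pairwise_identity(s, s), 1)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  withr::with_seed(3, {
    a <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    expect_lt(pairwise_identity(a, b), 1)
  })
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("neighbor joining reproduces a hand-solved additive 4-taxon tree", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  # four-point condition: AB|CD split (3 + 7 < 5 + 7 = 6 + 6)
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  # pendant branches A:1, B:2, C:3, D:4 and one internal branch of 1
  pend <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                        tr$edge[, 2])], tr$tip.label)
  expect_equal(pend[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 4))
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))
  # the tree reproduces the input distances exactly
  expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d, tolerance = 1e-12)
  # topology AB|CD
  ref <- ape::unroot(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  expect_equal(ape::dist.topo(ape::unroot(tr), ref)[1], 0, ignore_attr = TRUE)
})

test_that("three taxa solve the closed-form star equations", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d)
  pend <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(pend[c("x", "y", "z")], c(x = 1, y = 2, z = 3))
})

test_that("neighbor joining recovers random additive trees and agrees with ape", {
  for (s in 1:10) {
    n <- sample(4:12, 1)
    ref <- random_additive(n, seed = 100 + s)
    tr <- nj_tree(ref$d)
    # path-length reconstruction of the additive matrix
    expect_lt(max(abs(cophenetic(tr)[rownames(ref$d), colnames(ref$d)] -
                        ref$d)), 1e-9)
    # topology identical to the generating tree and to ape's NJ
    expect_equal(ape::dist.topo(ape::unroot(tr), ref$tree)[1], 0,
                 ignore_attr = TRUE)
    ape_tr <- ape::nj(ref$d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ape_tr))[1], 0,
                 ignore_attr = TRUE)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), ">= 3 taxa")
  asym <- matrix(c(0, 1, 5, 2, 0, 1, 1, 3, 0), 3, 3)
  expect_error(nj_tree(asym), "symmetric")
})

make_isolate <- function(v4, flank_seed = 1) {
  withr::with_seed(flank_seed, {
    fl <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
    paste0(fl(40), "GTGTCAGCAGCCGCGGTAA", v4, rc(REV), fl(40))
  })
}

mutate_seq <- function(s, k, seed = 2) {
  withr::with_seed(seed, {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), k)) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    paste(ch, collapse = "")
  })
}

test_that("isolates match Zotus by identical V4 or nearest tree leaf", {
  zotus <- simulate_zotu_seqs(c("ZotuA", "ZotuB", "ZotuC"), seed = 5)
  isolates <- tibble::tibble(
    id = c("ISO-1", "ISO-2", "ISO-3"),
    sequence = c(
      make_isolate(zotus$sequence[1], 1),                 # exact V4 of ZotuA
      make_isolate(mutate_seq(zotus$sequence[2], 2), 2),  # 2 mismatches to ZotuB
      make_isolate(paste(rep("AC", 125), collapse = ""), 3)  # unrelated
    )
  )
  m <- match_isolates(zotus, isolates)
  m1 <- m[m$isolate_id == "ISO-1", ]
  expect_true(m1$matched)
  expect_equal(m1$zotu_id, "ZotuA")
  expect_equal(m1$v4_identity, 1)
  m2 <- m[m$isolate_id == "ISO-2", ]  # below identity 1, rescued by the tree
  expect_true(m2$matched)
  expect_equal(m2$zotu_id, "ZotuB")
  expect_lt(m2$v4_identity, 1)
  expect_lt(m2$tree_distance, 0.03)
  m3 <- m[m$isolate_id == "ISO-3", ]  # beyond the distance cap
  expect_false(m3$matched)
  expect_true(is.na(m3$zotu_id))
  expect_setequal(unmatched_zotus(m), "ZotuC")
})

test_that("matching is invariant to input row order", {
  zotus <- simulate_zotu_seqs(c("ZotuA", "ZotuB", "ZotuC"), seed = 6)
  isolates <- tibble::tibble(
    id = c("ISO-1", "ISO-2"),
    sequence = c(make_isolate(zotus$sequence[2], 4),
                 make_isolate(zotus$sequence[3], 5))
  )
  m1 <- match_isolates(zotus, isolates)
  m2 <- match_isolates(zotus[c(3, 1, 2), ], isolates[2:1, ])
  expect_equal(tibble::as_tibble(m1), tibble::as_tibble(m2))
})

test_that("isolate combinations enumerate shared, disjoint and mixed sets", {
  matches <- tibble::tibble(
    isolate_id = c(paste0("BOP-", c(1, 5, 11, 16)),
                   paste0("BOP-", c(1, 5, 11, 16)),
                   "BOP-102", "BOP-108"),
    zotu_id = c(rep("Zotu1", 4), rep("Zotu12259", 4), rep("Zotu10", 2)),
    matched = TRUE
  )
  # shared set of four isolates: choose(4, 2) = 6 combinations
  shared <- enumerate_combinations("Zotu1", "Zotu12259", matches)
  expect_equal(nrow(shared), 6)
  expect_true(all(shared$isolate_1 < shared$isolate_2))
  # disjoint sets of 4 and 2: 8 combinations
  expect_equal(nrow(enumerate_combinations("Zotu1", "Zotu10", matches)), 8)
  # overlapping sets: cross pairs minus self-pairs, deduplicated
  overlap <- tibble::tibble(
    isolate_id = c("i1", "i2", "i3", "i2", "i3", "i4"),
    zotu_id = c(rep("Zx", 3), rep("Zy", 3)),
    matched = TRUE
  )
  combos <- enumerate_combinations("Zx", "Zy", overlap)
  expect_equal(nrow(combos), 6)  # i1i2 i1i3 i1i4 i2i3 i2i4 i3i4
  expect_error(enumerate_combinations("Zx", "Zmissing", overlap), "Zmissing")
})
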