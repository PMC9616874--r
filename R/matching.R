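# Matching cultured isolates to network Zotus: V4 extraction by primer
# search, global-alignment identity, neighbor-joining tree proximity, and
# enumeration of isolate combinations representing a Zotu pair.

#' Extract the V4 amplicon from a 16S sequence
#'
#' Finds the forward primer site and, downstream of it, the reverse primer
#' site (matched as its reverse complement), honouring IUPAC degeneracies
#' and allowing up to `max_mismatch` mismatches per site, and returns the
#' insert between them (primers excluded). Returns `NA` when either site is
#' absent within the mismatch budget (no amplicon); with several forward
#' hits the leftmost is used with a warning.
#'
#' @param sequence A single DNA sequence (character).
#' @param fwd_primer,rev_primer Primer sequences, both given 5'->3'
#'   (defaults: the standard V4 pair 515F/806R).
#' @param max_mismatch Mismatch budget per primer site (default 1).
#' @return The insert as a character scalar, or `NA_character_`.
#' @export
extract_v4 <- function(sequence,
                       fwd_primer = "GTGYCAGCMGCCGCGGTAA",
                       rev_primer = "GGACTACNVGGGTWTCTAAT",
                       max_mismatch = 1) {
  subj <- Biostrings::DNAString(sequence)
  fhits <- Biostrings::matchPattern(Biostrings::DNAString(fwd_primer), subj,
                                    max.mismatch = max_mismatch,
                                    fixed = FALSE)
  if (length(fhits) == 0) return(NA_character_)
  if (length(fhits) > 1) warn("multiple forward primer hits; using the leftmost.")
  fend <- Biostrings::end(fhits)[1]
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(rev_primer))
  rhits <- Biostrings::matchPattern(rc, subj, max.mismatch = max_mismatch,
                                    fixed = FALSE)
  starts <- Biostrings::start(rhits)
  starts <- starts[starts > fend]
  if (length(starts) == 0) return(NA_character_)
  rstart <- min(starts)
  if (rstart - 1 < fend + 1) return(NA_character_)
  as.character(subj[(fend + 1):(rstart - 1)])
}

#' Pairwise sequence identity by global alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and linear
#' gap penalty -2; identity is the number of matched columns divided by the
#' total number of alignment columns. Symmetric, and 1 exactly iff the two
#' sequences are identical.
#'
#' @param a,b DNA sequences (character scalars, non-empty).
#' @return Identity in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty.")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2
  )
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / cols
}

#' Pairwise p-distance matrix of a sequence set
#'
#' `1 - pairwise_identity` for every pair; symmetric with a zero diagonal.
#'
#' @param seqs Tibble with columns `id`, `sequence`.
#' @return A labelled symmetric matrix.
#' @export
pdistance_matrix <- function(seqs) {
  n <- nrow(seqs)
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- 1 - pairwise_identity(seqs$sequence[i],
                                                    seqs$sequence[j])
      }
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining: iteratively joins the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch
#' lengths from the standard NJ formulas. Negative branch lengths are
#' clamped to zero with the deficit shifted to the sister branch (a note is
#' emitted). On an additive distance matrix the tree reproduces every
#' pairwise distance exactly.
#'
#' @param d A symmetric distance matrix with labelled dimnames (or a
#'   `dist`), at least 3 taxa, zero diagonal.
#' @return An unrooted `phylo` tree (ape) with branch lengths.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) abort("need >= 3 taxa for neighbor joining.")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric.")
  labels <- rownames(d)
  # each active cluster is represented by a newick fragment
  frag <- labels
  clamped <- 0L
  fmt <- function(x) sprintf("%.15g", x)
  while (length(frag) > 3) {
    r <- nrow(d)
    rs <- rowSums(d)
    Q <- (r - 2) * d - outer(rs, rs, `+`)
    diag(Q) <- Inf
    k <- which.min(Q)  # first minimum in column-major order: deterministic
    i <- (k - 1) %% r + 1
    j <- (k - 1) %/% r + 1
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    bi <- 0.5 * d[i, j] + (rs[i] - rs[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- d[i, j]; bi <- 0; clamped <- clamped + 1L }
    if (bj < 0) { bi <- d[i, j]; bj <- 0; clamped <- clamped + 1L }
    newfrag <- paste0("(", frag[i], ":", fmt(bi), ",", frag[j], ":",
                      fmt(bj), ")")
    dn <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    d <- rbind(cbind(d, new = dn), new = c(dn, 0))
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    frag <- c(frag[-c(i, j)], newfrag)
  }
  # resolve the final three clusters around a central node
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b <- c(b1, b2, b3)
  if (any(b < 0)) { clamped <- clamped + sum(b < 0); b[b < 0] <- 0 }
  if (clamped > 0) {
    inform(sprintf("neighbor joining clamped %d negative branch length(s).",
                   clamped))
  }
  txt <- paste0("(", frag[1], ":", fmt(b[1]), ",", frag[2], ":", fmt(b[2]),
                ",", frag[3], ":", fmt(b[3]), ");")
  ape::read.tree(text = txt)
}

#' Match isolates to Zotus
#'
#' An isolate is matched to a Zotu when the identity between its extracted
#' V4 region and the Zotu's V4 sequence reaches `identity_threshold`
#' (default 1: an identical V4 region). Otherwise the isolate falls back to
#' the nearest Zotu leaf by path length on the neighbor-joining tree of all
#' V4 sequences, accepted only when that distance is below `distance_cap`
#' (default 0.03, roughly a 3% divergence guard against cross-genus
#' matches). Identity ties are broken by tree distance, then left
#' unmatched. Deterministic and invariant to input row order.
#'
#' @param zotus Tibble of Zotu V4 sequences (`id`, `sequence`).
#' @param isolates Tibble of isolate 16S sequences (`id`, `sequence`).
#' @param identity_threshold Identity required for a direct match
#'   (default 1.0).
#' @param distance_cap Strict upper bound on the tree path length of a
#'   fallback match (default 0.03).
#' @param fwd_primer,rev_primer,max_mismatch V4 extraction parameters
#'   (see [extract_v4()]).
#' @return A tibble of class `isolate_matches`: `isolate_id`, `zotu_id`
#'   (`NA` if unmatched), `v4_identity`, `tree_distance`, `matched`. The
#'   NJ tree is attached as attribute `"tree"`; [unmatched_zotus()] lists
#'   Zotus no isolate represents.
#' @export
match_isolates <- function(zotus, isolates, identity_threshold = 1.0,
                           distance_cap = 0.03,
                           fwd_primer = "GTGYCAGCMGCCGCGGTAA",
                           rev_primer = "GGACTACNVGGGTWTCTAAT",
                           max_mismatch = 1) {
  zotus <- zotus |> arrange(.data$id)
  isolates <- isolates |> arrange(.data$id)
  v4 <- map_chr(isolates$sequence, extract_v4, fwd_primer = fwd_primer,
                rev_primer = rev_primer, max_mismatch = max_mismatch)
  ok <- !is.na(v4)
  idm <- matrix(NA_real_, nrow(isolates), nrow(zotus),
                dimnames = list(isolates$id, zotus$id))
  for (i in which(ok)) {
    for (j in seq_len(nrow(zotus))) {
      idm[i, j] <- pairwise_identity(v4[i], zotus$sequence[j])
    }
  }
  # NJ tree over all V4 sequences (Zotus + amplifiable isolates)
  pool <- bind_rows(
    tibble(id = zotus$id, sequence = zotus$sequence),
    tibble(id = isolates$id[ok], sequence = v4[ok])
  )
  tree <- NULL; treed <- NULL
  if (nrow(pool) >= 3) {
    tree <- nj_tree(pdistance_matrix(pool))
    treed <- cophenetic(tree)
  }
  rows <- map_dfr(seq_len(nrow(isolates)), function(i) {
    iso <- isolates$id[i]
    if (!ok[i]) {
      return(tibble(isolate_id = iso, zotu_id = NA_character_,
                    v4_identity = NA_real_, tree_distance = NA_real_,
                    matched = FALSE))
    }
    ids <- idm[i, ]
    td <- if (!is.null(treed) && iso %in% rownames(treed)) {
      treed[iso, zotus$id]
    } else {
      setNames(rep(NA_real_, nrow(zotus)), zotus$id)
    }
    best_id <- max(ids)
    cand <- names(ids)[ids == best_id]
    if (best_id >= identity_threshold) {
      pick <- tie_break(cand, td)
      return(tibble(isolate_id = iso, zotu_id = pick,
                    v4_identity = best_id,
                    tree_distance = if (is.na(pick)) NA_real_ else unname(td[pick]),
                    matched = !is.na(pick)))
    }
    # fallback: nearest Zotu leaf on the tree, within the cap
    if (all(is.na(td))) {
      return(tibble(isolate_id = iso, zotu_id = NA_character_,
                    v4_identity = best_id, tree_distance = NA_real_,
                    matched = FALSE))
    }
    nearest <- names(td)[td == min(td)]
    pick <- if (length(nearest) == 1) nearest else NA_character_
    dist <- min(td)
    okdist <- !is.na(pick) && dist < distance_cap
    tibble(isolate_id = iso,
           zotu_id = if (okdist) pick else NA_character_,
           v4_identity = unname(ids[if (!is.na(pick)) pick else which.max(ids)]),
           tree_distance = dist,
           matched = okdist)
  })
  structure(rows, class = c("isolate_matches", class(tibble())),
            tree = tree, zotu_ids = zotus$id)
}

tie_break <- function(cand, td) {
  if (length(cand) == 1) return(cand)
  dd <- td[cand]
  if (all(is.na(dd))) return(NA_character_)
  nearest <- cand[which(dd == min(dd, na.rm = TRUE))]
  if (length(nearest) == 1) nearest else NA_character_
}

#' Zotus not represented by any matched isolate
#'
#' @param matches Result of [match_isolates()].
#' @return Character vector of Zotu ids.
#' @export
unmatched_zotus <- function(matches) {
  setdiff(attr(matches, "zotu_ids"),
          matches$zotu_id[matches$matched])
}

#' Enumerate isolate combinations representing a Zotu pair
#'
#' Given the representative isolate sets R(x) and R(y) of the two Zotus of
#' a pair, enumerates the unordered isolate combinations to co-culture:
#' all distinct unordered pairs {i, j} with i in R(x), j in R(y), i != j,
#' de-duplicated. A shared set of size m yields choose(m, 2) combinations;
#' disjoint sets yield |R(x)| x |R(y)|.
#'
#' @param zotu_x,zotu_y The two Zotu ids of the pair.
#' @param matches Result of [match_isolates()] (or any tibble with columns
#'   `isolate_id`, `zotu_id`, `matched`).
#' @return Tibble with `zotu_a`, `zotu_b`, `isolate_1`, `isolate_2`
#'   (`isolate_1 < isolate_2`).
#' @export
enumerate_combinations <- function(zotu_x, zotu_y, matches) {
  rep_set <- function(z) {
    s <- unique(matches$isolate_id[matches$matched &
                                     !is.na(matches$zotu_id) &
                                     matches$zotu_id == z])
    if (length(s) == 0) abort(paste0("no isolates represent Zotu '", z, "'"))
    s
  }
  rx <- rep_set(zotu_x); ry <- rep_set(zotu_y)
  combos <- tidyr::expand_grid(i = rx, j = ry) |>
    filter(.data$i != .data$j) |>
    mutate(isolate_1 = pmin(.data$i, .data$j),
           isolate_2 = pmax(.data$i, .data$j)) |>
    distinct(.data$isolate_1, .data$isolate_2)
  tibble(zotu_a = min(zotu_x, zotu_y), zotu_b = max(zotu_x, zotu_y),
         isolate_1 = combos$isolate_1, isolate_2 = combos$isolate_2)
}

#' Write an isolate-match table
#'
#' @param matches Result of [match_isolates()].
#' @param path Output TSV path.
#' @export
write_match_table <- function(matches, path) {
  readr::write_tsv(as_tibble(as.data.frame(matches)), path)
  invisible(path)
}
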