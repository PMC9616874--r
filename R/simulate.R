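# Synthetic community generator: dilution-series plate arrays with planted
# pairwise interactions, growth curves and reference sequences. This is the
# ground-truth scaffold that replaces raw sequencing data for every
# downstream stage.

#' Simulate a source community
#'
#' Draws a log-normal rank-abundance community standing in for a homogenized
#' plant / root / sediment sample before serial dilution.
#'
#' @param n_species Number of taxa (>= 2).
#' @param lognormal_mu,lognormal_sigma Parameters of the log-normal
#'   abundance draw (sigma = 0 gives a perfectly even community).
#' @param cells_per_ul Total cell density of the undiluted homogenate
#'   (cells per microlitre).
#' @param seed Optional integer seed; the same seed reproduces the community
#'   exactly.
#'
#' @return A tibble of class `source_community` with columns `species_id`
#'   and `abundance` (relative abundances summing to 1), carrying
#'   `cells_per_ul` as an attribute.
#' @examples
#' simulate_source(10, lognormal_sigma = 0, seed = 1)
#' @export
simulate_source <- function(n_species, lognormal_mu = 0, lognormal_sigma = 1,
                            cells_per_ul = 1e6, seed = NULL) {
  if (length(n_species) != 1 || is.na(n_species) || n_species < 2) {
    abort("`n_species` must be a single integer >= 2.")
  }
  if (lognormal_sigma < 0) abort("`lognormal_sigma` must be >= 0.")
  if (cells_per_ul <= 0) abort("`cells_per_ul` must be positive.")
  draw <- function() rlnorm(n_species, meanlog = lognormal_mu, sdlog = lognormal_sigma)
  raw <- if (is.null(seed)) draw() else with_seed(seed, draw())
  out <- tibble(
    species_id = sprintf("Zotu%03d", seq_len(n_species)),
    abundance = raw / sum(raw)
  )
  new_source_community(out, cells_per_ul)
}

new_source_community <- function(tbl, cells_per_ul) {
  stopifnot(abs(sum(tbl$abundance) - 1) < 1e-9, all(tbl$abundance >= 0),
            !anyDuplicated(tbl$species_id))
  structure(tbl, class = c("source_community", class(tibble())),
            cells_per_ul = cells_per_ul)
}

#' Total cell density of a source community
#' @param source A [simulate_source()] community.
#' @return Cells per microlitre of the undiluted homogenate.
#' @export
cells_per_ul <- function(source) attr(source, "cells_per_ul")

#' Declare ground-truth pairwise interactions
#'
#' Canonicalizes a table of planted taxon-pair interactions: pairs are
#' unordered (stored with `species_a < species_b`), unique, and never
#' self-pairs. `sign` is +1 (positive association) or -1 (negative);
#' `effect_size` scales the multiplicative share perturbation applied when
#' both partners are co-seeded in a well.
#'
#' @param pairs A data frame with columns `species_a`, `species_b`,
#'   `sign`, `effect_size`.
#' @return A tibble of class `interaction_truth`.
#' @export
interaction_truth <- function(pairs) {
  pairs <- as_tibble(pairs)
  need <- c("species_a", "species_b", "sign", "effect_size")
  if (!all(need %in% names(pairs))) {
    abort(paste("`pairs` needs columns:", paste(need, collapse = ", ")))
  }
  if (any(pairs$species_a == pairs$species_b)) abort("self-pairs are not allowed.")
  if (!all(pairs$sign %in% c(-1, 1))) abort("`sign` must be +1 or -1.")
  if (any(pairs$effect_size < 0)) abort("`effect_size` must be >= 0.")
  out <- pairs |>
    mutate(
      a = pmin(.data$species_a, .data$species_b),
      b = pmax(.data$species_a, .data$species_b),
      species_a = .data$a, species_b = .data$b
    ) |>
    select(all_of(need))
  if (anyDuplicated(paste(out$species_a, out$species_b))) {
    abort("duplicate pairs after canonicalization.")
  }
  structure(out, class = c("interaction_truth", class(tibble())))
}

#' Expected cells seeded per well
#'
#' The Poisson seeding rate of each taxon for a given plate design:
#' `cells_per_ul x inoculum_volume_ul x abundance x 10^-dilution_level`.
#' The total rate decays by exactly 10x per dilution level.
#'
#' @param source A [simulate_source()] community.
#' @param design A [plate_design()].
#' @return Tibble with `species_id` and `expected_cells`.
#' @export
expected_seeding <- function(source, design) {
  tibble(
    species_id = source$species_id,
    expected_cells = cells_per_ul(source) * design$inoculum_volume_ul *
      source$abundance * 10^(-design$dilution_level)
  )
}

#' Simulate one cultivation plate
#'
#' Seeds each well with Poisson numbers of cells of each taxon at the
#' dilution-scaled rate, grows the seeded taxa to a per-well equilibrium in
#' which each taxon's final share is its seeded share multiplied by
#' `exp(sign x effect_size)` for every co-seeded interaction partner
#' (renormalized), and draws multinomial read counts at `read_depth` for
#' occupied wells. Wells with zero seeded cells yield all-zero rows, which
#' are retained (growth scoring happens downstream).
#'
#' Positive interactions act on co-seeded wells only by default; setting
#' `co_colonization = TRUE` additionally correlates the seeding rates of
#' positively interacting partners through a shared per-well log-normal
#' factor, emulating co-colonization rather than in-well growth coupling.
#'
#' @param source A [simulate_source()] community.
#' @param design A [plate_design()].
#' @param truth Optional [interaction_truth()] of planted pairs.
#' @param read_depth Reads sequenced per occupied well (>= 0).
#' @param seed Optional integer seed (bit-identical tables for equal seeds).
#' @param co_colonization Correlate seeding of positive pairs (default off).
#' @param co_seed_sd Log-sd of the shared seeding factor when
#'   `co_colonization` is on.
#'
#' @return A `plate_tbl`: a tibble with a `well` column and one integer
#'   count column per taxon, carrying the design, plate id and per-well
#'   seeded-occupancy truth as attributes (see [plate_occupancy()]).
#' @examples
#' src <- simulate_source(10, lognormal_sigma = 0, seed = 1)
#' des <- plate_design("roots", "R2A", dilution_level = 4)
#' p <- simulate_plate(src, des, read_depth = 1000, seed = 1)
#' dim(p)
#' @export
simulate_plate <- function(source, design, truth = NULL, read_depth = 5000,
                           seed = NULL, co_colonization = FALSE,
                           co_seed_sd = 0.8) {
  if (read_depth < 0) abort("`read_depth` must be >= 0.")
  stopifnot(inherits(design, "plate_design"))
  lam <- expected_seeding(source, design)$expected_cells
  n_sp <- nrow(source)
  n_w <- design$n_wells
  sp <- source$species_id
  if (!is.null(truth)) {
    miss <- setdiff(c(truth$species_a, truth$species_b), sp)
    if (length(miss)) abort(paste("truth names unknown species:", paste(miss, collapse = ", ")))
  }

  body <- function() {
    lam_w <- matrix(lam, nrow = n_w, ncol = n_sp, byrow = TRUE)
    if (co_colonization && !is.null(truth) && nrow(truth)) {
      pos <- truth[truth$sign > 0, , drop = FALSE]
      for (i in seq_len(nrow(pos))) {
        f <- rlnorm(n_w, meanlog = -co_seed_sd^2 / 2, sdlog = co_seed_sd)
        ia <- match(pos$species_a[i], sp); ib <- match(pos$species_b[i], sp)
        lam_w[, ia] <- lam_w[, ia] * f
        lam_w[, ib] <- lam_w[, ib] * f
      }
    }
    seeded <- matrix(rpois(n_w * n_sp, lam_w), nrow = n_w, ncol = n_sp)
    w <- seeded * 1.0
    if (!is.null(truth) && nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        ia <- match(truth$species_a[i], sp); ib <- match(truth$species_b[i], sp)
        both <- seeded[, ia] > 0 & seeded[, ib] > 0
        mult <- exp(truth$sign[i] * truth$effect_size[i])
        w[both, ia] <- w[both, ia] * mult
        w[both, ib] <- w[both, ib] * mult
      }
    }
    counts <- matrix(0L, nrow = n_w, ncol = n_sp)
    occupied <- which(rowSums(seeded) > 0)
    for (i in occupied) {
      counts[i, ] <- as.integer(rmultinom(1, read_depth, w[i, ]))
    }
    list(seeded = seeded, counts = counts)
  }
  res <- if (is.null(seed)) body() else with_seed(seed, body())

  wells <- well_ids(n_w)
  tbl <- as_tibble(as.data.frame(res$counts, col.names = sp))
  names(tbl) <- sp
  tbl <- dplyr::bind_cols(tibble(well = wells), tbl)
  occupancy <- tibble(
    well = wells,
    seeded_cells = rowSums(res$seeded),
    seeded_species = rowSums(res$seeded > 0)
  )
  new_plate_tbl(tbl, plate_id = design_id(design), design = design,
                occupancy = occupancy)
}

new_plate_tbl <- function(tbl, plate_id, design, occupancy = NULL) {
  structure(tbl, class = c("plate_tbl", class(tibble())),
            plate_id = plate_id, design = design, occupancy = occupancy)
}

#' @rdname simulate_plate
#' @param plate A `plate_tbl`.
#' @export
plate_occupancy <- function(plate) attr(plate, "occupancy")

#' Plate accessors
#'
#' `plate_id()` returns the plate identifier; `plate_design_of()` the
#' [plate_design()]; `plate_counts()` the wells x taxa integer count matrix
#' (well ids as rownames); `zotu_ids()` the taxon column names.
#'
#' @param plate A `plate_tbl`.
#' @name plate-accessors
#' @export
plate_id <- function(plate) attr(plate, "plate_id")

#' @rdname plate-accessors
#' @export
plate_design_of <- function(plate) attr(plate, "design")

#' @rdname plate-accessors
#' @export
plate_counts <- function(plate) {
  m <- as.matrix(as.data.frame(plate)[, setdiff(names(plate), "well"), drop = FALSE])
  rownames(m) <- plate$well
  m
}

#' @rdname plate-accessors
#' @export
zotu_ids <- function(plate) setdiff(names(plate), "well")

#' Simulate a whole plate array
#'
#' One [simulate_plate()] per row of a design grid, with per-plate seeds
#' derived deterministically from `seed`.
#'
#' @param source A [simulate_source()] community.
#' @param designs A design grid as returned by [full_design()].
#' @param truth Optional [interaction_truth()].
#' @param read_depth Reads per occupied well.
#' @param seed Integer seed; plate `i` uses `seed + i`.
#' @param ... Passed on to [simulate_plate()].
#' @return A named list of `plate_tbl`s (names are plate ids).
#' @export
simulate_plate_array <- function(source, designs, truth = NULL,
                                 read_depth = 5000, seed = 1, ...) {
  plates <- vector("list", nrow(designs))
  for (i in seq_len(nrow(designs))) {
    d <- plate_design(
      sample_type = designs$sample_type[i], medium = designs$medium[i],
      dilution_level = designs$dilution_level[i],
      replicate = designs$replicate[i], n_wells = designs$n_wells[i]
    )
    plates[[i]] <- simulate_plate(source, d, truth = truth,
                                  read_depth = read_depth,
                                  seed = seed + i, ...)
  }
  names(plates) <- map_chr(plates, plate_id)
  plates
}

# ---- growth curves ---------------------------------------------------------

logistic_curve <- function(times, n0, r, K) {
  K * n0 * exp(r * times) / (K + n0 * (exp(r * times) - 1))
}

growth_defaults <- function() {
  list(
    times = seq(0, 48, by = 2), n0 = 1e5,
    r_a = 0.6, r_b = 0.5, K_a = 1e9, K_b = 8e8,
    k_up = 30, k_down = 1 / 30, noise_sd = 0.1,
    decline_start = Inf, decline_rate = 0
  )
}

#' Simulate mono- and co-culture growth curves for a labelled interaction
#'
#' Logistic growth for each partner in axenic culture; in co-culture the
#' carrying capacity is scaled by a label-specific interaction multiplier
#' (`k_up` for a benefitting partner, `k_down` for a harmed one, 1 for an
#' unaffected one). Optionally a post-peak exponential decline
#' (`decline_start`, `decline_rate`) emulates the biphasic
#' grow-then-crash trajectories seen in broth co-cultures. Multiplicative
#' log-normal noise (`noise_sd`, default 0.1) is applied pointwise.
#'
#' @param label One of `"neutralism"`, `"competition"`, `"mutualism"`,
#'   `"commensalism"`, `"amensalism"`, `"exploitation"`. Asymmetric labels
#'   read as the effect on partner a / partner b: commensalism = (+,0),
#'   amensalism = (-,0), exploitation = (+,-).
#' @param params Named list overriding any of the defaults
#'   (`times`, `n0`, `r_a`, `r_b`, `K_a`, `K_b`, `k_up`, `k_down`,
#'   `noise_sd`, `decline_start`, `decline_rate`).
#' @param seed Optional integer seed.
#' @return A tibble of class `growth_curve_set` with columns `time_h`,
#'   `series` (one of `mono_a`, `mono_b`, `co_a`, `co_b`) and `density`
#'   (cells/ml), carrying the true label as attribute `label`.
#' @examples
#' gc <- simulate_growth_curves("competition", params = list(noise_sd = 0), seed = 1)
#' @export
simulate_growth_curves <- function(label, params = list(), seed = NULL) {
  labs <- c("neutralism", "competition", "mutualism", "commensalism",
            "amensalism", "exploitation")
  if (!label %in% labs) {
    abort(paste0("unknown label '", label, "'; must be one of: ",
                 paste(labs, collapse = ", ")))
  }
  p <- utils::modifyList(growth_defaults(), params)
  if (p$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  mult <- switch(label,
    neutralism   = c(1, 1),
    competition  = c(p$k_down, p$k_down),
    mutualism    = c(p$k_up, p$k_up),
    commensalism = c(p$k_up, 1),
    amensalism   = c(p$k_down, 1),
    exploitation = c(p$k_up, p$k_down)
  )
  decline <- function(x, times) {
    late <- times > p$decline_start
    x[late] <- x[late] * exp(-p$decline_rate * (times[late] - p$decline_start))
    x
  }
  base <- list(
    mono_a = decline(logistic_curve(p$times, p$n0, p$r_a, p$K_a), p$times),
    mono_b = decline(logistic_curve(p$times, p$n0, p$r_b, p$K_b), p$times),
    co_a   = decline(logistic_curve(p$times, p$n0, p$r_a, p$K_a * mult[1]), p$times),
    co_b   = decline(logistic_curve(p$times, p$n0, p$r_b, p$K_b * mult[2]), p$times)
  )
  noisy <- function() {
    map(base, function(x) {
      if (p$noise_sd == 0) x else x * rlnorm(length(x), 0, p$noise_sd)
    })
  }
  vals <- if (is.null(seed)) noisy() else with_seed(seed, noisy())
  out <- map_dfr(names(vals), function(nm) {
    dens <- vals[[nm]]
    tibble(time_h = p$times, series = nm, density = dens)
  })
  structure(out, class = c("growth_curve_set", class(tibble())),
            label = label, params = p)
}

#' True label of a simulated growth-curve set
#' @param curves A [simulate_growth_curves()] result.
#' @export
curve_label <- function(curves) attr(curves, "label")

# ---- reference sequences ---------------------------------------------------

#' Simulate Zotu V4 sequences and isolate 16S sequences
#'
#' `simulate_zotu_seqs()` draws random V4-length amplicon sequences, one per
#' taxon. `simulate_isolate_seqs()` builds synthetic near-full-length 16S
#' sequences for cultured isolates by embedding a Zotu's V4 region between
#' the amplification primer sites with random flanking sequence, optionally
#' introducing point substitutions into the V4 region.
#'
#' @param species_ids Taxon labels.
#' @param v4_length Length of the simulated V4 region (nt).
#' @param seed Integer seed.
#' @return `simulate_zotu_seqs()`: tibble `id`, `sequence`.
#' @export
simulate_zotu_seqs <- function(species_ids, v4_length = 250, seed = 1) {
  draw <- function() {
    map_chr(seq_along(species_ids), function(i) {
      paste(sample(c("A", "C", "G", "T"), v4_length, replace = TRUE), collapse = "")
    })
  }
  tibble(id = species_ids, sequence = with_seed(seed, draw()))
}

#' @rdname simulate_zotu_seqs
#' @param zotu_seqs Result of `simulate_zotu_seqs()`.
#' @param n_per_zotu Isolates to generate per Zotu (recycled).
#' @param v4_mismatches Point substitutions introduced into each isolate's
#'   V4 copy (0 = isolates share an identical V4 with their Zotu).
#' @param flank Length of random sequence added outside each primer site.
#' @param fwd_primer,rev_primer Amplification primers (5'->3').
#' @return `simulate_isolate_seqs()`: tibble `id`, `zotu_id`, `sequence`.
#' @export
simulate_isolate_seqs <- function(zotu_seqs, n_per_zotu = 2, v4_mismatches = 0,
                                  flank = 120,
                                  fwd_primer = "GTGYCAGCMGCCGCGGTAA",
                                  rev_primer = "GGACTACNVGGGTWTCTAAT",
                                  seed = 1) {
  n_per <- rep_len(n_per_zotu, nrow(zotu_seqs))
  rc_rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev_primer)))
  # primers may carry IUPAC degeneracies; instantiate one concrete variant
  concrete <- function(s) {
    iupac <- list(R = c("A","G"), Y = c("C","T"), S = c("C","G"), W = c("A","T"),
                  K = c("G","T"), M = c("A","C"), B = c("C","G","T"),
                  D = c("A","G","T"), H = c("A","C","T"), V = c("A","C","G"),
                  N = c("A","C","G","T"))
    chars <- strsplit(s, "")[[1]]
    paste(map_chr(chars, function(ch) {
      if (ch %in% names(iupac)) sample(iupac[[ch]], 1) else ch
    }), collapse = "")
  }
  build <- function() {
    rows <- list()
    k <- 0
    for (i in seq_len(nrow(zotu_seqs))) {
      for (j in seq_len(n_per[i])) {
        k <- k + 1
        v4 <- zotu_seqs$sequence[i]
        if (v4_mismatches > 0) {
          pos <- sample(nchar(v4), v4_mismatches)
          ch <- strsplit(v4, "")[[1]]
          for (p in pos) ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
          v4 <- paste(ch, collapse = "")
        }
        fl <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")
        rows[[k]] <- tibble(
          id = sprintf("ISO-%03d", k),
          zotu_id = zotu_seqs$id[i],
          sequence = paste0(fl(flank), concrete(fwd_primer), v4,
                            concrete(rc_rev), fl(flank))
        )
      }
    }
    bind_rows(rows)
  }
  with_seed(seed, build())
}
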