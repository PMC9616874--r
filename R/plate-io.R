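# Reading/writing plate feature tables and the plate-level growth filter.

#' Write / read a plate feature table
#'
#' The on-disk format is a TSV whose first column `well` holds well ids and
#' whose remaining columns are integer read counts, one per Zotu, plus an
#' optional JSON sidecar recording the plate design. `read_plate_table()`
#' round-trips `write_plate_table()` bit-exactly.
#'
#' @param plate A `plate_tbl` (see [simulate_plate()]).
#' @param path TSV path.
#' @param sidecar_path Optional JSON path for the design metadata.
#' @return `write_plate_table()` returns `path` invisibly;
#'   `read_plate_table()` returns a `plate_tbl`.
#' @export
write_plate_table <- function(plate, path, sidecar_path = NULL) {
  readr::write_tsv(as_tibble(as.data.frame(plate)), path)
  if (!is.null(sidecar_path)) {
    d <- plate_design_of(plate)
    jsonlite::write_json(
      c(list(plate_id = plate_id(plate)), unclass(d)),
      sidecar_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_plate_table
#' @export
read_plate_table <- function(path, sidecar_path = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    well = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (nrow(tbl) == 0) abort("no wells: the plate table has zero rows.")
  if (!"well" %in% names(tbl)) abort("plate table must have a `well` column.")
  if (anyDuplicated(tbl$well)) {
    abort(paste("duplicate well id:", tbl$well[duplicated(tbl$well)][1]))
  }
  zcols <- setdiff(names(tbl), "well")
  if (anyDuplicated(zcols)) abort("duplicate Zotu column ids.")
  for (z in zcols) {
    v <- tbl[[z]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      abort(sprintf(
        "invalid count %s at well '%s', Zotu '%s': counts must be non-negative integers",
        format(v[bad[1]]), tbl$well[bad[1]], z
      ))
    }
    tbl[[z]] <- as.integer(v)
  }
  design <- NULL; pid <- basename(path)
  if (!is.null(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    design <- plate_design(
      sample_type = sc$sample_type, medium = sc$medium,
      dilution_level = sc$dilution_level, replicate = sc$replicate,
      n_wells = sc$n_wells, inoculum_volume_ul = sc$inoculum_volume_ul,
      well_volume_ul = sc$well_volume_ul
    )
    pid <- sc$plate_id
  }
  new_plate_tbl(tbl, plate_id = pid, design = design)
}

#' Score microbial growth per well
#'
#' A well "grew" iff its total read count reaches `min_reads`. This is the
#' in-silico proxy for the visual growth scoring used on real plates: only a
#' read-based criterion is available from a feature table.
#'
#' @param plate A `plate_tbl`.
#' @param min_reads Minimum total reads for a well to count as grown
#'   (default 100, >= 1).
#' @return A tibble with columns `well`, `total_reads`, `grew`. Raising
#'   `min_reads` can only switch wells from grown to not grown.
#' @export
detect_growth <- function(plate, min_reads = 100) {
  if (min_reads < 1) abort("`min_reads` must be >= 1.")
  totals <- rowSums(plate_counts(plate))
  tibble(well = plate$well, total_reads = unname(totals),
         grew = unname(totals) >= min_reads)
}

#' Retain effective plates
#'
#' A plate is effective when strictly more than `min_grow_frac` of its wells
#' show growth (default 30%, matching the study's "more than 30% of wells"
#' cutoff; 29/96 wells is retained, 28/96 is not). The denominator is the
#' plate's designed well count.
#'
#' @param plates A list of `plate_tbl`s.
#' @param min_reads Growth threshold per well (see [detect_growth()]).
#' @param min_grow_frac Strict lower bound on the grown-well fraction.
#' @return The retained subset of `plates`, original order preserved.
#' @export
effective_plates <- function(plates, min_reads = 100, min_grow_frac = 0.30) {
  if (min_grow_frac < 0 || min_grow_frac > 1) {
    abort("`min_grow_frac` must be in [0, 1].")
  }
  keep <- map_lgl(plates, function(p) {
    g <- detect_growth(p, min_reads = min_reads)
    sum(g$grew) / plate_design_of(p)$n_wells > min_grow_frac
  })
  plates[keep]
}

#' Growth summary across an array of plates
#'
#' @param plates A list of `plate_tbl`s.
#' @param min_reads Growth threshold per well.
#' @return Tibble with one row per plate: `plate_id`, `sample_type`,
#'   `medium`, `dilution_level`, `replicate`, `n_wells`, `n_grew`,
#'   `grow_frac`.
#' @export
growth_summary <- function(plates, min_reads = 100) {
  map_dfr(plates, function(p) {
    d <- plate_design_of(p)
    g <- detect_growth(p, min_reads = min_reads)
    tibble(
      plate_id = plate_id(p), sample_type = d$sample_type, medium = d$medium,
      dilution_level = d$dilution_level, replicate = d$replicate,
      n_wells = d$n_wells, n_grew = sum(g$grew),
      grow_frac = sum(g$grew) / d$n_wells
    )
  })
}

#' FASTA helpers
#'
#' Thin wrappers around Biostrings for the sequence tables used by the
#' isolate-matching stage (`id`, `sequence` tibbles).
#'
#' @param seqs Tibble with columns `id`, `sequence`.
#' @param path FASTA path.
#' @export
write_seq_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_seq_fasta
#' @export
read_seq_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = names(x), sequence = unname(as.character(x)))
}
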