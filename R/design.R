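#' Plate design metadata
#'
#' Describes one 96-well cultivation plate of the dilution-series array:
#' which sample type was homogenized, which broth it was diluted into, the
#' dilution level (a level of `d` means a 10^-d dilution of the source
#' homogenate), and the replicate letter. The study design crosses
#' 3 sample types x 7 dilution levels x 3 replicates x 2 media.
#'
#' @param sample_type One of `"plants"`, `"roots"`, `"sediments"`.
#' @param medium Cultivation broth, `"R2A"` or `"TSB"`.
#' @param dilution_level Integer in 1..7; the well inoculum is the source
#'   community diluted 10^-dilution_level.
#' @param replicate Replicate label, one of `"A"`, `"B"`, `"C"`.
#' @param n_wells Wells per plate (default 96).
#' @param inoculum_volume_ul Volume of diluted homogenate seeded per well
#'   (microlitres, default 1).
#' @param well_volume_ul Broth volume per well (microlitres, default 150).
#'
#' @return An object of class `plate_design` (a named list).
#' @examples
#' plate_design("roots", "R2A", dilution_level = 4)
#' @export
plate_design <- function(sample_type = c("plants", "roots", "sediments"),
                         medium = c("R2A", "TSB"),
                         dilution_level,
                         replicate = c("A", "B", "C"),
                         n_wells = 96,
                         inoculum_volume_ul = 1,
                         well_volume_ul = 150) {
  sample_type <- match.arg(sample_type)
  medium <- match.arg(medium)
  replicate <- match.arg(as.character(replicate), c("A", "B", "C"))
  if (length(dilution_level) != 1 || is.na(dilution_level) ||
      dilution_level != as.integer(dilution_level) ||
      dilution_level < 1 || dilution_level > 7) {
    abort("`dilution_level` must be a single integer in 1..7.")
  }
  if (length(n_wells) != 1 || is.na(n_wells) || n_wells < 1) {
    abort("`n_wells` must be >= 1.")
  }
  if (inoculum_volume_ul <= 0 || well_volume_ul <= 0) {
    abort("volumes must be positive.")
  }
  structure(
    list(
      sample_type = sample_type,
      medium = medium,
      dilution_level = as.integer(dilution_level),
      replicate = replicate,
      n_wells = as.integer(n_wells),
      inoculum_volume_ul = inoculum_volume_ul,
      well_volume_ul = well_volume_ul
    ),
    class = "plate_design"
  )
}

#' @export
print.plate_design <- function(x, ...) {
  cat(sprintf(
    "<plate_design> %s / %s, dilution 10^-%d, replicate %s, %d wells\n",
    x$sample_type, x$medium, x$dilution_level, x$replicate, x$n_wells
  ))
  invisible(x)
}

#' Identifier string for a plate design
#'
#' @param design A [plate_design()].
#' @return A single string, e.g. `"roots-R2A-d4-A"`.
#' @export
design_id <- function(design) {
  sprintf("%s-%s-d%d-%s", design$sample_type, design$medium,
          design$dilution_level, design$replicate)
}

#' Enumerate the full cultivation array design
#'
#' Expands the complete study design: 3 sample types x 7 dilution levels x
#' 3 replicates x 2 media = 126 plates of 96 wells (12,096 wells).
#'
#' @param sample_types,media,dilution_levels,replicates Factors of the design
#'   grid; defaults are the full study design.
#' @param n_wells Wells per plate.
#' @return A tibble with one row per plate and the design columns.
#' @examples
#' d <- full_design()
#' nrow(d)          # 126 plates
#' sum(d$n_wells)   # 12096 wells
#' @export
full_design <- function(sample_types = c("plants", "roots", "sediments"),
                        media = c("R2A", "TSB"),
                        dilution_levels = 1:7,
                        replicates = c("A", "B", "C"),
                        n_wells = 96) {
  tidyr::expand_grid(
    sample_type = sample_types,
    dilution_level = as.integer(dilution_levels),
    replicate = replicates,
    medium = media
  ) |>
    mutate(n_wells = as.integer(n_wells))
}

#' Well identifiers in fixed plate order
#'
#' 96-well plates use row-major microtitre coordinates A1..H12; other sizes
#' get a stable zero-padded ordering.
#'
#' @param n_wells Number of wells.
#' @return Character vector of well ids, length `n_wells`.
#' @export
well_ids <- function(n_wells) {
  if (n_wells == 96) {
    as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  } else {
    sprintf("W%0*d", max(3L, nchar(n_wells)), seq_len(n_wells))
  }
}
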