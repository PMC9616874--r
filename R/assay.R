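# qPCR quantification and interaction classification from mono- vs
# co-culture growth curves.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10 template copies over a dilution
#' series. The amplification efficiency is `E = 10^(-1/slope) - 1`, so the
#' canonical slope of -3.3219 (= -1/log10(2)) corresponds to 100%
#' efficiency (perfect doubling per cycle).
#'
#' @param data Data frame with columns `log10_copies` and `cq`, at least 3
#'   distinct dilution points.
#' @return An object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared`, `efficiency` and the calibrated `cq_range`.
#' @examples
#' std <- tibble::tibble(log10_copies = 1:6, cq = 38 - 3.3219 * (1:6))
#' glance(fit_standard_curve(std))
#' @export
fit_standard_curve <- function(data) {
  if (!all(c("log10_copies", "cq") %in% names(data))) {
    abort("`data` needs columns `log10_copies` and `cq`.")
  }
  if (any(!is.finite(data$cq)) || any(!is.finite(data$log10_copies))) {
    abort("`cq` and `log10_copies` must be finite.")
  }
  if (length(unique(data$log10_copies)) < 3) {
    abort("need >= 3 distinct dilution points.")
  }
  fit <- lm(cq ~ log10_copies, data = data)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  # R^2 computed directly; summary.lm() warns on an exact fit
  sst <- sum((data$cq - mean(data$cq))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(residuals(fit)^2) / sst
  structure(
    list(
      slope = slope, intercept = intercept,
      r_squared = r2,
      efficiency = 10^(-1 / slope) - 1,
      cq_range = range(data$cq), n_points = nrow(data)
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Cq = %.4f %+.4f * log10(copies); R^2 = %.4f, E = %.1f%%\n",
    x$intercept, x$slope, x$r_squared, 100 * x$efficiency
  ))
  invisible(x)
}

#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, efficiency = x$efficiency,
         n_points = x$n_points)
}

#' @export
autoplot.standard_curve <- function(object, ...) {
  xr <- (object$cq_range - object$intercept) / object$slope
  ggplot2::ggplot(tibble(log10_copies = xr,
                         cq = object$intercept + object$slope * xr),
                  ggplot2::aes(.data$log10_copies, .data$cq)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log10 copies", y = "Cq") +
    ggplot2::theme_minimal()
}

#' Absolute quantification from Cq values
#'
#' Inverts the standard curve, `copies = 10^((cq - intercept)/slope)`, and
#' converts gene copies to cell densities by dividing by the 16S rRNA gene
#' copy number of the target (`cells = copies / rrn_copies`). Cq values
#' outside the calibrated range are still converted but flagged with a
#' warning.
#'
#' @param data Data frame with a `cq` column (other columns pass through).
#' @param curve A [fit_standard_curve()] result.
#' @param rrn_copies 16S rRNA gene copies per genome (>= 1).
#' @return `data` with added columns `copies_per_ul`, `cells_per_ul` and
#'   `in_range`.
#' @export
quantify_cq <- function(data, curve, rrn_copies = 1) {
  if (!inherits(curve, "standard_curve")) abort("`curve` must be a standard_curve.")
  if (rrn_copies < 1) abort("`rrn_copies` must be >= 1.")
  if (!"cq" %in% names(data)) abort("`data` needs a `cq` column.")
  copies <- 10^((data$cq - curve$intercept) / curve$slope)
  in_range <- data$cq >= curve$cq_range[1] & data$cq <= curve$cq_range[2]
  if (any(!in_range)) {
    warn(sprintf("%d Cq value(s) outside the calibrated range [%.2f, %.2f].",
                 sum(!in_range), curve$cq_range[1], curve$cq_range[2]))
  }
  data |>
    mutate(copies_per_ul = copies,
           cells_per_ul = copies / rrn_copies,
           in_range = in_range)
}

#' Growth metrics over a time window
#'
#' The headline statistic is `auc_log`: the trapezoidal area under
#' log10(density) versus time within the window, after flooring zero
#' densities at `detection_limit`. Also reports the maximum and final
#' densities in the window.
#'
#' @param data Data frame with columns `time_h` and `density`.
#' @param window Numeric `c(start, end)` in hours; `NULL` uses the full
#'   time range. Points with `start <= time_h <= end` are used (>= 2
#'   required).
#' @param detection_limit Density floor applied before the log transform
#'   (default 1).
#' @return One-row tibble: `auc_log`, `max_density`, `end_density`,
#'   `window_start`, `window_end`.
#' @export
growth_metrics <- function(data, window = NULL, detection_limit = 1) {
  if (!all(c("time_h", "density") %in% names(data))) {
    abort("`data` needs columns `time_h` and `density`.")
  }
  if (any(data$density < 0)) abort("densities must be >= 0.")
  window <- window %||% range(data$time_h)
  d <- data |> filter(.data$time_h >= window[1], .data$time_h <= window[2]) |>
    arrange(.data$time_h)
  if (nrow(d) < 2) abort("empty window: need >= 2 time points inside it.")
  y <- log10(pmax(d$density, detection_limit))
  auc <- sum(diff(d$time_h) * (head(y, -1) + y[-1]) / 2)
  tibble(auc_log = auc, max_density = max(d$density),
         end_density = d$density[nrow(d)],
         window_start = window[1], window_end = window[2])
}

label_map <- function(ea, eb) {
  key <- paste(ea, eb)
  switch(key,
    "+ +" = "mutualism",
    "+ 0" = , "0 +" = "commensalism",
    "+ -" = , "- +" = "exploitation",
    "- 0" = , "0 -" = "amensalism",
    "- -" = "competition",
    "0 0" = "neutralism"
  )
}

#' Classify the interaction of an isolate pair
#'
#' For each time window, compares co-culture to mono-culture growth of each
#' partner by the difference in log-scale AUC,
#' `delta_x = auc_log(co_x) - auc_log(mono_x)`, thresholded at
#' `epsilon x window length` (epsilon in log10-units per hour, default
#' 0.2): the per-partner effect is `+`, `0` or `-`, and the pair label
#' follows the standard taxonomy: (+,+) mutualism, (+,0) commensalism,
#' (+,-) exploitation, (-,0) amensalism, (-,-) competition, (0,0)
#' neutralism. Windowed calls expose biphasic interactions (e.g. neutral
#' for the first 12 h, suppression afterwards). `collapse = TRUE` folds the
#' labels onto the three-way plate readout: any `-` effect is
#' "competitive", any remaining `+` is "mutual", else "neutral".
#'
#' @param curves A long data frame with columns `time_h`, `series`
#'   (`mono_a`, `mono_b`, `co_a`, `co_b`) and `density`; all four series
#'   must share the same time grid.
#' @param windows A list of `c(start, end)` windows (hours), or `NULL` for
#'   one full-range window. Windows must not overlap.
#' @param epsilon Effect threshold in log10-units per hour (default 0.2);
#'   reported with every call.
#' @param detection_limit Density floor for the log transform.
#' @param collapse Collapse the six labels to mutual/competitive/neutral.
#' @return A tibble with one row per window: `window_start`, `window_end`,
#'   `delta_a`, `delta_b`, `effect_a`, `effect_b`, `label`, `epsilon`.
#' @export
classify_interaction <- function(curves, windows = NULL, epsilon = 0.2,
                                 detection_limit = 1, collapse = FALSE) {
  need <- c("mono_a", "mono_b", "co_a", "co_b")
  ser <- split(as_tibble(as.data.frame(curves))[c("time_h", "density")],
               curves$series)
  if (!all(need %in% names(ser))) {
    abort(paste("`curves` must contain series:", paste(need, collapse = ", ")))
  }
  grids <- map(ser[need], function(s) sort(s$time_h))
  if (!all(map_lgl(grids[-1], function(g) identical(g, grids[[1]])))) {
    abort("mismatched time grids: all four series must share the same time points.")
  }
  windows <- windows %||% list(range(grids[[1]]))
  if (is.data.frame(windows)) {
    windows <- map(seq_len(nrow(windows)),
                   function(i) c(windows[[1]][i], windows[[2]][i]))
  }
  ws <- map_dbl(windows, 1); we <- map_dbl(windows, 2)
  ord <- order(ws)
  if (any(ws[ord][-1] < we[ord][-length(we)])) abort("windows must not overlap.")
  map_dfr(windows, function(w) {
    auc <- map_dbl(ser[need], function(s) {
      growth_metrics(s, window = w, detection_limit = detection_limit)$auc_log
    })
    delta_a <- auc[["co_a"]] - auc[["mono_a"]]
    delta_b <- auc[["co_b"]] - auc[["mono_b"]]
    thr <- epsilon * (w[2] - w[1])
    eff <- function(d) if (d > thr) "+" else if (d < -thr) "-" else "0"
    ea <- eff(delta_a); eb <- eff(delta_b)
    label <- label_map(ea, eb)
    if (collapse) {
      label <- if (ea == "-" || eb == "-") "competitive"
               else if (ea == "+" || eb == "+") "mutual" else "neutral"
    }
    tibble(window_start = w[1], window_end = w[2],
           delta_a = delta_a, delta_b = delta_b,
           effect_a = ea, effect_b = eb, label = label, epsilon = epsilon)
  })
}

#' Growth-curve autoplot
#'
#' Mono- and co-culture trajectories on a log10 density scale.
#'
#' @param object A `growth_curve_set`.
#' @param ... Unused.
#' @export
autoplot.growth_curve_set <- function(object, ...) {
  as_tibble(as.data.frame(object)) |>
    tidyr::separate_wider_delim("series", "_", names = c("culture", "partner")) |>
    ggplot2::ggplot(ggplot2::aes(.data$time_h, pmax(.data$density, 1),
                                 colour = .data$partner,
                                 linetype = .data$culture)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "density (cells/ml)") +
    ggplot2::theme_minimal()
}

#' Write interaction calls
#'
#' @param calls Output of [classify_interaction()] (optionally with a pair
#'   id column added).
#' @param path Output TSV path.
#' @export
write_interaction_calls <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}
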