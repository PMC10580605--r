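#' Severity class labels, from healthy to very severely lodged
#'
#' The six classes, totally ordered: `H` (healthy, score exactly 0),
#' `Upright` (0, 0.05], `LL` low (0.05, 0.15], `ML` moderate (0.15, 0.30],
#' `SL` severe (0.30, 0.60], `VSL` very severe (0.60, 1.0]. The intervals
#' are contiguous and right-closed; the field protocol prints class bounds
#' to two decimals, which would leave small gaps, so the lower bound of
#' each class is taken to be the upper bound of the class below.
#'
#' @format character vector of length 6 in increasing severity order.
#' @export
severity_levels <- c("H", "Upright", "LL", "ML", "SL", "VSL")

# right-closed upper bounds of the non-healthy classes, in class order
.severity_breaks <- c(0, 0.05, 0.15, 0.30, 0.60, 1.0)

#' Crop angle of inclination from a plumb-bob height pair
#'
#' The plumb bob gives the vertical height `hv` of a bent stem; the slant
#' height `hsl` is the stem length along its axis. The angle of inclination
#' from the vertical is `90 - asin(hv / hsl)` in degrees: an upright stem
#' (`hv == hsl`) scores 0 degrees, a flat stem (`hv == 0`) scores 90.
#'
#' Ratios marginally above 1 (within 1e-9, i.e. measurement noise at the
#' last digit) are clamped to 1; larger violations are an error because
#' a vertical height genuinely above the slant height is geometrically
#' impossible and indicates a recording mistake.
#'
#' @param hv numeric vector of vertical heights, same unit as `hsl`, >= 0.
#' @param hsl numeric vector of slant heights, > 0.
#' @return numeric vector of angles in degrees, in \[0, 90\].
#' @examples
#' cai_from_plumb(0.5, 1)   # 60 degrees
#' cai_from_plumb(1, 1)     # upright: 0 degrees
#' @export
cai_from_plumb <- function(hv, hsl) {
  if (!is.numeric(hv) || !is.numeric(hsl)) {
    stop("`hv` and `hsl` must be numeric", call. = FALSE)
  }
  if (length(hv) != length(hsl)) {
    stop("`hv` and `hsl` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(hv)) || any(!is.finite(hsl))) {
    stop("heights must be finite", call. = FALSE)
  }
  if (any(hsl <= 0)) stop("slant height `hsl` must be positive", call. = FALSE)
  if (any(hv < 0)) stop("vertical height `hv` must be non-negative", call. = FALSE)
  ratio <- hv / hsl
  over <- ratio > 1
  if (any(ratio[over] > 1 + 1e-9)) {
    stop("measurement inconsistency: vertical height exceeds slant height",
         call. = FALSE)
  }
  ratio[over] <- 1
  90 - asin(ratio) * 180 / pi
}

#' Plot lodged area from the four-quadrant visual protocol
#'
#' Each quadrant value is the lodged area contributed by that quadrant as a
#' percentage of the whole plot (so each lies in \[0, 25\] and the four sum
#' to at most 100). The plot lodged area is their sum, clamped to
#' \[0, 100\] against accumulated rounding.
#'
#' @param q1,q2,q3,q4 numeric vectors, per-quadrant lodged-area
#'   contributions in percent of plot area, each in \[0, 25\].
#' @return numeric vector, plot lodged area in percent.
#' @export
aggregate_quadrant_la <- function(q1, q2, q3, q4) {
  q <- cbind(q1, q2, q3, q4)
  if (!is.numeric(q) || any(!is.finite(q))) {
    stop("quadrant values must be finite numerics", call. = FALSE)
  }
  if (any(q < 0) || any(q > 25)) {
    stop("each quadrant lodged-area value must lie in [0, 25]", call. = FALSE)
  }
  pmin(pmax(rowSums(q), 0), 100)
}

#' Plot-level crop angle of inclination from lodged subplots
#'
#' Unweighted arithmetic mean of the per-subplot angles. Lodged plots carry
#' 4-8 lodged subplots; a healthy plot has none, in which case the caller
#' should take the plot angle to be 0 (see [assess_plot()]).
#'
#' @param angles numeric vector of subplot angles in degrees, each in
#'   \[0, 90\]; may be empty.
#' @return mean angle in degrees, or `NA_real_` with class attribute when
#'   `angles` is empty (no lodged subplots to average).
#' @export
aggregate_subplot_cai <- function(angles) {
  if (length(angles) == 0L) return(NA_real_)
  if (!is.numeric(angles) || any(!is.finite(angles))) {
    stop("subplot angles must be finite numerics", call. = FALSE)
  }
  if (any(angles < 0) || any(angles > 90)) {
    stop("subplot angles must lie in [0, 90] degrees", call. = FALSE)
  }
  mean(angles)
}

#' Normalized lodging score index
#'
#' `LS = (LA / 100) * (CAI / 90)`: the product of the lodged-area fraction
#' and the normalized angle of inclination. Zero iff either factor is zero;
#' one iff the plot is fully lodged (100%) and fully flat (90 degrees).
#'
#' @param la_pct numeric vector, lodged area in percent, \[0, 100\].
#' @param cai_deg numeric vector, crop angle of inclination in degrees,
#'   \[0, 90\].
#' @return numeric vector of scores in \[0, 1\].
#' @examples
#' lodging_score(50, 45)  # 0.25
#' @export
lodging_score <- function(la_pct, cai_deg) {
  if (!is.numeric(la_pct) || !is.numeric(cai_deg) ||
      any(!is.finite(la_pct)) || any(!is.finite(cai_deg))) {
    stop("inputs must be finite numerics", call. = FALSE)
  }
  if (any(la_pct < 0) || any(la_pct > 100)) {
    stop("`la_pct` must lie in [0, 100]", call. = FALSE)
  }
  if (any(cai_deg < 0) || any(cai_deg > 90)) {
    stop("`cai_deg` must lie in [0, 90]", call. = FALSE)
  }
  (la_pct / 100) * (cai_deg / 90)
}

#' Severity class of a lodging score
#'
#' Maps each score in \[0, 1\] to exactly one of the six classes (see
#' [severity_levels]): `H` for a score of exactly 0, then right-closed
#' intervals up to `VSL` at (0.60, 1.0].
#'
#' @param ls numeric vector of lodging scores in \[0, 1\].
#' @return ordered factor with levels `severity_levels`.
#' @export
classify_severity <- function(ls) {
  if (!is.numeric(ls) || any(!is.finite(ls))) {
    stop("`ls` must be finite numeric", call. = FALSE)
  }
  if (any(ls < 0) || any(ls > 1)) {
    stop("lodging score must lie in [0, 1]", call. = FALSE)
  }
  idx <- findInterval(ls, .severity_breaks, left.open = TRUE) + 1L
  # findInterval with left.open gives 0 for ls == 0 -> class 1 (H)
  factor(severity_levels[idx], levels = severity_levels, ordered = TRUE)
}

#' Full assessment of one plot from field-protocol measurements
#'
#' Composes the quadrant lodged-area sum, the subplot angle mean (0 when the
#' plot has no lodged subplots), the lodging score, and the severity class
#' into one record.
#'
#' @param quadrants numeric vector of length 4, per-quadrant lodged-area
#'   contributions in percent of plot area.
#' @param subplot_angles numeric vector of lodged-subplot angles in degrees;
#'   empty for a healthy plot.
#' @return a one-row data.frame with columns `la_pct`, `cai_deg`, `ls`,
#'   `severity`.
#' @export
assess_plot <- function(quadrants, subplot_angles = numeric()) {
  if (length(quadrants) != 4L) {
    stop("`quadrants` must have exactly four values", call. = FALSE)
  }
  la <- aggregate_quadrant_la(quadrants[1], quadrants[2], quadrants[3],
                              quadrants[4])
  cai <- aggregate_subplot_cai(subplot_angles)
  if (is.na(cai)) cai <- 0  # healthy plot: no lodged subplots
  ls <- lodging_score(la, cai)
  data.frame(la_pct = la, cai_deg = cai, ls = ls,
             severity = classify_severity(ls))
}

#' Read a plot-measurement CSV
#'
#' One row per plot. Required columns: `plot_id`, `genotype`, `q1`..`q4`
#' (per-quadrant lodged area, percent of plot). Subplot measurements come in
#' one of two forms: a `subplots` column of semicolon-separated `hv/hsl`
#' pairs (e.g. `"0.52/1.00;0.48/0.95"`), or an `angles` column of
#' semicolon-separated pre-computed angles in degrees. Either column may be
#' empty for a healthy plot.
#'
#' @param path path to a UTF-8 CSV with a header row.
#' @return data.frame with columns `plot_id`, `genotype`, `q1`..`q4` and a
#'   list-column `subplot_angles` of numeric vectors.
#' @export
read_plot_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("plot_id", "genotype", "q1", "q2", "q3", "q4")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("plot CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  parse_field <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(numeric())
    strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  }
  if ("angles" %in% names(df)) {
    ang <- lapply(df$angles, function(s) as.numeric(parse_field(s)))
  } else if ("subplots" %in% names(df)) {
    ang <- lapply(df$subplots, function(s) {
      toks <- parse_field(s)
      if (!length(toks)) return(numeric())
      pairs <- do.call(rbind, strsplit(toks, "/", fixed = TRUE))
      if (ncol(pairs) != 2L) {
        stop("malformed `subplots` field: expected hv/hsl pairs",
             call. = FALSE)
      }
      cai_from_plumb(as.numeric(pairs[, 1]), as.numeric(pairs[, 2]))
    })
  } else {
    stop("plot CSV must contain an `angles` or `subplots` column",
         call. = FALSE)
  }
  out <- df[need]
  out$subplot_angles <- ang
  out
}

#' Score every plot of a measurement table
#'
#' @param plots data.frame as returned by [read_plot_csv()].
#' @return the input with appended columns `la_pct`, `cai_deg`, `ls`,
#'   `severity` (list-column of angles dropped).
#' @export
score_plots <- function(plots) {
  need <- c("plot_id", "genotype", "q1", "q2", "q3", "q4", "subplot_angles")
  missing <- setdiff(need, names(plots))
  if (length(missing)) {
    stop("plot table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  res <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    assess_plot(as.numeric(plots[i, c("q1", "q2", "q3", "q4")]),
                plots$subplot_angles[[i]])
  }))
  cbind(plots[c("plot_id", "genotype", "q1", "q2", "q3", "q4")], res)
}

#' Write a scored plot table to CSV
#'
#' @param scored data.frame from [score_plots()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_csv <- function(scored, path) {
  out <- scored
  out$severity <- as.character(out$severity)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
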