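# Fermentation time-course analytics: growth rates, consumption rates,
# yields, lipid-free biomass and nutrient-limitation onsets.

#' Construct (and validate) a fermentation time series
#'
#' @param df Data frame with a strictly increasing `time` column (hours)
#'   and any of `biomass`, `glucose`, `glycerol`, `citrate`,
#'   `lipid_fraction`, `ammonium` (g/L; lipid fraction as proportion of
#'   dry cell weight).
#' @return The data frame with class `fermentation_ts`.
#' @export
fermentation_time_series <- function(df) {
  stopifnot(is.data.frame(df), "time" %in% names(df))
  if (any(diff(df$time) <= 0)) stop("time must be strictly increasing")
  conc_cols <- intersect(names(df), c("biomass", "glucose", "glycerol",
                                      "citrate", "ammonium"))
  for (col in conc_cols)
    if (any(df[[col]] < 0, na.rm = TRUE)) stop("negative concentrations in ", col)
  if ("lipid_fraction" %in% names(df) &&
      any(df$lipid_fraction < 0 | df$lipid_fraction > 1, na.rm = TRUE))
    stop("lipid_fraction must lie in [0, 1]")
  class(df) <- c("fermentation_ts", "data.frame")
  df
}

#' Read a fermentation time series from a delimited text file
#'
#' @param path Path to a file with a header line
#'   (`time,biomass,glucose,...`); comma or tab delimited.
#' @return A [fermentation_time_series()].
#' @export
read_time_series <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  fermentation_time_series(utils::read.delim(path, sep = sep))
}

window_slopes <- function(time, y, width) {
  n <- length(time)
  if (n < width) return(numeric(0))
  vapply(seq_len(n - width + 1), function(i) {
    idx <- i:(i + width - 1)
    unname(stats::coef(stats::lm(y[idx] ~ time[idx]))[2])
  }, 0)
}

#' Maximum specific growth rate from a time course
#'
#' Least-squares slope of `ln(biomass)` against time.  With an explicit
#' `window` the slope over that interval is returned; otherwise the maximum
#' over sliding windows of `width` consecutive samples (the log-phase
#' estimate).
#'
#' @param ts A `fermentation_ts`.
#' @param window Optional `c(t0, t1)` time interval (hours).
#' @param width Sliding-window width in samples (default 3).
#' @return Specific growth rate in 1/h.
#' @export
specific_growth_rate <- function(ts, window = NULL, width = 3) {
  keep <- if (is.null(window)) rep(TRUE, nrow(ts))
  else ts$time >= window[1] & ts$time <= window[2]
  t <- ts$time[keep]; x <- ts$biomass[keep]
  if (length(t) < 3) stop("need at least 3 points for a growth-rate fit")
  if (any(x <= 0)) stop("nonpositive biomass in the fitted window")
  lx <- log(x)
  if (!is.null(window)) return(unname(stats::coef(stats::lm(lx ~ t))[2]))
  max(window_slopes(t, lx, width))
}

#' Substrate consumption rate over a phase
#'
#' Negative least-squares slope of the substrate concentration against
#' time, reported positive.  When `phase` is omitted, the pre-depletion
#' phase is used: all samples up to the last one with concentration above
#' `floor`.  An increasing substrate yields rate 0 with attribute
#' `warning = "substrate increasing"`.
#'
#' @param ts A `fermentation_ts`.
#' @param substrate Column name (`"glucose"`, `"glycerol"`, ...).
#' @param phase Optional `c(t0, t1)` interval (hours).
#' @param floor Depletion floor in g/L (default 0.05).
#' @return Consumption rate in g/L/h.
#' @export
consumption_rate <- function(ts, substrate, phase = NULL, floor = 0.05) {
  if (!substrate %in% names(ts)) stop("no column '", substrate, "' in time series")
  y <- ts[[substrate]]
  keep <- if (!is.null(phase)) ts$time >= phase[1] & ts$time <= phase[2]
  else {
    above <- which(y > floor)
    if (length(above) == 0) return(structure(0, warning = "substrate depleted"))
    seq_len(nrow(ts)) <= max(above)
  }
  t <- ts$time[keep]; y <- y[keep]
  if (length(t) < 2 || all(y == y[1])) return(0)
  slope <- unname(stats::coef(stats::lm(y ~ t))[2])
  if (slope > 0) return(structure(0, warning = "substrate increasing"))
  -slope
}

#' Citrate yield on consumed substrate
#'
#' `citrate_produced / sum(substrates_consumed)`, in g citrate per g
#' substrate.  Full precision is returned; round to 2 decimals for
#' table-style reporting.
#'
#' @param citrate_produced Citrate produced (g/L).
#' @param substrates_consumed Named or unnamed numeric vector of consumed
#'   substrate amounts (g/L).
#' @return Yield (g/g).
#' @export
yield_citrate <- function(citrate_produced, substrates_consumed) {
  total <- sum(substrates_consumed)
  if (total <= 0) stop("total substrate consumption must be positive")
  citrate_produced / total
}

#' Lipid-free biomass
#'
#' Total biomass minus the stored-lipid mass: `total * (1 - fraction)`.
#'
#' @param total_biomass Biomass concentration (g/L).
#' @param lipid_fraction Lipid fraction of dry cell weight, in `[0, 1]`.
#' @return Lipid-free biomass (g/L).
#' @export
lipid_free_biomass <- function(total_biomass, lipid_fraction) {
  if (any(lipid_fraction < 0 | lipid_fraction > 1))
    stop("lipid_fraction must lie in [0, 1]")
  total_biomass * (1 - lipid_fraction)
}

#' Onset of a nutrient limitation
#'
#' First time the nutrient concentration falls below `threshold`, linearly
#' interpolated between samples; `NA` if it never does.
#'
#' @param ts A `fermentation_ts`.
#' @param nutrient Column name.
#' @param threshold Limitation threshold (g/L).
#' @return Onset time in hours, or `NA_real_`.
#' @export
detect_limitation <- function(ts, nutrient, threshold) {
  if (!nutrient %in% names(ts)) stop("no column '", nutrient, "' in time series")
  y <- ts[[nutrient]]; t <- ts$time
  below <- which(y < threshold)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(t[1])
  # linear interpolation on the bracketing segment
  t[i - 1] + (y[i - 1] - threshold) / (y[i - 1] - y[i]) * (t[i] - t[i - 1])
}

#' Summarize fermentation kinetics
#'
#' Convenience wrapper assembling the log-phase growth rate, substrate
#' consumption rates, citrate titer and yield, maximum lipid fraction,
#' final lipid-free biomass and limitation onsets from a time course.
#'
#' @param ts A `fermentation_ts`.
#' @param substrates Substrate columns to report (default: those present).
#' @param limitation_threshold Threshold used for onset detection (g/L).
#' @return A list of class `kinetics_summary`; rates and yields rounded to
#'   2 decimals in the printed report, full precision in the list.
#' @export
kinetics_summary <- function(ts, substrates = intersect(c("glucose", "glycerol"),
                                                        names(ts)),
                             limitation_threshold = 0.05) {
  consumed <- vapply(substrates, function(s) max(ts[[s]]) - min(ts[[s]]), 0)
  titer <- if ("citrate" %in% names(ts)) max(ts$citrate) else NA_real_
  res <- list(
    mu_max = specific_growth_rate(ts),
    consumption_rates = vapply(substrates, function(s) as.numeric(consumption_rate(ts, s)), 0),
    citrate_titer = titer,
    yield_citrate = if (!is.na(titer) && sum(consumed) > 0)
      yield_citrate(titer, consumed) else NA_real_,
    lipid_max_fraction = if ("lipid_fraction" %in% names(ts))
      max(ts$lipid_fraction) else NA_real_,
    lipid_free_biomass = if (all(c("biomass", "lipid_fraction") %in% names(ts)))
      lipid_free_biomass(ts$biomass[nrow(ts)], ts$lipid_fraction[nrow(ts)])
    else NA_real_,
    limitation_onsets = vapply(intersect(c(substrates, "ammonium"), names(ts)),
                               function(s) detect_limitation(ts, s, limitation_threshold), 0))
  class(res) <- "kinetics_summary"
  res
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat("<kinetics_summary>\n")
  cat(sprintf("  mu_max            %.2f 1/h\n", x$mu_max))
  for (s in names(x$consumption_rates))
    cat(sprintf("  %-8s consumed %.2f g/L/h\n", s, x$consumption_rates[[s]]))
  if (!is.na(x$citrate_titer))
    cat(sprintf("  citrate titer     %.1f g/L (yield %.2f g/g)\n",
                x$citrate_titer, x$yield_citrate))
  invisible(x)
}
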