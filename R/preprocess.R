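#' @title Pre-processing of fed-batch culture measurements
#' @name preprocess
#' @description
#' Converts sampled offline measurements (metabolite concentrations, viable
#' cell density, viability, titer) into cell-specific rates: outlier screening
#' on a moving-median trend, LOWESS smoothing, and a fed-batch mass balance
#' that corrects for continuous feed and bolus additions.
NULL

#' Construct a culture time series
#'
#' @param time sampling times \[h\], strictly increasing.
#' @param concentrations data frame or named list of per-metabolite
#'   concentration series \[mmol/L\], each the length of `time`.
#' @param vcd viable cell density \[cells/L\].
#' @param viability fraction in \[0, 1\].
#' @param titer product concentration \[mg/L\].
#' @param volume reactor volume \[L\].
#' @param feed a `feed_schedule` (see [feed_schedule()]), or `NULL` for batch.
#' @return object of class `culture_timeseries`.
#' @export
culture_timeseries <- function(time, concentrations, vcd, viability, titer,
                               volume, feed = NULL) {
  n <- length(time)
  if (n < 2L || any(diff(time) <= 0)) stop("time must be strictly increasing")
  concentrations <- as.data.frame(concentrations)
  if (nrow(concentrations) != n) stop("concentration series length mismatch")
  for (nm in c("vcd", "viability", "titer", "volume"))
    if (length(get(nm)) != n) stop(nm, " length mismatch")
  if (any(vcd < 0)) stop("vcd must be non-negative")
  if (any(viability < 0 | viability > 1)) stop("viability must lie in [0, 1]")
  if (any(volume <= 0)) stop("volume must be positive")
  structure(list(time = as.numeric(time), concentrations = concentrations,
                 vcd = as.numeric(vcd), viability = as.numeric(viability),
                 titer = as.numeric(titer), volume = as.numeric(volume),
                 feed = feed),
            class = "culture_timeseries")
}

#' @export
print.culture_timeseries <- function(x, ...) {
  cat("<culture_timeseries> ", length(x$time), " samples over ",
      round(max(x$time) / 24, 1), " days; variables: ",
      paste(names(x$concentrations), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write a culture time series as tidy CSV
#'
#' Long format with columns `time_h`, `variable`, `value`, `unit`. The
#' variables `vcd`, `viability`, `titer` and `volume` are reserved; all other
#' variables are treated as metabolite concentrations.
#'
#' @param series a `culture_timeseries`.
#' @param path CSV file path.
#' @export
write_culture_csv <- function(series, path) {
  units <- c(vcd = "cells/L", viability = "fraction", titer = "mg/L",
             volume = "L")
  rows <- list()
  add <- function(var, val, unit) {
    rows[[length(rows) + 1L]] <<- data.frame(time_h = series$time,
                                             variable = var, value = val,
                                             unit = unit)
  }
  for (nm in names(series$concentrations))
    add(nm, series$concentrations[[nm]], "mmol/L")
  for (nm in names(units)) add(nm, series[[nm]], units[[nm]])
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(series)
}

#' @rdname write_culture_csv
#' @param feed optional `feed_schedule` to attach on read.
#' @export
read_culture_csv <- function(path, feed = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reserved <- c("vcd", "viability", "titer", "volume")
  tt <- sort(unique(df$time_h))
  get <- function(var) {
    sub <- df[df$variable == var, ]
    sub$value[match(tt, sub$time_h)]
  }
  mets <- setdiff(unique(df$variable), reserved)
  conc <- as.data.frame(lapply(stats::setNames(mets, mets), get))
  culture_timeseries(tt, conc, get("vcd"), get("viability"), get("titer"),
                     get("volume"), feed = feed)
}

#' Moving-median / MAD outlier screen
#'
#' Flags points whose residual from a centred moving-median trend exceeds
#' `z_max` robust standard deviations (MAD scaled by 1.4826) and replaces them
#' by linear interpolation from the neighbouring retained points. Designed for
#' short daily-sampled series where a single analytical failure shows up as an
#' isolated spike.
#'
#' @param series a `culture_timeseries`, or a numeric vector.
#' @param z_max threshold in robust SDs (default 4).
#' @param window moving-median half-width in points (default 2, i.e. 5-point
#'   windows).
#' @return same type as `series`; for a `culture_timeseries` the attribute
#'   `n_replaced` counts replacements per variable.
#' @export
remove_outliers <- function(series, z_max = 4, window = 2L) {
  if (is.numeric(series)) return(screen_vector(series, z_max, window)$x)
  stopifnot(inherits(series, "culture_timeseries"))
  if (length(series$time) < 5L) stop("series too short for outlier screening")
  counts <- integer(0)
  for (nm in names(series$concentrations)) {
    sc <- screen_vector(series$concentrations[[nm]], z_max, window)
    series$concentrations[[nm]] <- sc$x
    counts[nm] <- sc$n
  }
  for (nm in c("vcd", "titer")) {
    sc <- screen_vector(series[[nm]], z_max, window)
    series[[nm]] <- sc$x
    counts[nm] <- sc$n
  }
  attr(series, "n_replaced") <- counts
  series
}

#' @keywords internal
screen_vector <- function(x, z_max, window) {
  n <- length(x)
  if (n < 5L) stop("series too short for outlier screening")
  med <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - window):min(n, i + window)
    stats::median(x[idx])
  }, numeric(1))
  resid <- x - med
  s <- stats::mad(resid)
  if (s < .Machine$double.eps) return(list(x = x, n = 0L))
  bad <- which(abs(resid) > z_max * s)
  if (!length(bad)) return(list(x = x, n = 0L))
  good <- setdiff(seq_len(n), bad)
  x[bad] <- stats::approx(good, x[good], xout = bad, rule = 2)$y
  list(x = x, n = length(bad))
}

#' LOWESS smoothing at the observation times
#'
#' Locally weighted linear regression with tricube weights (the classic
#' scatterplot smoother), one pass, no robustness iterations — appropriate for
#' the short, already outlier-screened series produced by daily sampling.
#' Wraps [stats::lowess()].
#'
#' @param time,value observation pairs (time need not be equally spaced).
#' @param frac span: fraction of points in each local window, in (0, 1\].
#' @return numeric vector of smoothed values at `time`.
#' @export
smooth_lowess <- function(time, value, frac = 0.5) {
  n <- length(time)
  if (n < 3L) stop("need at least 3 points")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  if (floor(frac * n) < 2L) stop("frac so small a window has < 2 points")
  out <- stats::lowess(time, value, f = frac, iter = 0)
  # lowess sorts by x; map back (time is strictly increasing in our use)
  out$y[match(time, out$x)]
}

#' Smooth all series of a culture time series
#'
#' @param series a `culture_timeseries`.
#' @param frac LOWESS span (default 0.5).
#' @return smoothed `culture_timeseries`.
#' @export
smooth_culture <- function(series, frac = 0.5) {
  stopifnot(inherits(series, "culture_timeseries"))
  for (nm in names(series$concentrations))
    series$concentrations[[nm]] <-
      pmax(smooth_lowess(series$time, series$concentrations[[nm]], frac), 0)
  series$vcd <- pmax(smooth_lowess(series$time, series$vcd, frac), 0)
  series$titer <- pmax(smooth_lowess(series$time, series$titer, frac), 0)
  series
}

#' Convert concentrations to cell-specific rates
#'
#' Per sampling interval, the specific rate of metabolite i is
#' \deqn{q_i = \frac{\Delta(C_i V) - \int F C_{feed,i} dt - \sum boluses_i}
#'            {\bar{X}_{dw} \bar{V} \, \Delta t}}
#' i.e. the change of amount corrected for continuous feed and bolus input,
#' normalised by the mean biomass dry weight in the interval. Negative rates
#' denote consumption. The specific growth rate is
#' \eqn{\mu = \Delta \ln(X V) / \Delta t} (dilution-free, since total cells
#' are used) and specific productivity analogously from the titer amount.
#' Interval values are assigned to interval midpoints.
#'
#' @param series a smoothed `culture_timeseries` (see [smooth_culture()]).
#' @param dw_per_cell cell dry weight \[g/cell\], default 250 pg.
#' @return object of class `specific_flux_series`: data frame `q` of rates
#'   \[µmol/g_DW/h\] at midpoint times, plus `mu` \[1/h\] and `qp`
#'   \[mg/g_DW/h\].
#' @export
concentrations_to_fluxes <- function(series, dw_per_cell = 250e-12) {
  stopifnot(inherits(series, "culture_timeseries"))
  tt <- series$time
  n <- length(tt)
  V <- series$volume
  Xdw <- series$vcd * dw_per_cell            # g_DW / L
  if (any(Xdw[-n] + Xdw[-1] <= 0)) stop("zero biomass in an interval")
  dt <- diff(tt)
  tm <- (tt[-n] + tt[-1]) / 2
  Vm <- (V[-n] + V[-1]) / 2
  Xm <- (Xdw[-n] + Xdw[-1]) / 2
  fs <- series$feed
  q <- data.frame(row.names = seq_len(n - 1L))
  for (nm in names(series$concentrations)) {
    Ci <- series$concentrations[[nm]]
    amt <- Ci * V                             # mmol
    fed <- feed_input(fs, nm, tt)             # mmol fed per interval
    dq <- (diff(amt) - fed) / (Xm * Vm * dt)  # mmol/g_DW/h
    q[[nm]] <- dq * 1000                      # µmol/g_DW/h
  }
  totX <- Xdw * V
  mu <- diff(log(pmax(totX, 1e-300))) / dt
  totP <- series$titer * V
  qp <- diff(totP) / (Xm * Vm * dt)           # mg/g_DW/h
  structure(list(time = tm, q = q, mu = mu, qp = qp),
            class = "specific_flux_series")
}

#' Amount of metabolite added by the feed in each sampling interval
#' @keywords internal
feed_input <- function(feed, metabolite, time) {
  n <- length(time)
  out <- numeric(n - 1L)
  if (is.null(feed)) return(out)
  cf <- feed$continuous$composition
  crate <- feed$continuous$rate
  conc <- if (!is.null(cf) && metabolite %in% names(cf)) cf[[metabolite]] else 0
  out <- out + crate * conc * diff(time)
  bl <- feed$boluses
  if (!is.null(bl) && nrow(bl)) {
    for (k in seq_len(nrow(bl))) {
      ci <- bolus_concentration(bl, k, metabolite)
      if (ci == 0) next
      # samples record the pre-bolus state, so a bolus at a sampling time
      # belongs to the interval that starts there
      i <- findInterval(bl$time_h[k] + 1e-9, time)
      if (i >= 1L && i <= n - 1L) out[i] <- out[i] + ci * bl$volume_L[k]
    }
  }
  out
}

#' @keywords internal
bolus_concentration <- function(boluses, k, metabolite) {
  col <- paste0("conc_", metabolite)
  if (col %in% names(boluses)) boluses[[col]][k] else 0
}

#' @export
print.specific_flux_series <- function(x, ...) {
  cat("<specific_flux_series> ", length(x$time), " intervals; metabolites: ",
      paste(names(x$q), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write specific rates as tidy CSV
#' @param flux a `specific_flux_series`.
#' @param path CSV path.
#' @export
write_flux_csv <- function(flux, path) {
  rows <- lapply(names(flux$q), function(nm)
    data.frame(time_h = flux$time, variable = nm, value = flux$q[[nm]],
               unit = "umol/g_DW/h"))
  rows[[length(rows) + 1L]] <- data.frame(time_h = flux$time, variable = "mu",
                                          value = flux$mu, unit = "1/h")
  rows[[length(rows) + 1L]] <- data.frame(time_h = flux$time, variable = "qp",
                                          value = flux$qp, unit = "mg/g_DW/h")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(flux)
}
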