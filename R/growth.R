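#' Fit growth parameters to one outgrowth curve
#'
#' Estimates the maximum specific growth rate as the largest slope of
#' log OD over sliding windows of `window` consecutive points, the time at
#' which the (blank-corrected) OD first crosses `od_threshold` by linear
#' interpolation between the bracketing samples, and the yield of biomass
#' as the OD gain over the curve. A curve that never reaches the
#' threshold is flagged as not grown (`grew = FALSE`, `t_cross = NA`);
#' its yield is still reported.
#'
#' @param time_h Sampling times in hours (strictly increasing, >= 5 points).
#' @param od Optical densities (same length as `time_h`).
#' @param od_threshold OD threshold for the time-to-threshold readout; if
#'   `NULL`, the midpoint of the curve's own minimum and maximum OD.
#' @param window Points per log-slope window (>= 3, default 5).
#' @param blank Background OD subtracted before analysis (default 0).
#' @return A `growth_fit` list: `mu` (1/h), `td` (doubling time, h),
#'   `t_cross` (h or `NA`), `yield_biomass` (OD units), `grew`,
#'   `od_threshold`.
#' @examples
#' pd <- simulate_outgrowth(1, times = seq(0, 24, 0.25))
#' fit_growth(pd$time_h, pd$od)
#' @export
fit_growth <- function(time_h, od, od_threshold = NULL, window = 5,
                       blank = 0) {
  if (length(time_h) != length(od))
    stop("'time_h' and 'od' must have equal length", call. = FALSE)
  keep <- is.finite(time_h) & is.finite(od)
  if (!any(keep)) stop("all OD values are missing", call. = FALSE)
  time_h <- time_h[keep]; od <- od[keep]
  if (length(time_h) < 5L)
    stop("an outgrowth curve needs at least 5 usable points", call. = FALSE)
  if (is.unsorted(time_h, strictly = TRUE))
    stop("'time_h' must be strictly increasing", call. = FALSE)
  window <- .check_count(window, "window", min = 3L)
  window <- min(window, length(time_h))

  odc <- od - blank
  if (is.null(od_threshold)) od_threshold <- (min(odc) + max(odc)) / 2

  # Specific growth rate from sliding-window slopes of the linearised
  # growth law. The OD trace is lightly smoothed (a running mean rescales
  # an exponential without changing its log slope) and windows are
  # restricted to the informative OD band — above a floor where
  # measurement noise dominates the log scale, below the saturating
  # plateau. On the logit scale ln(x / (K - x)) a logistic trajectory is
  # exactly linear with slope mu, so every window estimates the same
  # quantity and the median across windows is both unbiased for clean
  # curves and robust to noise-inflated windows.
  ods <- .running_mean(odc, 5L)
  K_hat <- max(ods)
  usable <- is.finite(ods) & ods >= max(0.02 * K_hat, .Machine$double.eps) &
    ods <= 0.8 * K_hat
  lgt <- ifelse(usable, log(ods / (K_hat - ods)), NA_real_)
  slopes <- c()
  for (i in seq_len(length(time_h) - window + 1L)) {
    j <- i:(i + window - 1L)
    y <- lgt[j]
    if (anyNA(y)) next
    x <- time_h[j]
    slopes <- c(slopes, stats::cov(x, y) / stats::var(x))
  }
  mu <- if (length(slopes)) stats::median(slopes) else NA_real_
  td <- if (!is.na(mu) && mu > 0) log(2) / mu else NA_real_

  above <- odc >= od_threshold
  t_cross <- NA_real_
  grew <- any(above)
  if (grew) {
    k <- which(above)[1]
    if (k == 1L) {
      t_cross <- time_h[1]
    } else if (odc[k - 1L] > 0) {
      # growth is locally exponential: interpolate on the log scale
      t_cross <- time_h[k - 1L] + (log(od_threshold) - log(odc[k - 1L])) /
        (log(odc[k]) - log(odc[k - 1L])) * (time_h[k] - time_h[k - 1L])
    } else {
      t_cross <- time_h[k - 1L] + (od_threshold - odc[k - 1L]) /
        (odc[k] - odc[k - 1L]) * (time_h[k] - time_h[k - 1L])
    }
  }
  structure(list(mu = mu, td = td, t_cross = t_cross,
                 yield_biomass = max(od) - min(od), grew = grew,
                 od_threshold = od_threshold),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth fit: mu = %.4f /h (td = %.2f h), yield = %.3f OD, %s\n",
              x$mu, x$td, x$yield_biomass,
              if (x$grew) sprintf("threshold %.3f crossed at %.2f h",
                                  x$od_threshold, x$t_cross)
              else "threshold never crossed"))
  invisible(x)
}

#' Viability from a time-to-threshold shift
#'
#' Every doubling time of delay in reaching the OD threshold, relative to
#' a fully viable reference culture, corresponds to a halving of the
#' viable inoculum: `v = 2^(-(t_cross - t_cross_ref) / td)`, capped at 1
#' when the sample crosses earlier than the reference. A sample that
#' never crossed (`t_cross = NA`) has viability 0.
#'
#' @param t_cross Threshold-crossing time of the aged sample (h), or `NA`.
#' @param t_cross_ref Crossing time of the fully viable reference (h).
#' @param td Doubling time (h, > 0).
#' @return Viable fraction in `[0, 1]`.
#' @examples
#' viability_from_shift(10.5, 9, 1.5) # one doubling lost
#' @export
viability_from_shift <- function(t_cross, t_cross_ref, td) {
  if (!is.finite(td) || td <= 0)
    stop("'td' must be a positive doubling time", call. = FALSE)
  if (is.na(t_cross)) return(0)
  min(2^(-(t_cross - t_cross_ref) / td), 1)
}

#' Build a survival curve from per-day growth fits
#'
#' Converts the threshold-crossing times of outgrowth curves collected at
#' successive aging days into viable fractions via
#' [viability_from_shift()], using the earliest day as the fully viable
#' reference (viability 1 by definition) and its doubling time for the
#' shift-to-viability conversion. Once a day shows no growth, that day
#' and all later days are censored to viability 0, so spurious late
#' regrowth cannot resurrect a dead culture.
#'
#' @param fits Named list of `growth_fit` objects; names are aging days.
#' @param td Doubling time used for conversion; default: the reference
#'   day's fitted `td`.
#' @return A `survival_curve` data frame (`aging_day`, `viability`) with
#'   attribute `reference_day`.
#' @export
build_survival_curve <- function(fits, td = NULL) {
  if (is.null(names(fits)))
    stop("'fits' must be named by aging day", call. = FALSE)
  days <- as.numeric(names(fits))
  o <- order(days)
  days <- days[o]; fits <- fits[o]
  ref <- fits[[1]]
  if (!isTRUE(ref$grew))
    stop("no viable reference: the earliest aging day shows no growth",
         call. = FALSE)
  if (is.null(td)) td <- ref$td
  v <- vapply(fits, function(f) {
    viability_from_shift(if (isTRUE(f$grew)) f$t_cross else NA_real_,
                         ref$t_cross, td)
  }, numeric(1))
  v[1] <- 1
  dead <- which(v == 0)
  if (length(dead)) v[seq(min(dead), length(v))] <- 0
  out <- data.frame(aging_day = days, viability = unname(v))
  attr(out, "reference_day") <- days[1]
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Survival Integral of a viability curve
#'
#' The CLS phenotype: the area under the viability-versus-aging-day curve
#' by the trapezoidal rule, in day units. With daily sampling from day 1,
#' a strain alive at day 1 but dead by day 2 scores the assay floor of
#' 0.5 days; a strain fully viable over `D` sampled days scores `D - 1`.
#'
#' @param curve A `survival_curve`, or a data frame with `aging_day` and
#'   `viability` columns.
#' @return The Survival Integral (numeric scalar, days).
#' @examples
#' survival_integral(data.frame(aging_day = 1:5,
#'                              viability = c(1, .8, .5, .2, 0)))
#' @export
survival_integral <- function(curve) {
  d <- curve$aging_day
  v <- curve$viability
  if (length(d) < 2L)
    stop("a survival curve needs at least 2 aging days", call. = FALSE)
  if (is.unsorted(d, strictly = TRUE))
    stop("aging days must be strictly increasing", call. = FALSE)
  if (any(v < 0 | v > 1))
    stop("viabilities must lie in [0, 1]", call. = FALSE)
  sum(diff(d) * (v[-1] + v[-length(v)]) / 2)
}

#' Quantify CLS and growth parameters from plate-reader data
#'
#' Runs the full outgrowth-to-phenotype pipeline for every strain x
#' condition in a long-format plate dataset: fits the earliest aging
#' day's curve as the fully viable reference (its midpoint OD defines the
#' default threshold and its doubling time the shift conversion),
#' extracts threshold crossings for every aging day, assembles the
#' survival curve with censoring, and integrates it to the Survival
#' Integral. Growth rate and yield of biomass are reported from the
#' reference day.
#'
#' @param plate A `plate_data` data frame (`strain`, `condition`,
#'   `aging_day`, `time_h`, `od`).
#' @param od_threshold OD threshold; `NULL` (default) uses the midpoint
#'   of each reference curve's min and max OD.
#' @param window Log-slope window for [fit_growth()].
#' @param blank Background OD subtracted before fitting.
#' @return A `cls_phenotypes` data frame: `strain`, `condition`, `si`,
#'   `mu`, `td`, `yield`; survival curves attached as attribute
#'   `survival_curves`.
#' @export
quantify_plate <- function(plate, od_threshold = NULL, window = 5, blank = 0) {
  required <- c("strain", "condition", "aging_day", "time_h", "od")
  missing <- setdiff(required, names(plate))
  if (length(missing))
    stop("plate data is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  groups <- split(plate, list(plate$strain, plate$condition), drop = TRUE)
  rows <- vector("list", length(groups))
  curves <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    days <- sort(unique(g$aging_day))
    ref_sub <- g[g$aging_day == days[1], ]
    ref_fit <- fit_growth(ref_sub$time_h, ref_sub$od,
                          od_threshold = od_threshold, window = window,
                          blank = blank)
    fits <- stats::setNames(vector("list", length(days)), days)
    fits[[1]] <- ref_fit
    if (length(days) > 1L) for (k in 2:length(days)) {
      sub <- g[g$aging_day == days[k], ]
      fits[[k]] <- fit_growth(sub$time_h, sub$od,
                              od_threshold = ref_fit$od_threshold,
                              window = window, blank = blank)
    }
    curve <- build_survival_curve(fits, td = ref_fit$td)
    curves[[i]] <- curve
    rows[[i]] <- data.frame(strain = g$strain[1], condition = g$condition[1],
                            si = survival_integral(curve), mu = ref_fit$mu,
                            td = ref_fit$td, yield = ref_fit$yield_biomass,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(curves) <- names(groups)
  attr(out, "survival_curves") <- curves
  class(out) <- c("cls_phenotypes", "data.frame")
  out
}

#' @export
plot.survival_curve <- function(x, ...) {
  graphics::plot(x$aging_day, x$viability, type = "b", pch = 19,
                 xlab = "aging day", ylab = "viable fraction",
                 ylim = c(0, 1), ...)
  invisible(x)
}
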