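#' Default growth-model parameters for outgrowth simulation
#'
#' @param K Carrying capacity (OD units).
#' @param mu Maximum specific growth rate (1/h).
#' @param od0 Inoculum optical density (OD units).
#' @return A named list of growth parameters.
#' @export
growth_params <- function(K = 1.0, mu = 0.4, od0 = 0.005) {
  .check_scalar_number(K, "K", lower = 0, strict_lower = TRUE)
  .check_scalar_number(mu, "mu", lower = 0, strict_lower = TRUE)
  .check_scalar_number(od0, "od0", lower = 0, strict_lower = TRUE)
  if (od0 >= K) stop("'od0' must be below the carrying capacity", call. = FALSE)
  list(K = K, mu = mu, od0 = od0)
}

# Logistic biomass trajectory from inoculum x0.
.logistic_od <- function(t, x0, K, mu) {
  if (x0 <= 0) return(rep(0, length(t)))
  K * x0 * exp(mu * t) / (K + x0 * (exp(mu * t) - 1))
}

#' Simulate outgrowth kinetics for an aging culture
#'
#' Generates plate-reader optical density curves for one strain across
#' successive aging timepoints. At each aging day only the viable fraction
#' `v` of the inoculum regrows: the growing sub-population follows
#' logistic growth from an effective inoculum `od0 * v`, while the dead
#' fraction contributes a constant `od0 * (1 - v)` to the signal. The
#' time a curve takes to reach a fixed OD threshold is therefore delayed,
#' relative to a fully viable culture, by `log2(1/v)` doubling times —
#' the time-shift principle on which viability quantification rests.
#'
#' @param viability Numeric vector of viable fractions in `[0, 1]`, one
#'   per aging day; names (or positions) give the aging day.
#' @param params Growth-model parameters from [growth_params()].
#' @param times Sampling time grid in hours (strictly increasing).
#' @param noise_sd Additive Gaussian OD noise standard deviation.
#' @param seed Optional integer seed.
#' @param strain_id,condition Labels carried into the output.
#' @return A `plate_data` data frame with columns `strain`, `condition`,
#'   `aging_day`, `time_h`, `od`.
#' @examples
#' pd <- simulate_outgrowth(c(1, 0.5, 0.1), times = seq(0, 24, 0.5))
#' head(pd)
#' @export
simulate_outgrowth <- function(viability, params = growth_params(),
                               times = seq(0, 24, by = 0.25),
                               noise_sd = 0, seed = NULL,
                               strain_id = "strain1", condition = "SC") {
  if (any(!is.finite(viability)) || any(viability < 0 | viability > 1))
    stop("viabilities must lie in [0, 1]", call. = FALSE)
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE) ||
      any(times < 0))
    stop("'times' must be a non-negative strictly increasing grid",
         call. = FALSE)
  .check_scalar_number(noise_sd, "noise_sd", lower = 0)
  .set_seed_if_given(seed)

  days <- if (!is.null(names(viability))) as.integer(names(viability))
          else seq_along(viability)
  out <- vector("list", length(viability))
  for (i in seq_along(viability)) {
    v <- viability[i]
    od <- params$od0 * (1 - v) +
      .logistic_od(times, params$od0 * v, params$K, params$mu)
    if (noise_sd > 0)
      od <- pmax(od + stats::rnorm(length(times), 0, noise_sd), 0)
    out[[i]] <- data.frame(strain = strain_id, condition = condition,
                           aging_day = days[i], time_h = times, od = od,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("plate_data", "data.frame")
  res
}

#' Exponential-survival viability schedule matching a target SI
#'
#' Constructs per-day viable fractions `v(day) = exp(-(day - first) / tau)`
#' on the given sampling days, with the decay time `tau` chosen so that
#' the trapezoidal Survival Integral of the schedule equals `si`. This is
#' the generative inverse used to turn a simulated SI phenotype into
#' outgrowth curves. Targets at or below the assay floor (half the first
#' sampling interval) collapse to death at the second day; targets at the
#' maximum representable SI give full viability throughout.
#'
#' @param si Target Survival Integral (day units).
#' @param days Integer sampling days (default 1:10).
#' @return Named numeric vector of viabilities, one per day.
#' @export
viability_schedule <- function(si, days = 1:10) {
  if (length(days) < 2L || is.unsorted(days, strictly = TRUE))
    stop("'days' must be strictly increasing with >= 2 entries", call. = FALSE)
  si_max <- max(days) - min(days)
  si_min <- (days[2] - days[1]) / 2
  v_for <- function(tau) exp(-(days - days[1]) / tau)
  si_of <- function(tau) {
    v <- v_for(tau)
    sum(diff(days) * (v[-1] + v[-length(v)]) / 2)
  }
  if (si >= si_max) {
    v <- rep(1, length(days))
  } else if (si <= si_min) {
    v <- c(1, rep(0, length(days) - 1L))
  } else {
    tau <- stats::uniroot(function(x) si_of(x) - si, lower = 1e-4,
                          upper = 1e4, tol = 1e-10)$root
    v <- v_for(tau)
  }
  stats::setNames(v, days)
}
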