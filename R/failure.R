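#' Parameters of the probabilistic cartilage failure-with-repair model
#'
#' Constants of the Weibull cumulative-damage model of cartilage
#' fatigue, its power-law cycles-to-failure relation, and the competing
#' Weibull repair process, together with the simulation horizon and
#' numerical grid.
#'
#' `volume_rule` selects the stressed-cartilage volume entering the
#' weakest-link volume scaling: `"reference"` (default) evaluates
#' failure for an explant-equivalent tissue volume equal to
#' `reference_volume`, the scale at which the fatigue constants were
#' fitted; `"loaded"` uses the geometric stressed volume of the contact
#' solution (loaded area x thickness).  The loaded-volume ratio for a
#' physiological contact patch is of order 100, which saturates the
#' lifetime failure probability; the reference convention reproduces
#' lifetime risks on the scale of epidemiological incidence.  See the
#' methods vignette.
#'
#' @param reference_volume Reference stressed cartilage volume, mm^3
#'   (default 78.5).
#' @param weibull_exponent Weibull exponent k (default 14.3).
#' @param power_law_exponent Power-law exponent b of the
#'   cycles-to-failure relation (default 12.9).
#' @param weibull_coefficient Weibull coefficient applied to strain
#'   (default 1.03).
#' @param power_law_coefficient Power-law coefficient (default 1.0).
#' @param repair_time Time at which 63.2% of damaged cases have
#'   recovered, years (default 5.0).
#' @param repair_exponent Repair Weibull exponent (default 5.2).
#' @param horizon Simulation horizon in years (default 37, skeletal
#'   maturity at 18 through the median age of knee osteoarthritis
#'   diagnosis at 55).
#' @param daily_distance Daily walking distance in m (default 6000).
#' @param time_step Grid step for the time integration, years
#'   (default 0.01).
#' @param cycle_count `"steps"` (default) or `"strides"`; see
#'   [daily_loading_cycles()].
#' @param strain_input `"peak"` (default) or `"mean"`: which strain of a
#'   contact solution drives damage in the pipeline.
#' @param volume_rule `"reference"` (default) or `"loaded"`.
#' @param repair_reference `"absolute"` (default) evaluates the repair
#'   survivor term at absolute time; `"since_damage"` convolves it with
#'   the age of the damage.
#' @return An object of class `failure_params`.
#' @export
failure_params <- function(reference_volume = 78.5,
                           weibull_exponent = 14.3,
                           power_law_exponent = 12.9,
                           weibull_coefficient = 1.03,
                           power_law_coefficient = 1.0,
                           repair_time = 5.0,
                           repair_exponent = 5.2,
                           horizon = 37,
                           daily_distance = 6000,
                           time_step = 0.01,
                           cycle_count = c("steps", "strides"),
                           strain_input = c("peak", "mean"),
                           volume_rule = c("reference", "loaded"),
                           repair_reference = c("absolute", "since_damage")) {
  cycle_count <- match.arg(cycle_count)
  strain_input <- match.arg(strain_input)
  volume_rule <- match.arg(volume_rule)
  repair_reference <- match.arg(repair_reference)
  pos <- c(reference_volume, weibull_exponent, power_law_exponent,
           weibull_coefficient, power_law_coefficient, repair_time,
           repair_exponent, horizon, daily_distance, time_step)
  if (any(pos <= 0)) stop("all failure parameters must be positive")
  if (time_step >= repair_time)
    stop("'time_step' must be smaller than 'repair_time'")
  structure(
    list(reference_volume = reference_volume,
         weibull_exponent = weibull_exponent,
         power_law_exponent = power_law_exponent,
         weibull_coefficient = weibull_coefficient,
         power_law_coefficient = power_law_coefficient,
         repair_time = repair_time,
         repair_exponent = repair_exponent,
         horizon = horizon,
         daily_distance = daily_distance,
         time_step = time_step,
         cycle_count = cycle_count,
         strain_input = strain_input,
         volume_rule = volume_rule,
         repair_reference = repair_reference),
    class = "failure_params")
}

#' @export
print.failure_params <- function(x, ...) {
  cat("Cartilage failure-with-repair parameters\n")
  cat(sprintf("  Weibull k = %.1f, power-law b = %.1f (shape k/b = %.4f), coefficients %.2f / %.1f\n",
              x$weibull_exponent, x$power_law_exponent,
              x$weibull_exponent / x$power_law_exponent,
              x$weibull_coefficient, x$power_law_coefficient))
  cat(sprintf("  repair: %.1f y, exponent %.1f (%s time) | horizon %g y, dt %g y\n",
              x$repair_time, x$repair_exponent, x$repair_reference,
              x$horizon, x$time_step))
  cat(sprintf("  reference volume %.1f mm^3 (%s rule) | %g m/day counted as %s\n",
              x$reference_volume, x$volume_rule, x$daily_distance,
              x$cycle_count))
  invisible(x)
}

#' Time to cartilage failure under cyclic strain
#'
#' Time at which 63.2% (1 - 1/e) of samples would fail under the
#' imposed strain magnitude and daily cycle rate:
#' `t_f = c_p * (time per loading cycle) * (c_w * strain)^(-b)`,
#' with the time per cycle derived from the daily walking distance and
#' stride length ([daily_loading_cycles()]) and converted to years.
#' Strictly decreasing in strain and in daily distance.
#'
#' @param strain Compressive strain driving damage, in `(0, 1)`.
#' @param stride_length Stride length in m.
#' @param params A [failure_params()] object.
#' @return Time to failure in years (vectorised over `strain` /
#'   `stride_length`).
#' @examples
#' time_to_failure(0.22, 1.71)
#' @export
time_to_failure <- function(strain, stride_length, params = failure_params()) {
  if (any(strain <= 0)) stop("'strain' must be positive")
  if (any(strain >= 1)) stop("'strain' must be below 1")
  cycles_per_day <- daily_loading_cycles(stride_length,
                                         params$daily_distance,
                                         params$cycle_count)
  years_per_cycle <- (1 / cycles_per_day) / 365.25
  params$power_law_coefficient * years_per_cycle *
    (params$weibull_coefficient * strain)^(-params$power_law_exponent)
}

.volume_ratio <- function(stressed_volume, params) {
  if (any(stressed_volume < 0)) stop("'stressed_volume' must be non-negative")
  stressed_volume / params$reference_volume
}

#' Cumulative probability of cartilage failure (no repair)
#'
#' Weibull cumulative-damage law with weakest-link volume scaling:
#' `P(t) = 1 - exp(-(V / V_ref) * (t / t_f)^(k / b))`.  At `t = t_f`
#' with `V = V_ref` this equals `1 - 1/e` (63.2%).
#'
#' @param t Time in years (vectorised).
#' @param stressed_volume Stressed cartilage volume V, mm^3.
#' @param t_f Time to failure in years (from [time_to_failure()]).
#' @param params A [failure_params()] object.
#' @return Failure probability in `[0, 1]`.
#' @export
p_fail <- function(t, stressed_volume, t_f, params = failure_params()) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(t_f <= 0)) stop("'t_f' must be positive")
  kb <- params$weibull_exponent / params$power_law_exponent
  1 - exp(-.volume_ratio(stressed_volume, params) * (t / t_f)^kb)
}

#' Cumulative probability of cartilage repair
#'
#' Weibull repair law `P_r(t) = 1 - exp(-(t / t_r)^a)`; at `t` equal to
#' the repair time constant 63.2% of damaged cases have recovered.
#'
#' @param t Time in years (vectorised).
#' @param params A [failure_params()] object.
#' @return Repair probability in `[0, 1]`.
#' @examples
#' p_repair(5.0)   # 0.632
#' @export
p_repair <- function(t, params = failure_params()) {
  if (any(t < 0)) stop("'t' must be non-negative")
  1 - exp(-(t / params$repair_time)^params$repair_exponent)
}

#' Instantaneous failure density
#'
#' Exact time-derivative of [p_fail()]:
#' `f(t) = (V/V_ref) (k/b) (1/t_f) (t/t_f)^(k/b - 1)
#'   exp(-(V/V_ref)(t/t_f)^(k/b))`,
#' the instantaneous likelihood of failure across time; its integral
#' recovers the cumulative law.
#'
#' @inheritParams p_fail
#' @return Density in probability per year.
#' @export
failure_density <- function(t, stressed_volume, t_f,
                            params = failure_params()) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(t_f <= 0)) stop("'t_f' must be positive")
  kb <- params$weibull_exponent / params$power_law_exponent
  vr <- .volume_ratio(stressed_volume, params)
  u <- (t / t_f)^kb
  out <- vr * kb * (1 / t_f) * (t / t_f)^(kb - 1) * exp(-vr * u)
  out[t == 0] <- 0
  out
}

#' Failure probability over the lifetime horizon, with and without repair
#'
#' Integrates the failure density weighted by the probability that
#' repair has not yet taken place,
#' `P(T) = integral_0^T f(t) (1 - P_repair(t)) dt` (trapezoidal rule on
#' the configured grid), alongside the unrepaired cumulative curve.
#' With `repair_reference = "since_damage"` the survivor term is
#' evaluated at the age of the damage, `1 - P_repair(T - t)`, instead of
#' at absolute time.
#'
#' @param stressed_volume Stressed cartilage volume V, mm^3.
#' @param t_f Time to failure in years.
#' @param params A [failure_params()] object (supplies horizon and
#'   grid step).
#' @return An object of class `failure_result`: `time` grid (years),
#'   `p_fail` and `p_fail_with_repair` curves, `time_to_failure`, and
#'   terminal probabilities `p_terminal_no_repair` / `p_terminal`.
#' @examples
#' res <- p_fail_with_repair(78.5, time_to_failure(0.24, 1.71))
#' res$p_terminal
#' @export
p_fail_with_repair <- function(stressed_volume, t_f,
                               params = failure_params()) {
  if (length(t_f) != 1 || t_f <= 0) stop("'t_f' must be a positive scalar")
  t <- seq(0, params$horizon, by = params$time_step)
  if (t[length(t)] < params$horizon) t <- c(t, params$horizon)
  no_repair <- p_fail(t, stressed_volume, t_f, params)
  dens <- failure_density(t, stressed_volume, t_f, params)
  if (params$repair_reference == "absolute") {
    integrand <- dens * (1 - p_repair(t, params))
    with_repair <- pracma::cumtrapz(t, integrand)[, 1]
  } else {
    # survivor term at damage age T - t: one quadrature per horizon point
    with_repair <- vapply(seq_along(t), function(j) {
      tj <- t[seq_len(j)]
      g <- dens[seq_len(j)] * (1 - p_repair(t[j] - tj, params))
      if (j == 1) 0 else pracma::trapz(tj, g)
    }, numeric(1))
  }
  with_repair <- pmin(pmax(with_repair, 0), 1)
  structure(
    list(time = t,
         p_fail = no_repair,
         p_fail_with_repair = with_repair,
         time_to_failure = t_f,
         stressed_volume = stressed_volume,
         p_terminal_no_repair = no_repair[length(t)],
         p_terminal = with_repair[length(t)]),
    class = "failure_result")
}

#' @export
print.failure_result <- function(x, ...) {
  cat("Lifetime cartilage failure projection\n")
  cat(sprintf("  time to failure %.1f y | horizon %.0f y\n",
              x$time_to_failure, max(x$time)))
  cat(sprintf("  terminal probability: %.2f%% with repair, %.2f%% without\n",
              100 * x$p_terminal, 100 * x$p_terminal_no_repair))
  invisible(x)
}
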