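#' LED fixture specification
#'
#' @param etr_cap maximum supplemental ETR the fixture can add,
#'   umol m-2 s-1 (default 86.21, the packaged fixture value).
#' @param efficacy photon efficacy, umol/J (default 2.9).
#' @return object of class `led_spec`.
#' @export
led_spec <- function(etr_cap = 86.21, efficacy = 2.9) {
  stopifnot(etr_cap > 0, efficacy > 0)
  structure(list(etr_cap = etr_cap, efficacy = efficacy),
            class = "led_spec")
}

#' LED maximum PPFD implied by the ETR cap
#' @param led a [led_spec()].
#' @param params a [light_response_params()].
#' @return PPFD, umol m-2 s-1.
#' @export
ppfd_max_led <- function(led, params) ppfd_from_etr(led$etr_cap, params)

#' PWM duty cycle for a supplemental PPFD
#'
#' Linear dimming model: `100 * supplemental_ppfd / ppfd_max`. Inputs outside
#' `[0, ppfd_max]` are clamped with a warning.
#'
#' @param supplemental_ppfd requested PPFD, umol m-2 s-1.
#' @param ppfd_max LED maximum PPFD at 100% duty.
#' @return duty cycle, percent in [0, 100]. Vectorised.
#' @export
duty_cycle <- function(supplemental_ppfd, ppfd_max) {
  stopifnot(ppfd_max > 0)
  if (any(supplemental_ppfd < -1e-9) ||
      any(supplemental_ppfd > ppfd_max * (1 + 1e-9)))
    warning("supplemental PPFD outside [0, ppfd_max]; clamped")
  100 * pmin(pmax(supplemental_ppfd, 0), ppfd_max) / ppfd_max
}

#' Default heuristic threshold PPFD
#'
#' The smallest constant PPFD which, held over the whole photoperiod,
#' delivers exactly the DPI target: invert the light response at the
#' required mean ETR `dpi_target / (T * m * 1e-6)`. For the default lettuce
#' parameters this is about 203.2 umol m-2 s-1.
#'
#' @param params a [light_response_params()].
#' @param period a [photoperiod_spec()].
#' @return threshold PPFD, umol m-2 s-1.
#' @export
heuristic_threshold <- function(params, period = photoperiod_spec()) {
  mean_etr <- params$dpi_target / (period$n_steps * period$step_seconds * 1e-6)
  if (mean_etr >= params$a)
    stop("DPI target requires mean ETR >= asymptote; unreachable")
  ppfd_from_etr(mean_etr, params)
}

day_result <- function(sun_ppfd, supplemental_ppfd, prices, params, period,
                       led, spec, controller, feasible = TRUE,
                       shortfall = 0, forecast_ppfd = NULL) {
  pmax_led <- ppfd_max_led(led, params)
  combined_etr <- etr_from_ppfd(sun_ppfd + supplemental_ppfd, params)
  steps <- data.frame(
    step = seq_along(sun_ppfd),
    sun_ppfd = sun_ppfd,
    supplemental_ppfd = supplemental_ppfd,
    duty_cycle = duty_cycle(supplemental_ppfd, pmax_led),
    price = prices,
    combined_etr = combined_etr,
    step_cost = step_cost(supplemental_ppfd, prices, spec))
  if (!is.null(forecast_ppfd)) steps$forecast_ppfd <- forecast_ppfd
  structure(list(
    controller = controller,
    steps = steps,
    dpi = integral_over_day(combined_etr, period$step_seconds),
    dli = integral_over_day(sun_ppfd + supplemental_ppfd,
                            period$step_seconds),
    sun_dli = integral_over_day(sun_ppfd, period$step_seconds),
    cost_cents = sum(steps$step_cost),
    feasible = feasible, shortfall = shortfall),
    class = "day_result")
}

#' @export
print.day_result <- function(x, ...) {
  cat(sprintf(
    "%s day: DPI %.3f, DLI %.2f (sun %.2f) mol m-2 d-1, cost %.2f cents/m2%s\n",
    x$controller, x$dpi, x$dli, x$sun_dli, x$cost_cents,
    if (x$feasible) "" else " [infeasible]"))
  invisible(x)
}

#' Perfect-knowledge optimal baseline for one day
#'
#' Solves the full-horizon cost minimisation once with the day's actual
#' sunlight known in advance — the theoretical optimum against which the
#' practical controllers are benchmarked.
#'
#' @param sun_ppfd actual per-step sunlight PPFD, length T.
#' @param prices per-step price vector.
#' @param params a [light_response_params()].
#' @param period a [photoperiod_spec()].
#' @param led a [led_spec()].
#' @param spec a [conversion_spec()].
#' @return a `day_result` (per-step schedule, achieved DPI/DLI, daily cost).
#' @export
run_baseline <- function(sun_ppfd, prices, params,
                         period = photoperiod_spec(), led = led_spec(),
                         spec = conversion_spec()) {
  stopifnot(length(sun_ppfd) == period$n_steps)
  inp <- optimization_input(prices, sun_ppfd, params,
                            step_seconds = period$step_seconds,
                            etr_cap = led$etr_cap)
  plan <- solve_lighting(inp)
  day_result(sun_ppfd, plan$x_ppfd, prices, params, period, led, spec,
             "baseline", plan$feasible, plan$shortfall)
}

#' Receding-horizon prediction-based controller for one day
#'
#' At each step the controller observes the current sunlight measurement,
#' forecasts the remaining day with the Markov model (expected values
#' conditioned on the measurement), re-solves the remaining-horizon
#' optimization with the accumulated-light credit of elapsed steps, and
#' commits only the current step's supplemental light. Before the first
#' measurement the forecast is the historical per-step mean. In `oracle`
#' mode the true future replaces the forecast, which reproduces the baseline.
#'
#' @param sun_ppfd actual per-step sunlight PPFD (revealed step by step).
#' @param model a fitted [fit_sunlight_model()] (ignored in oracle mode).
#' @param prices,params,period,led,spec as in [run_baseline()].
#' @param oracle if `TRUE`, feed the controller the true future sunlight.
#' @return a `day_result`; `feasible` is `FALSE` if any re-solve found the
#'   remaining requirement uncoverable.
#' @export
run_predictive <- function(sun_ppfd, model, prices, params,
                           period = photoperiod_spec(), led = led_spec(),
                           spec = conversion_spec(), oracle = FALSE) {
  T <- period$n_steps
  stopifnot(length(sun_ppfd) == T)
  if (!oracle) stopifnot(inherits(model, "transition_model"),
                         model$n_steps == T)
  x_ppfd <- numeric(T)
  forecast_log <- numeric(T)
  credit <- 0
  feasible <- TRUE; shortfall <- 0
  for (i in seq_len(T)) {
    future <- if (i < T) {
      if (oracle) sun_ppfd[(i + 1):T]
      else predict_remaining(model, i, sun_ppfd[i])
    } else numeric(0)
    horizon_sun <- c(sun_ppfd[i], future)
    forecast_log[i] <- sun_ppfd[i]
    inp <- optimization_input(prices[i:T], horizon_sun, params,
                              step_seconds = period$step_seconds,
                              etr_cap = led$etr_cap,
                              credit_etr_sum = credit)
    plan <- solve_lighting(inp)
    if (!plan$feasible) { feasible <- FALSE; shortfall <- plan$shortfall }
    x_ppfd[i] <- plan$x_ppfd[1L]
    credit <- credit + plan$x_etr[1L] + etr_from_ppfd(sun_ppfd[i], params)
  }
  res <- day_result(sun_ppfd, x_ppfd, prices, params, period, led, spec,
                    if (oracle) "predictive (oracle)" else "predictive",
                    feasible, shortfall)
  res
}

#' Threshold heuristic controller for one day
#'
#' Price- and forecast-blind: at every step, tops sunlight up to a fixed
#' PPFD threshold (capped at the LED maximum); supplies nothing when
#' sunlight alone exceeds the threshold.
#'
#' @param sun_ppfd actual per-step sunlight PPFD.
#' @param prices,params,period,led,spec as in [run_baseline()].
#' @param threshold_ppfd target PPFD; default from [heuristic_threshold()].
#' @return a `day_result`.
#' @export
run_heuristic <- function(sun_ppfd, prices, params,
                          period = photoperiod_spec(), led = led_spec(),
                          spec = conversion_spec(),
                          threshold_ppfd = NULL) {
  stopifnot(length(sun_ppfd) == period$n_steps)
  if (is.null(threshold_ppfd))
    threshold_ppfd <- heuristic_threshold(params, period)
  stopifnot(threshold_ppfd > 0)
  supp <- pmin(pmax(threshold_ppfd - sun_ppfd, 0),
               ppfd_max_led(led, params))
  day_result(sun_ppfd, supp, prices, params, period, led, spec, "heuristic")
}
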