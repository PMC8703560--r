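#' Electricity price profiles
#'
#' Builds a per-step price vector (cents/kWh) over the photoperiod. Fixed
#' profiles repeat one price; hourly profiles hold each hour's price constant
#' across the 15-min steps falling in that clock hour, wrapping at midnight.
#'
#' The packaged variable profile (`price_profile_variable()`) is a synthetic
#' 24-h time-of-use shape — low off-peak overnight, a midday peak and a
#' higher early-evening peak — shipped as
#' `inst/extdata/price_variable_24h_synthetic.csv`. It emulates the shape of
#' a scaled day-ahead market profile; it is generated data, not a published
#' tariff.
#'
#' @param price fixed price, cents/kWh (default 13.19).
#' @param period a [photoperiod_spec()].
#' @return numeric vector of length `period$n_steps` with attribute
#'   `kind` (`"fixed"` or `"variable"`).
#' @export
price_profile_fixed <- function(price = 13.19, period = photoperiod_spec()) {
  stopifnot(price >= 0)
  structure(rep(price, period$n_steps), kind = "fixed")
}

#' @rdname price_profile_fixed
#' @param path CSV with columns `hour` (0-23) and `price_cents_per_kwh`;
#'   defaults to the packaged synthetic profile.
#' @export
price_profile_variable <- function(path = NULL,
                                   period = photoperiod_spec()) {
  if (is.null(path))
    path <- system.file("extdata", "price_variable_24h_synthetic.csv",
                        package = "greenlight", mustWork = TRUE)
  df <- utils::read.csv(path)
  stopifnot(all(c("hour", "price_cents_per_kwh") %in% names(df)))
  if (!setequal(df$hour, 0:23)) stop("hourly profile must cover hours 0-23")
  hourly <- df$price_cents_per_kwh[order(df$hour)]
  if (any(hourly < 0)) stop("prices must be non-negative")
  step_hour <- floor((period$start_hour +
    (seq_len(period$n_steps) - 1) * period$step_seconds / 3600) %% 24)
  structure(hourly[step_hour + 1L], kind = "variable")
}

#' Optical-to-electrical cost conversion
#'
#' Converts the optimizer's objective units (cents/kWh x umol m-2 s-1) to
#' cents/m2. A fixture efficacy of 2.9 umol/J means 1 kW of LED input power
#' produces 2.9e3 umol/s of photons, so a supplemental PPFD `p` draws
#' `p / (efficacy * 1e3)` kW/m2; over a `step_hours` step at price `C`
#' (cents/kWh) the step cost is `C * p / (efficacy * 1e3) * step_hours`
#' cents/m2. The derived factor `q = step_hours / (efficacy * 1e3)` maps the
#' whole-plan objective `f` to cents/m2 as `q * f`.
#'
#' @param efficacy LED photon efficacy, umol/J (default 2.9).
#' @param step_hours step length, hours (default 0.25).
#' @return object of class `conversion_spec` with fields `efficacy`,
#'   `step_hours`, `q`.
#' @export
conversion_spec <- function(efficacy = 2.9, step_hours = 0.25) {
  stopifnot(efficacy > 0, step_hours > 0)
  structure(list(efficacy = efficacy, step_hours = step_hours,
                 q = step_hours / (efficacy * 1e3)),
            class = "conversion_spec")
}

#' Electricity cost of one control step
#'
#' @param supplemental_ppfd supplemental PPFD delivered, umol m-2 s-1.
#' @param price electricity price, cents/kWh.
#' @param spec a [conversion_spec()].
#' @return cost, cents/m2. Vectorised; linear in both arguments.
#' @export
step_cost <- function(supplemental_ppfd, price, spec = conversion_spec()) {
  stopifnot(inherits(spec, "conversion_spec"))
  if (any(supplemental_ppfd < 0) || any(price < 0))
    stop("inputs must be non-negative")
  price * supplemental_ppfd * spec$q
}

#' Daily electricity cost and comparison to a reference
#'
#' Sums [step_cost()] over a day's supplemental PPFD series. When a
#' reference cost is supplied, also reports the percent increase
#' `100 * (c - c_ref) / c_ref` (Inf-marked as `NA` when the reference is 0
#' and the cost is not).
#'
#' @param supplemental_ppfd per-step supplemental PPFD.
#' @param prices per-step price vector (same length).
#' @param spec a [conversion_spec()].
#' @param reference_cost optional reference daily cost, cents/m2.
#' @return list with `cost_cents`, `cost_dollars`, and (when a reference is
#'   given) `increase_pct`.
#' @export
daily_cost <- function(supplemental_ppfd, prices, spec = conversion_spec(),
                       reference_cost = NULL) {
  stopifnot(length(supplemental_ppfd) == length(prices))
  cents <- sum(step_cost(supplemental_ppfd, prices, spec))
  out <- list(cost_cents = cents, cost_dollars = cents / 100)
  if (!is.null(reference_cost))
    out$increase_pct <- percent_increase(cents, reference_cost)
  out
}

#' Percent increase over a reference
#' @param cost,reference_cost costs in the same units.
#' @return `100 * (cost - reference_cost) / reference_cost`; 0 when both are
#'   zero; `NA` when only the reference is zero.
#' @export
percent_increase <- function(cost, reference_cost) {
  if (reference_cost == 0) {
    if (cost == 0) 0 else NA_real_
  } else 100 * (cost - reference_cost) / reference_cost
}

#' Growth-per-cost efficiency
#'
#' Plain ratio of total shoot dry weight to total electricity cost; growth
#' measurements are external inputs, not simulated.
#'
#' @param total_dry_weight_g grams.
#' @param total_cost_cents cents; must be positive.
#' @return g/cent.
#' @export
efficiency_ratio <- function(total_dry_weight_g, total_cost_cents) {
  if (total_cost_cents <= 0) stop("total_cost_cents must be positive")
  total_dry_weight_g / total_cost_cents
}
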