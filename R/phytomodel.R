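#' Crop light-response parameters
#'
#' Parameters of the exponential-saturation electron transport rate (ETR)
#' response to photosynthetic photon flux density (PPFD),
#' \eqn{ETR = a (1 - e^{-k \cdot PPFD})}, together with the crop's minimum
#' daily photochemical integral (DPI) requirement. All rates are in
#' \eqn{\mu mol\,m^{-2}\,s^{-1}}; daily integrals in \eqn{mol\,m^{-2}\,d^{-1}}.
#'
#' @param a ETR asymptote, \eqn{\mu mol\,m^{-2}\,s^{-1}}. Must be > 0.
#' @param k initial-slope coefficient per \eqn{\mu mol\,m^{-2}\,s^{-1}};
#'   the initial slope of the response curve divided by `a`. Must be > 0.
#' @param dpi_target minimum DPI the crop must receive per day,
#'   \eqn{mol\,m^{-2}\,d^{-1}}. Must be >= 0.
#' @param name optional preset label.
#' @return An object of class `light_response_params`.
#' @seealso [crop_preset()] for named presets, [etr_from_ppfd()].
#' @export
light_response_params <- function(a, k, dpi_target, name = NULL) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(dpi_target), length(dpi_target) == 1L,
            is.finite(dpi_target))
  if (a <= 0) stop("'a' (ETR asymptote) must be positive")
  if (k <= 0) stop("'k' (initial-slope coefficient) must be positive")
  if (dpi_target < 0) stop("'dpi_target' must be non-negative")
  structure(list(a = a, k = k, dpi_target = dpi_target,
                 name = if (is.null(name)) NA_character_ else name),
            class = "light_response_params")
}

#' Named crop presets
#'
#' Currently ships the "Green Towers" lettuce parameterisation
#' (a = 121, k = 0.00277, DPI target 3 mol m-2 d-1).
#'
#' @param name preset name; `"green_towers"` (aliases `"green towers"`,
#'   `"green_towers_lettuce"`).
#' @return A [light_response_params()] object.
#' @export
crop_preset <- function(name = "green_towers") {
  key <- gsub("[ -]", "_", tolower(name))
  switch(key,
    green_towers = ,
    green_towers_lettuce = light_response_params(
      a = 121, k = 0.00277, dpi_target = 3, name = "green_towers"),
    stop("unknown crop preset: ", name)
  )
}

#' @export
print.light_response_params <- function(x, ...) {
  cat(sprintf(
    "Light-response parameters%s\n  a = %g umol m-2 s-1, k = %g, DPI target = %g mol m-2 d-1\n",
    if (is.na(x$name)) "" else paste0(" [", x$name, "]"), x$a, x$k,
    x$dpi_target))
  invisible(x)
}

#' Photoperiod discretisation
#'
#' The daily lighting window split into equal control steps. The photoperiod
#' length must be an exact multiple of the step length; the default is the
#' common 16 h lettuce photoperiod at 15-min (900 s) steps, i.e. T = 64.
#'
#' @param step_seconds control-step length m, seconds.
#' @param photoperiod_hours photoperiod length, hours.
#' @param start_time local clock time of photoperiod start, `"HH:MM"`.
#' @return Object of class `photoperiod_spec` with fields `step_seconds`,
#'   `n_steps`, `photoperiod_hours`, `start_time`, `start_hour` (decimal).
#' @export
photoperiod_spec <- function(step_seconds = 900, photoperiod_hours = 16,
                             start_time = "04:30") {
  stopifnot(step_seconds > 0, photoperiod_hours > 0)
  total <- photoperiod_hours * 3600
  n <- total / step_seconds
  if (abs(n - round(n)) > 1e-9)
    stop("photoperiod (", total, " s) is not an integer multiple of ",
         "step_seconds (", step_seconds, " s)")
  hm <- strsplit(start_time, ":", fixed = TRUE)[[1L]]
  if (length(hm) != 2L || anyNA(suppressWarnings(as.numeric(hm))))
    stop("start_time must be 'HH:MM'")
  structure(list(step_seconds = step_seconds,
                 n_steps = as.integer(round(n)),
                 photoperiod_hours = photoperiod_hours,
                 start_time = start_time,
                 start_hour = as.numeric(hm[1L]) + as.numeric(hm[2L]) / 60),
            class = "photoperiod_spec")
}

#' @export
print.photoperiod_spec <- function(x, ...) {
  cat(sprintf("Photoperiod: %g h from %s, %d steps of %g s\n",
              x$photoperiod_hours, x$start_time, x$n_steps, x$step_seconds))
  invisible(x)
}

#' ETR from PPFD (light-response curve)
#'
#' Electron transport rate produced by a given photon flux density under the
#' exponential-saturation model \eqn{a (1 - e^{-k\,PPFD})}. Vectorised.
#'
#' @param ppfd PPFD, \eqn{\mu mol\,m^{-2}\,s^{-1}}; must be >= 0.
#' @param params a [light_response_params()] object.
#' @return ETR, \eqn{\mu mol\,m^{-2}\,s^{-1}}; strictly increasing in `ppfd`
#'   and bounded above by `params$a`.
#' @examples
#' p <- crop_preset("green_towers")
#' etr_from_ppfd(500, p)  # ~90.7
#' @export
etr_from_ppfd <- function(ppfd, params) {
  stopifnot(inherits(params, "light_response_params"), is.numeric(ppfd))
  if (any(!is.finite(ppfd)) || any(ppfd < 0))
    stop("'ppfd' must be finite and non-negative")
  params$a * (1 - exp(-params$k * ppfd))
}

#' PPFD from ETR (inverse light response)
#'
#' Analytic inverse of [etr_from_ppfd()]: the PPFD needed to drive a given
#' ETR. Only ETRs strictly below the asymptote `a` are reachable.
#'
#' @param etr ETR, \eqn{\mu mol\,m^{-2}\,s^{-1}}; requires 0 <= etr < a.
#' @param params a [light_response_params()] object.
#' @return PPFD, \eqn{\mu mol\,m^{-2}\,s^{-1}}.
#' @export
ppfd_from_etr <- function(etr, params) {
  stopifnot(inherits(params, "light_response_params"), is.numeric(etr))
  if (any(!is.finite(etr)) || any(etr < 0))
    stop("'etr' must be finite and non-negative")
  if (any(etr >= params$a))
    stop("'etr' must be below the asymptote a = ", params$a,
         " (saturation is unreachable at finite PPFD)")
  -log(1 - etr / params$a) / params$k
}

#' Daily integral of a per-step rate series
#'
#' Step-length-weighted sum with the micromole-to-mole conversion:
#' \eqn{\sum_t v_t \cdot m \cdot 10^{-6}}. Applied to an ETR series this is
#' the daily photochemical integral (DPI); applied to a PPFD series, the
#' daily light integral (DLI). This is the single place in the package where
#' the 1e-6 unit conversion is applied.
#'
#' @param series per-step rates, \eqn{\mu mol\,m^{-2}\,s^{-1}}.
#' @param step_seconds step length m, seconds.
#' @return integral in \eqn{mol\,m^{-2}\,d^{-1}}.
#' @export
integral_over_day <- function(series, step_seconds) {
  stopifnot(is.numeric(series), step_seconds > 0)
  if (any(!is.finite(series)) || any(series < 0))
    stop("'series' must be finite and non-negative")
  sum(series) * step_seconds * 1e-6
}
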