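#' Inputs to the supplemental-lighting optimization
#'
#' Bundles everything one horizon solve needs: per-step electricity prices
#' `C_t`, per-step sunlight (as ETR and, consistently, as PPFD), the DPI
#' requirement, the step length, the LED ETR cap, and the ETR-sum credit
#' already accumulated over elapsed steps of the day (for receding-horizon
#' re-solves).
#'
#' @param prices per-step price, cents/kWh; non-negative, length T.
#' @param sun_ppfd per-step sunlight PPFD `s_t` (actual or forecast).
#' @param params a [light_response_params()].
#' @param dpi_target minimum DPI for the whole day, mol m-2 d-1; defaults to
#'   `params$dpi_target`.
#' @param step_seconds step length m, seconds.
#' @param etr_cap maximum supplemental ETR the LEDs can add per step,
#'   umol m-2 s-1; must satisfy `0 <= etr_cap < a`.
#' @param credit_etr_sum sum of realized combined ETR `x_t + sbar_t` over
#'   already-elapsed steps, umol m-2 s-1 (ETR-sum units).
#' @param sun_etr optional per-step sunlight ETR; computed from `sun_ppfd`
#'   when omitted, and checked for consistency when given.
#' @return object of class `optimization_input`.
#' @export
optimization_input <- function(prices, sun_ppfd, params,
                               dpi_target = params$dpi_target,
                               step_seconds = 900, etr_cap = 86.21,
                               credit_etr_sum = 0, sun_etr = NULL) {
  stopifnot(inherits(params, "light_response_params"),
            is.numeric(prices), is.numeric(sun_ppfd),
            length(prices) == length(sun_ppfd), length(prices) >= 1L)
  if (any(prices < 0)) stop("prices must be non-negative")
  if (etr_cap < 0 || etr_cap >= params$a)
    stop("etr_cap must satisfy 0 <= etr_cap < a")
  if (is.null(sun_etr)) {
    sun_etr <- etr_from_ppfd(sun_ppfd, params)
  } else if (max(abs(sun_etr - etr_from_ppfd(sun_ppfd, params))) >
             1e-6 * params$a) {
    stop("sun_etr is inconsistent with etr_from_ppfd(sun_ppfd)")
  }
  structure(list(prices = prices, sun_ppfd = sun_ppfd, sun_etr = sun_etr,
                 dpi_target = dpi_target, step_seconds = step_seconds,
                 etr_cap = etr_cap, credit_etr_sum = credit_etr_sum,
                 params = params),
            class = "optimization_input")
}

#' Minimum-cost supplemental lighting plan over a horizon
#'
#' Solves the convex program
#' \deqn{\min_x \sum_t C_t \left[\frac{1}{k}\ln\frac{a}{a - x_t - \bar s_t}
#'   - s_t\right] \quad \mathrm{s.t.}\quad \sum_t (x_t + \bar s_t) \ge
#'   \frac{\bar D}{m\,10^{-6}} - \mathrm{credit},\; 0 \le x_t \le
#'   \bar U_{LED},}
#' where \eqn{x_t} is the supplemental ETR committed at step t. The objective
#' is the electricity-price-weighted supplemental PPFD (see
#' [objective_cost()]); the constraint makes the day's combined photochemical
#' integral reach the DPI target net of what elapsed steps already supplied.
#'
#' The problem is separable and convex with one linear coupling constraint,
#' so it is solved exactly at its KKT conditions: for a multiplier
#' \eqn{\lambda} on the light constraint the per-step optimum is the closed
#' form \eqn{x_t(\lambda) = \mathrm{clip}(a - \bar s_t - C_t/(k\lambda),\,
#' 0,\, cap_t)}, monotone in \eqn{\lambda}; the multiplier is found by
#' bisection until the constraint binds. Zero-price steps supply light first
#' (their marginal cost is zero). A numerical guard keeps every step's
#' combined ETR at least `1e-6 * a` below the asymptote.
#'
#' When even the all-cap plan cannot meet the requirement the all-cap plan is
#' returned with `feasible = FALSE` and the positive `shortfall` (ETR-sum
#' units); no error is raised, so a closed-loop controller can keep acting.
#'
#' @param input an [optimization_input()].
#' @return object of class `lighting_plan`: `x_etr`, `x_ppfd` (supplemental
#'   PPFD equivalent `ppfd_from_etr(x + sbar) - s`), `objective_value`
#'   (pre-conversion units, cents/kWh x umol m-2 s-1), `feasible`,
#'   `shortfall`, `required_etr_sum`, `lambda`.
#' @export
solve_lighting <- function(input) {
  stopifnot(inherits(input, "optimization_input"))
  a <- input$params$a; k <- input$params$k
  eps <- 1e-6 * a
  C <- input$prices
  sbar <- input$sun_etr
  T <- length(C)
  # per-step cap: LED limit, further reduced near saturation
  cap <- pmin(input$etr_cap, pmax(a - eps - sbar, 0))
  req <- input$dpi_target / (input$step_seconds * 1e-6) -
    input$credit_etr_sum - sum(sbar)

  x <- numeric(T)
  feasible <- TRUE; shortfall <- 0; lambda <- 0
  if (req > 1e-12) {
    if (sum(cap) < req) {
      x <- cap
      feasible <- FALSE
      shortfall <- req - sum(cap)
    } else {
      # zero-price steps first: free light, filled only as far as needed
      free <- which(C == 0)
      remaining <- req
      if (length(free)) {
        avail <- cap[free]
        take <- if (sum(avail) <= remaining) avail else {
          # fill in step order until the requirement is covered
          cum <- cumsum(avail)
          t2 <- pmin(avail, pmax(remaining - c(0, cum[-length(cum)]), 0))
          t2
        }
        x[free] <- take
        remaining <- remaining - sum(take)
      }
      pos <- which(C > 0)
      if (remaining > 1e-12 && length(pos)) {
        Cp <- C[pos]; sp <- sbar[pos]; capp <- cap[pos]
        g <- function(lam)
          sum(pmin(pmax(a - sp - Cp / (k * lam), 0), capp))
        lo <- 0.5 * min(Cp / (k * (a - sp)))
        hi <- 2 * max(Cp / (k * pmax(a - sp - capp, eps)))
        while (g(hi) < remaining) hi <- hi * 2
        for (it in 1:200) {
          mid <- (lo + hi) / 2
          if (g(mid) < remaining) lo <- mid else hi <- mid
        }
        lambda <- hi
        x[pos] <- pmin(pmax(a - sp - Cp / (k * lambda), 0), capp)
        # exact binding: distribute any residual over interior steps
        resid <- remaining - sum(x[pos])
        if (abs(resid) > 0) {
          interior <- pos[x[pos] > 1e-12 & x[pos] < cap[pos] - 1e-12]
          if (length(interior))
            x[interior] <- x[interior] + resid / length(interior)
        }
      }
    }
  }
  x <- pmin(pmax(x, 0), cap)
  combined <- pmin(x + sbar, a - eps)
  x_ppfd <- ppfd_from_etr(combined, input$params) - input$sun_ppfd
  x_ppfd <- pmax(x_ppfd, 0)
  x_ppfd[x == 0] <- 0          # avoid round-trip dust on unlit steps
  plan <- structure(list(x_etr = x, x_ppfd = x_ppfd,
                         feasible = feasible, shortfall = shortfall,
                         required_etr_sum = max(req, 0), lambda = lambda),
                    class = "lighting_plan")
  plan$objective_value <- objective_cost(plan, input)
  plan
}

#' @export
print.lighting_plan <- function(x, ...) {
  cat(sprintf(
    "Lighting plan: %d steps, supplemental ETR sum %.2f, objective %.4g%s\n",
    length(x$x_etr), sum(x$x_etr), x$objective_value,
    if (x$feasible) "" else sprintf(" [INFEASIBLE, shortfall %.2f]",
                                    x$shortfall)))
  invisible(x)
}

#' Evaluate the optimization objective at a plan
#'
#' Computes \eqn{f = \sum_t C_t [(1/k) \ln(a / (a - x_t - \bar s_t)) - s_t]}.
#' Because \eqn{(1/k)\ln(a/(a - \bar s_t)) = s_t} when
#' \eqn{\bar s_t = a(1 - e^{-k s_t})}, the bracket is exactly the
#' supplemental PPFD of step t, so `f` is the price-weighted supplemental
#' PPFD sum and vanishes for a zero-supplement plan.
#'
#' @param plan a `lighting_plan` (or a bare numeric vector of per-step
#'   supplemental ETR).
#' @param input the matching [optimization_input()].
#' @return objective value, cents/kWh x umol m-2 s-1 (multiply by the
#'   [conversion_spec()] factor `q` for cents/m2).
#' @export
objective_cost <- function(plan, input) {
  stopifnot(inherits(input, "optimization_input"))
  x <- if (inherits(plan, "lighting_plan")) plan$x_etr else plan
  stopifnot(length(x) == length(input$prices))
  a <- input$params$a; k <- input$params$k
  combined <- x + input$sun_etr
  if (any(combined >= a))
    stop("x_etr + sun_etr reaches the asymptote a; objective undefined")
  sum(input$prices * (log(a / (a - combined)) / k - input$sun_ppfd))
}

#' Export a plan to CSV
#'
#' One row per step: `step`, `x_etr`, `x_ppfd`, `duty_cycle`.
#'
#' @param plan a `lighting_plan`.
#' @param path output file.
#' @param ppfd_max_led LED maximum PPFD used for the duty-cycle mapping.
#' @export
write_plan_csv <- function(plan, path, ppfd_max_led) {
  stopifnot(inherits(plan, "lighting_plan"))
  utils::write.csv(data.frame(
    step = seq_along(plan$x_etr),
    x_etr = plan$x_etr,
    x_ppfd = plan$x_ppfd,
    duty_cycle = duty_cycle(plan$x_ppfd, ppfd_max_led)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
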