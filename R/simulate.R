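#' Run all three controllers over a season of evaluation days
#'
#' Generates (or accepts) a multi-day irradiance trace, fits the Markov
#' predictor on the training days, then runs the perfect-knowledge baseline,
#' the prediction-based receding-horizon controller, and the threshold
#' heuristic on every evaluation day. Returns per-day and cumulative cost
#' summaries with percent increases over the baseline, mirroring a
#' day-by-day cost comparison table.
#'
#' @param preset a [weather_preset()], used when `trace` is `NULL`.
#' @param n_train,n_eval training and evaluation day counts.
#' @param seed integer seed for weather generation.
#' @param prices per-step price vector (see [price_profile_fixed()] /
#'   [price_profile_variable()]); defaults to the fixed tariff.
#' @param params a [light_response_params()].
#' @param period a [photoperiod_spec()]; defaults to the preset's window.
#' @param led a [led_spec()].
#' @param spec a [conversion_spec()].
#' @param oracle run the predictive controller with the true future instead
#'   of Markov forecasts.
#' @param threshold_ppfd heuristic threshold override.
#' @param trace optional pre-generated [irradiance_trace()] with
#'   `n_train + n_eval` days (overrides `preset`/`seed` generation).
#' @param model optional pre-fitted [fit_sunlight_model()].
#' @param predictor list of predictor settings passed to
#'   [fit_sunlight_model()] (`n_bins`, `alpha`, `per_step`, `bin_value`).
#' @return object of class `season_result`: `daily` (data.frame with one row
#'   per evaluation day: costs in cents/m2 and percent increases),
#'   `cumulative` (one-row data.frame of summed costs and the increases
#'   recomputed from the sums), `days` (list of per-day `day_result`
#'   triples), `model`.
#' @export
simulate_season <- function(preset = weather_preset("winter_athens"),
                            n_train = 30, n_eval = 5, seed = 1,
                            prices = NULL,
                            params = crop_preset("green_towers"),
                            period = NULL, led = led_spec(),
                            spec = NULL, oracle = FALSE,
                            threshold_ppfd = NULL, trace = NULL,
                            model = NULL,
                            predictor = list()) {
  if (is.null(period))
    period <- photoperiod_spec(start_time = preset$photoperiod_start)
  if (is.null(prices)) prices <- price_profile_fixed(period = period)
  if (is.null(spec))
    spec <- conversion_spec(efficacy = led$efficacy,
                            step_hours = period$step_seconds / 3600)
  stopifnot(length(prices) == period$n_steps)
  if (is.null(trace))
    trace <- generate_days(preset, n_train + n_eval, seed, period)
  split <- split_train_eval(trace, n_train)
  if (is.null(model) && !oracle)
    model <- do.call(fit_sunlight_model, c(list(split$train), predictor))
  ev <- trace_matrix(split$eval)

  days <- vector("list", nrow(ev))
  rows <- vector("list", nrow(ev))
  for (d in seq_len(nrow(ev))) {
    sun <- ev[d, ]
    base <- run_baseline(sun, prices, params, period, led, spec)
    pred <- run_predictive(sun, model, prices, params, period, led, spec,
                           oracle = oracle)
    heur <- run_heuristic(sun, prices, params, period, led, spec,
                          threshold_ppfd)
    days[[d]] <- list(baseline = base, predictive = pred, heuristic = heur)
    rows[[d]] <- data.frame(
      day = d,
      sun_dli = base$sun_dli,
      baseline_cost = base$cost_cents,
      predictive_cost = pred$cost_cents,
      heuristic_cost = heur$cost_cents,
      predictive_increase_pct = percent_increase(pred$cost_cents,
                                                 base$cost_cents),
      heuristic_increase_pct = percent_increase(heur$cost_cents,
                                                base$cost_cents),
      baseline_dpi = base$dpi, predictive_dpi = pred$dpi,
      heuristic_dpi = heur$dpi,
      baseline_feasible = base$feasible,
      predictive_feasible = pred$feasible)
  }
  daily <- do.call(rbind, rows)
  cum <- data.frame(
    baseline_cost = sum(daily$baseline_cost),
    predictive_cost = sum(daily$predictive_cost),
    heuristic_cost = sum(daily$heuristic_cost))
  cum$predictive_increase_pct <-
    percent_increase(cum$predictive_cost, cum$baseline_cost)
  cum$heuristic_increase_pct <-
    percent_increase(cum$heuristic_cost, cum$baseline_cost)
  structure(list(daily = daily, cumulative = cum, days = days,
                 model = model, preset = preset, seed = seed),
            class = "season_result")
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf("Season simulation: %d evaluation day(s)%s\n",
              nrow(x$daily),
              if (!is.null(x$preset)) paste0(" [", x$preset$name, "]")
              else ""))
  cat(sprintf(
    "  cumulative cost (cents/m2): baseline %.2f, predictive %.2f (+%.2f%%), heuristic %.2f (+%.2f%%)\n",
    x$cumulative$baseline_cost, x$cumulative$predictive_cost,
    x$cumulative$predictive_increase_pct, x$cumulative$heuristic_cost,
    x$cumulative$heuristic_increase_pct))
  invisible(x)
}

#' Write season results to CSV
#'
#' `*_steps.csv` holds one row per (day, controller, step);
#' `*_daily.csv` the per-day summary plus a cumulative row whose percent
#' increases are recomputed from the summed costs.
#'
#' @param result a `season_result`.
#' @param out_dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_season_csv <- function(result, out_dir, prefix = "season") {
  stopifnot(inherits(result, "season_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  steps <- do.call(rbind, lapply(seq_along(result$days), function(d) {
    do.call(rbind, lapply(result$days[[d]], function(r)
      cbind(day = d, controller = r$controller, r$steps)))
  }))
  p1 <- file.path(out_dir, paste0(prefix, "_steps.csv"))
  utils::write.csv(steps, p1, row.names = FALSE, quote = FALSE)
  daily <- result$daily
  cum <- result$cumulative
  cum_row <- daily[1, ]; cum_row[] <- NA
  cum_row$day <- NA
  for (nm in names(cum)) cum_row[[nm]] <- cum[[nm]]
  p2 <- file.path(out_dir, paste0(prefix, "_daily.csv"))
  utils::write.csv(rbind(daily, cum_row), p2, row.names = FALSE,
                   quote = FALSE)
  invisible(c(p1, p2))
}

#' Load a structured run configuration
#'
#' YAML schema (all blocks optional, with package defaults):
#' \preformatted{
#' crop: green_towers            # or a, k, dpi_target
#' photoperiod: {start: "04:30", hours: 16, step_seconds: 900}
#' led: {etr_cap: 86.21, efficacy: 2.9}
#' price: {kind: fixed, price: 13.19}    # or kind: variable, file: path
#' weather: {preset: winter_athens, seed: 1, n_train: 30, n_eval: 5}
#' predictor: {n_bins: 10, alpha: 1}
#' heuristic_threshold: 203.2            # optional override
#' }
#'
#' @param path YAML file.
#' @return list of resolved component objects (`params`, `period`, `led`,
#'   `spec`, `prices`, `preset`, `seed`, `n_train`, `n_eval`, `predictor`,
#'   `threshold_ppfd`).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  params <- if (is.null(cfg$crop)) crop_preset("green_towers")
    else if (is.character(cfg$crop)) crop_preset(cfg$crop)
    else light_response_params(cfg$crop$a, cfg$crop$k, cfg$crop$dpi_target)
  w <- cfg$weather
  preset <- weather_preset(if (is.null(w$preset)) "winter_athens"
                           else w$preset)
  pp <- cfg$photoperiod
  period <- photoperiod_spec(
    step_seconds = if (is.null(pp$step_seconds)) 900 else pp$step_seconds,
    photoperiod_hours = if (is.null(pp$hours)) 16 else pp$hours,
    start_time = if (is.null(pp$start)) preset$photoperiod_start
                 else pp$start)
  led <- led_spec(
    etr_cap = if (is.null(cfg$led$etr_cap)) 86.21 else cfg$led$etr_cap,
    efficacy = if (is.null(cfg$led$efficacy)) 2.9 else cfg$led$efficacy)
  spec <- conversion_spec(led$efficacy, period$step_seconds / 3600)
  pr <- cfg$price
  prices <- if (is.null(pr) || identical(pr$kind, "fixed")) {
    price_profile_fixed(if (is.null(pr$price)) 13.19 else pr$price, period)
  } else if (identical(pr$kind, "variable")) {
    price_profile_variable(pr$file, period)
  } else stop("price$kind must be 'fixed' or 'variable'")
  list(params = params, period = period, led = led, spec = spec,
       prices = prices, preset = preset,
       seed = if (is.null(w$seed)) 1L else as.integer(w$seed),
       n_train = if (is.null(w$n_train)) 30L else as.integer(w$n_train),
       n_eval = if (is.null(w$n_eval)) 5L else as.integer(w$n_eval),
       predictor = if (is.null(cfg$predictor)) list() else cfg$predictor,
       threshold_ppfd = cfg$heuristic_threshold)
}

#' Fit and serialize a sunlight model from a config
#'
#' Generates the training trace (preset + seed), fits the Markov model with
#' the configured predictor settings, and writes it as JSON.
#'
#' @param config path to a YAML config (see [load_run_config()]).
#' @param out_path output model file.
#' @param trace_csv optional irradiance CSV to train on instead of
#'   generated weather.
#' @return the fitted model, invisibly; writes `out_path`.
#' @export
fit_sunlight_from_config <- function(config, out_path,
                                     trace_csv = NULL) {
  cfg <- load_run_config(config)
  trace <- if (is.null(trace_csv)) {
    generate_days(cfg$preset, cfg$n_train, cfg$seed, cfg$period)
  } else read_irradiance_csv(trace_csv, cfg$period)
  model <- do.call(fit_sunlight_model, c(list(trace), cfg$predictor))
  write_sunlight_model(model, out_path)
  message(sprintf("fitted %d-bin model (%s) on %d day(s); edges [%s]",
                  model$n_bins,
                  if (model$per_step) "per-step" else "pooled",
                  model$n_training_days,
                  paste(sprintf("%.0f", model$bin_edges), collapse = ", ")))
  invisible(model)
}

#' Simulate a season from a config
#'
#' @param config path to a YAML config.
#' @param out_dir optional directory for step-level and daily CSV reports.
#' @param oracle feed the predictive controller the true future.
#' @return a `season_result`.
#' @export
simulate_from_config <- function(config, out_dir = NULL, oracle = FALSE) {
  cfg <- load_run_config(config)
  res <- simulate_season(
    preset = cfg$preset, n_train = cfg$n_train, n_eval = cfg$n_eval,
    seed = cfg$seed, prices = cfg$prices, params = cfg$params,
    period = cfg$period, led = cfg$led, spec = cfg$spec, oracle = oracle,
    threshold_ppfd = cfg$threshold_ppfd, predictor = cfg$predictor)
  if (!is.null(out_dir)) write_season_csv(res, out_dir)
  res
}

#' Plan one day's supplemental lighting from a config
#'
#' @param config path to a YAML config.
#' @param day_csv irradiance CSV containing exactly one day.
#' @param controller `"baseline"` or `"heuristic"` (predictive planning
#'   needs the step-by-step loop of [simulate_from_config()]).
#' @param out_path optional per-step plan CSV (step, supplemental PPFD,
#'   duty cycle).
#' @return a `day_result`.
#' @export
plan_day_from_config <- function(config, day_csv,
                                 controller = c("baseline", "heuristic"),
                                 out_path = NULL) {
  controller <- match.arg(controller)
  cfg <- load_run_config(config)
  trace <- read_irradiance_csv(day_csv, cfg$period)
  m <- trace_matrix(trace)
  if (nrow(m) != 1L) stop("day_csv must contain exactly one day")
  if (ncol(m) != cfg$period$n_steps)
    stop("day has ", ncol(m), " steps; expected ", cfg$period$n_steps)
  sun <- m[1, ]
  res <- switch(controller,
    baseline = run_baseline(sun, cfg$prices, cfg$params, cfg$period,
                            cfg$led, cfg$spec),
    heuristic = run_heuristic(sun, cfg$prices, cfg$params, cfg$period,
                              cfg$led, cfg$spec, cfg$threshold_ppfd))
  if (!is.null(out_path))
    utils::write.csv(res$steps[, c("step", "supplemental_ppfd",
                                   "duty_cycle")],
                     out_path, row.names = FALSE, quote = FALSE)
  res
}
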