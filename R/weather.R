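#' Synthetic greenhouse weather presets
#'
#' Parameter bundles for the seeded irradiance generator. A day is a
#' half-sine clear-sky PPFD profile multiplied by (i) a persistent 3-state
#' cloud attenuation process simulated at 3-min resolution, (ii) a per-day
#' lognormal amplitude factor (slow weather-system variability the fast
#' chain alone under-produces), and (iii) the greenhouse transmission
#' fraction. The two shipped presets are calibrated by long-run Monte Carlo
#' so that their 1000-day DLI distributions match the two experimental
#' regimes the package emulates: `winter_athens` (low, fairly stable light;
#' DLI 2.22 +/- 0.6 mol m-2 d-1 under shade) and `spring_athens` (high,
#' strongly variable light; DLI 7.45 +/- 3.11 mol m-2 d-1 under shade).
#' Peak values are effective (shade-cloth-included) calibration constants,
#' not astronomical clear-sky values.
#'
#' @param name `"winter_athens"` or `"spring_athens"`.
#' @return object of class `weather_preset`.
#' @export
weather_preset <- function(name = "winter_athens") {
  presets <- list(
    winter_athens = list(
      name = "winter_athens",
      clear_sky_peak_ppfd = 412,
      transmission = 0.40,
      day_length_hours = 10,
      cloud_persistence = 0.95,
      attenuation_levels = c(clear = 1.0, partly = 0.55, overcast = 0.25),
      day_amplitude_sd = 0.14,
      target_dli_mean = 2.22,
      target_dli_sd = 0.6,
      photoperiod_start = "04:30"),
    spring_athens = list(
      name = "spring_athens",
      clear_sky_peak_ppfd = 1220,
      transmission = 0.40,
      day_length_hours = 13,
      cloud_persistence = 0.985,
      attenuation_levels = c(clear = 1.0, partly = 0.45, overcast = 0.15),
      day_amplitude_sd = 0.17,
      target_dli_mean = 7.45,
      target_dli_sd = 3.11,
      photoperiod_start = "05:00"))
  if (!name %in% names(presets))
    stop("unknown weather preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")")
  p <- presets[[name]]
  stopifnot(p$transmission > 0, p$transmission <= 1,
            all(p$attenuation_levels > 0), all(p$attenuation_levels <= 1))
  structure(p, class = "weather_preset")
}

#' @export
print.weather_preset <- function(x, ...) {
  cat(sprintf(
    "Weather preset '%s': peak %g umol m-2 s-1, %g h daylight, transmission %g\n  target DLI %g +/- %g mol m-2 d-1\n",
    x$name, x$clear_sky_peak_ppfd, x$day_length_hours, x$transmission,
    x$target_dli_mean, x$target_dli_sd))
  invisible(x)
}

# tridiagonal clear <-> partly <-> overcast chain; stationary (1/4, 1/2, 1/4)
cloud_chain_matrix <- function(p) {
  rbind(c(p, 1 - p, 0),
        c((1 - p) / 2, p, (1 - p) / 2),
        c(0, 1 - p, p))
}

#' Generate seeded multi-day synthetic irradiance
#'
#' Simulates greenhouse-level PPFD at 3-min resolution and averages each
#' block of five samples to the 15-min control step, emulating a quantum
#' sensor polled every three minutes. Zero outside daylight hours; daylight
#' is centred in the photoperiod window. Deterministic given `seed` (the
#' caller's RNG state is preserved).
#'
#' @param preset a [weather_preset()].
#' @param n_days number of days, >= 1.
#' @param seed integer seed.
#' @param period a [photoperiod_spec()]; its step length must be a multiple
#'   of the 180-s sampling interval.
#' @param keep_fine if `TRUE`, attach the 3-min sample matrix as attribute
#'   `fine` (days x fine-steps).
#' @return an [irradiance_trace()] with `n_days` days of `period$n_steps`
#'   steps.
#' @export
generate_days <- function(preset, n_days, seed,
                          period = photoperiod_spec(
                            start_time = preset$photoperiod_start),
                          keep_fine = FALSE) {
  stopifnot(inherits(preset, "weather_preset"), n_days >= 1)
  fine_sec <- 180
  ratio <- period$step_seconds / fine_sec
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("step_seconds must be a multiple of ", fine_sec, " s")
  ratio <- as.integer(round(ratio))
  nf <- period$n_steps * ratio

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  # clear-sky half-sine over daylight, centred in the photoperiod
  t_mid <- (seq_len(nf) - 0.5) * fine_sec / 3600           # hours into window
  centre <- period$photoperiod_hours / 2
  L <- preset$day_length_hours
  phase <- (t_mid - (centre - L / 2)) / L
  clear <- ifelse(phase > 0 & phase < 1, sin(pi * phase), 0)

  P <- cloud_chain_matrix(preset$cloud_persistence)
  stationary <- c(0.25, 0.5, 0.25)
  lv <- preset$attenuation_levels
  sig <- preset$day_amplitude_sd

  fine <- matrix(0, n_days, nf)
  for (d in seq_len(n_days)) {
    amp <- exp(stats::rnorm(1, -sig^2 / 2, sig))
    state <- sample.int(3L, 1L, prob = stationary)
    att <- numeric(nf)
    for (j in seq_len(nf)) {
      att[j] <- lv[state]
      state <- sample.int(3L, 1L, prob = P[state, ])
    }
    fine[d, ] <- preset$clear_sky_peak_ppfd * preset$transmission *
      amp * clear * att
  }
  coarse <- t(apply(fine, 1L, function(r)
    colMeans(matrix(r, nrow = ratio))))
  if (n_days == 1L) coarse <- matrix(coarse, 1L)
  tr <- irradiance_trace(coarse, step_seconds = period$step_seconds)
  if (keep_fine) attr(tr, "fine") <- fine
  tr
}

#' Split a trace into training and evaluation days
#'
#' Deterministic prefix split: the first `n_train` days train the predictor,
#' the rest are held out for controller evaluation.
#'
#' @param trace an [irradiance_trace()].
#' @param n_train number of training days; must be < number of days.
#' @return list with elements `train` and `eval`, both [irradiance_trace()]s
#'   (eval days renumbered from 1).
#' @export
split_train_eval <- function(trace, n_train) {
  stopifnot(inherits(trace, "irradiance_trace"))
  days <- sort(unique(trace$day))
  if (n_train < 1 || n_train >= length(days))
    stop("n_train must be in [1, n_days - 1]")
  tr_days <- days[seq_len(n_train)]
  ev_days <- days[-seq_len(n_train)]
  ss <- attr(trace, "step_seconds")
  renum <- function(df) {
    df$day <- as.integer(factor(df$day))
    irradiance_trace(df, step_seconds = ss)
  }
  list(train = renum(trace[trace$day %in% tr_days, , drop = FALSE]),
       eval = renum(trace[trace$day %in% ev_days, , drop = FALSE]))
}
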