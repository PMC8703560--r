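#' Irradiance trace container
#'
#' A multi-day, equally spaced per-step sunlight PPFD record (the greenhouse
#' `s_t` series). Stored long: one row per (day, step).
#'
#' @param ppfd numeric matrix (days x steps) or long data.frame with columns
#'   `day`, `step`, `ppfd`.
#' @param step_seconds spacing of steps, seconds.
#' @return data.frame of class `irradiance_trace` with columns `day`
#'   (1-based ordinal), `step` (1..T), `ppfd`, and attribute `step_seconds`.
#' @export
irradiance_trace <- function(ppfd, step_seconds = 900) {
  if (is.matrix(ppfd)) {
    df <- data.frame(
      day = rep(seq_len(nrow(ppfd)), each = ncol(ppfd)),
      step = rep(seq_len(ncol(ppfd)), times = nrow(ppfd)),
      ppfd = as.vector(t(ppfd)))
  } else {
    stopifnot(is.data.frame(ppfd),
              all(c("day", "step", "ppfd") %in% names(ppfd)))
    df <- ppfd[order(ppfd$day, ppfd$step), c("day", "step", "ppfd")]
    row.names(df) <- NULL
  }
  if (any(!is.finite(df$ppfd)) || any(df$ppfd < 0))
    stop("PPFD values must be finite and non-negative")
  steps_per_day <- table(df$day)
  if (length(unique(steps_per_day)) != 1L)
    stop("every day must have the same number of steps")
  structure(df, step_seconds = step_seconds, class = c("irradiance_trace",
                                                       "data.frame"))
}

#' @export
print.irradiance_trace <- function(x, ...) {
  T <- max(x$step)
  cat(sprintf("Irradiance trace: %d day(s) x %d steps of %g s\n",
              length(unique(x$day)), T, attr(x, "step_seconds")))
  NextMethod()
}

#' Trace as a days-by-steps matrix
#' @param trace an [irradiance_trace()].
#' @return numeric matrix, one row per day.
#' @export
trace_matrix <- function(trace) {
  stopifnot(inherits(trace, "irradiance_trace"))
  days <- sort(unique(trace$day))
  T <- max(trace$step)
  m <- matrix(NA_real_, length(days), T)
  for (i in seq_along(days)) {
    d <- trace[trace$day == days[i], ]
    m[i, d$step] <- d$ppfd
  }
  if (anyNA(m)) stop("trace has missing (day, step) combinations")
  m
}

#' Read / write irradiance CSV
#'
#' CSV dialect: columns `timestamp` (ISO 8601 local, e.g.
#' `2021-01-14T04:30:00`) and `ppfd_umol_m2_s`. Rows are assigned to days by
#' calendar date and to steps by offset from the photoperiod start.
#'
#' @param path file path.
#' @param period a [photoperiod_spec()] giving step length and start time.
#' @return an [irradiance_trace()].
#' @export
read_irradiance_csv <- function(path, period = photoperiod_spec()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "ppfd_umol_m2_s") %in% names(df)))
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in ", path)
  date <- as.Date(ts)
  day <- as.integer(factor(date, levels = sort(unique(date))))
  secs <- as.numeric(ts) - as.numeric(as.POSIXct(paste0(date, "T00:00:00"),
    format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  off <- secs - period$start_hour * 3600
  step <- off / period$step_seconds + 1
  if (any(abs(step - round(step)) > 1e-6))
    stop("timestamps are not aligned to ", period$step_seconds,
         " s steps from ", period$start_time)
  step <- as.integer(round(step))
  if (any(step < 1L) || any(step > period$n_steps))
    stop("timestamps fall outside the ", period$photoperiod_hours,
         " h photoperiod starting ", period$start_time)
  irradiance_trace(data.frame(day = day, step = step,
                              ppfd = df$ppfd_umol_m2_s),
                   step_seconds = period$step_seconds)
}

#' @rdname read_irradiance_csv
#' @param trace an [irradiance_trace()] to write.
#' @param start_date calendar date of day 1 (class `Date` or string).
#' @export
write_irradiance_csv <- function(trace, path, period = photoperiod_spec(),
                                 start_date = as.Date("2021-01-01")) {
  stopifnot(inherits(trace, "irradiance_trace"))
  start_date <- as.Date(start_date)
  secs <- period$start_hour * 3600 + (trace$step - 1) * period$step_seconds
  ts <- sprintf("%sT%02d:%02d:%02d",
                format(start_date + (trace$day - 1)),
                secs %/% 3600, (secs %% 3600) %/% 60, secs %% 60)
  utils::write.csv(data.frame(timestamp = ts, ppfd_umol_m2_s = trace$ppfd),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Discretize PPFD into a bin index
#'
#' Half-open equal-rank binning `[edge_i, edge_{i+1})`; the top bin is closed
#' above. Values outside the edge range are clamped into the boundary bin
#' with a warning.
#'
#' @param ppfd PPFD value(s).
#' @param bin_edges ascending breakpoints of length `n_bins + 1`.
#' @return integer bin index (1-based), vectorised.
#' @export
discretize <- function(ppfd, bin_edges) {
  stopifnot(is.numeric(bin_edges), length(bin_edges) >= 2L,
            !is.unsorted(bin_edges, strictly = TRUE))
  n_bins <- length(bin_edges) - 1L
  if (any(ppfd < bin_edges[1L]) || any(ppfd > bin_edges[length(bin_edges)])) {
    warning("PPFD outside bin range; clamped to boundary bin")
    ppfd <- pmin(pmax(ppfd, bin_edges[1L]), bin_edges[length(bin_edges)])
  }
  idx <- findInterval(ppfd, bin_edges, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), n_bins)
}

#' Fit a Markov sunlight transition model
#'
#' Discretizes a multi-day training trace into PPFD bins and estimates
#' step-to-step transition probabilities by add-alpha-smoothed counting of
#' consecutive within-day bin pairs. With 10 or more training days a separate
#' transition matrix is fitted per step-of-day transition (time-inhomogeneous
#' chain); with fewer, a single matrix pooled over all steps is used. The
#' per-step arithmetic mean over training days is kept as the
#' before-sunrise forecast.
#'
#' @param trace an [irradiance_trace()] with at least two complete days.
#' @param n_bins number of equal-width PPFD bins over `[0, max(trace)]`.
#' @param alpha add-alpha smoothing pseudo-count per transition cell. The
#'   default `1/n_bins` puts one observation's worth of pseudo-mass on each
#'   row regardless of bin count, enough to keep unseen transitions from
#'   becoming absorbing zeros without flattening the sparse per-step
#'   matrices (a full Laplace `alpha = 1` adds `n_bins` pseudo-counts per
#'   row, which with per-step matrices typically outweighs the data and
#'   destroys forecast skill).
#' @param per_step `"auto"` (per-step matrices iff >= 10 training days),
#'   `TRUE`, or `FALSE`.
#' @param bin_value `"midpoint"` (default) or `"mean"` (training-data mean of
#'   observations falling in each bin; empty bins fall back to midpoints).
#' @return object of class `transition_model`: `bin_edges`, `bin_values`,
#'   `transition` (list of row-stochastic matrices, length T-1 or 1),
#'   `per_step` flag, `day_start_mean` (length T), `n_steps`, `step_seconds`.
#' @export
fit_sunlight_model <- function(trace, n_bins = 10, alpha = 1 / n_bins,
                               per_step = "auto",
                               bin_value = c("midpoint", "mean")) {
  stopifnot(inherits(trace, "irradiance_trace"), n_bins >= 2, alpha >= 0)
  bin_value <- match.arg(bin_value)
  m <- trace_matrix(trace)
  if (nrow(m) < 2L) stop("need at least 2 training days")
  T <- ncol(m)
  top <- max(m)
  if (top <= 0) stop("training trace is identically zero")
  edges <- seq(0, top, length.out = n_bins + 1L)
  values <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  if (bin_value == "mean") {
    b <- discretize(as.vector(m), edges)
    mv <- tapply(as.vector(m), factor(b, levels = seq_len(n_bins)), mean)
    values <- ifelse(is.na(mv), values, mv)
    names(values) <- NULL
  }
  if (identical(per_step, "auto")) per_step <- nrow(m) >= 10L
  bins <- matrix(discretize(as.vector(m), edges), nrow(m), T)

  # rows of states never observed leaving (possible only with alpha = 0)
  # fall back to self-persistence: they are unreachable from the data, but
  # a fresh measurement can still land in one.
  count_norm <- function(from, to) {
    cnt <- matrix(0, n_bins, n_bins)
    for (i in seq_along(from)) cnt[from[i], to[i]] <- cnt[from[i], to[i]] + 1
    cnt <- cnt + alpha
    rs <- rowSums(cnt)
    empty <- rs == 0
    if (any(empty)) {
      cnt[empty, ] <- diag(n_bins)[empty, , drop = FALSE]
      rs[empty] <- 1
    }
    cnt / rs
  }
  transition <- if (per_step) {
    lapply(seq_len(T - 1L), function(t) count_norm(bins[, t], bins[, t + 1L]))
  } else {
    list(count_norm(as.vector(bins[, -T]), as.vector(bins[, -1L])))
  }
  structure(list(bin_edges = edges, bin_values = values,
                 transition = transition, per_step = per_step,
                 day_start_mean = colMeans(m), n_steps = T,
                 step_seconds = attr(trace, "step_seconds"),
                 n_bins = as.integer(n_bins), alpha = alpha,
                 n_training_days = nrow(m)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf(
    "Markov sunlight model: %d bins over [0, %.1f], %s, %d training day(s)\n",
    x$n_bins, max(x$bin_edges),
    if (x$per_step) sprintf("%d per-step matrices", length(x$transition))
    else "1 pooled matrix", x$n_training_days))
  invisible(x)
}

step_matrix <- function(model, t) {
  if (model$per_step) model$transition[[t]] else model$transition[[1L]]
}

#' Before-sunrise full-day forecast
#'
#' With no measurement yet available, the forecast for every step of the day
#' is the per-step historical mean of the training days.
#'
#' @param model a fitted [fit_sunlight_model()] object.
#' @return numeric vector of expected PPFD, length `n_steps`.
#' @export
predict_day <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  model$day_start_mean
}

#' Forecast the remaining day from the latest measurement
#'
#' Conditions the chain on the current measurement: the state distribution is
#' initialised as the indicator of the measurement's bin and propagated
#' through the (per-step) transition matrices; each future step's forecast is
#' the probability-weighted mean of the bin representative values.
#'
#' @param model a fitted [fit_sunlight_model()] object.
#' @param current_step step index of the measurement, 1..T-1.
#' @param current_ppfd measured PPFD at `current_step`.
#' @return expected PPFD for steps `current_step + 1` .. `T`
#'   (length `T - current_step`).
#' @export
predict_remaining <- function(model, current_step, current_ppfd) {
  stopifnot(inherits(model, "transition_model"),
            current_step >= 1, current_step < model$n_steps)
  p <- numeric(model$n_bins)
  p[discretize(current_ppfd, model$bin_edges)] <- 1
  out <- numeric(model$n_steps - current_step)
  for (t in seq.int(current_step, model$n_steps - 1L)) {
    p <- as.vector(p %*% step_matrix(model, t))
    out[t - current_step + 1L] <- sum(p * model$bin_values)
  }
  out
}

#' Serialize / load a transition model
#'
#' Portable JSON schema: `bin_edges`, `bin_values`, `transition` (list of
#' matrices), `per_step`, `day_start_mean`, `n_steps`, `step_seconds`,
#' `n_bins`, `alpha`, `n_training_days`.
#'
#' @param model a `transition_model`.
#' @param path output file.
#' @export
write_sunlight_model <- function(model, path) {
  stopifnot(inherits(model, "transition_model"))
  x <- unclass(model)
  x$transition <- lapply(x$transition, function(m) unname(as.matrix(m)))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sunlight_model
#' @export
read_sunlight_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$transition <- if (is.list(x$transition)) {
    lapply(x$transition, as.matrix)
  } else if (is.array(x$transition) && length(dim(x$transition)) == 3L) {
    lapply(seq_len(dim(x$transition)[1L]), function(i)
      matrix(x$transition[i, , ], dim(x$transition)[2L]))
  } else list(as.matrix(x$transition))
  x$n_bins <- as.integer(x$n_bins)
  x$n_steps <- as.integer(x$n_steps)
  structure(x, class = "transition_model")
}
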