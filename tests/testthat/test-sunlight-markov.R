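test_that("discretize uses half-open bins with a closed top bin", {
  edges <- c(0, 100, 200)
  expect_identical(discretize(0, edges), 1L)
  expect_identical(discretize(150, edges), 2L)
  expect_identical(discretize(100, edges), 2L)
  expect_identical(discretize(200, edges), 2L)   # top edge closed above
  expect_warning(out <- discretize(250, edges), "clamped")
  expect_identical(out, 2L)
  expect_warning(out <- discretize(-5, edges), "clamped")
  expect_identical(out, 1L)
})

test_that("transition counting matches a hand count and rows normalize", {
  # one day with bin sequence 1,1,2,2 (2 bins): pairs (1->1),(1->2),(2->2)
  m <- rbind(c(10, 40, 160, 190), c(10, 40, 160, 190))
  tr <- irradiance_trace(m, step_seconds = 900)
  fit <- fit_sunlight_model(tr, n_bins = 2, alpha = 0, per_step = FALSE)
  expect_equal(fit$transition[[1]],
               rbind(c(0.5, 0.5), c(0, 1)))
  expect_equal(fit$bin_edges, c(0, 95, 190))
  expect_equal(fit$bin_values, c(47.5, 142.5))

  # any fit: every row of every matrix sums to 1
  set.seed(8)
  tr2 <- irradiance_trace(matrix(runif(12 * 16, 0, 500), 12, 16), 900)
  fit2 <- fit_sunlight_model(tr2, n_bins = 6)
  expect_true(fit2$per_step)           # >= 10 days -> per-step matrices
  expect_length(fit2$transition, 15)
  for (P in fit2$transition)
    expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-12)
  fit3 <- fit_sunlight_model(tr2, n_bins = 6, per_step = FALSE)
  expect_length(fit3$transition, 1)

  expect_error(fit_sunlight_model(
    irradiance_trace(matrix(1:4, 1), 900)), "2 training days")
})

test_that("before-sunrise forecast is the per-step historical mean", {
  p <- c(0, 50, 200, 120); q <- c(0, 150, 400, 100)
  tr <- irradiance_trace(rbind(p, q), 900)
  fit <- fit_sunlight_model(tr, n_bins = 4)
  expect_equal(predict_day(fit), (p + q) / 2)
  expect_true(all(predict_day(fit) >= 0))

  # identical training days: forecast is exactly that day
  tr1 <- irradiance_trace(rbind(p, p, p), 900)
  expect_equal(predict_day(fit_sunlight_model(tr1, n_bins = 3)), p)
})

test_that("expectation propagation matches exhaustive path enumeration", {
  set.seed(21)
  for (n_bins in 2:3) {
    for (rep in 1:5) {
      T <- 5
      tr <- irradiance_trace(matrix(runif(4 * T, 0, 300), 4, T), 900)
      fit <- fit_sunlight_model(tr, n_bins = n_bins, per_step = TRUE)
      start <- sample(seq_len(T - 1), 1)
      ppfd <- runif(1, 0, 300)
      got <- predict_remaining(fit, start, ppfd)
      mats <- fit$transition[start:(T - 1)]
      want <- enum_markov_expect(mats, discretize(ppfd, fit$bin_edges),
                                 fit$bin_values, T - start)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("forecasts stay in the bin-value range and respect stationarity", {
  # hand-built 2-bin chain with uniform stationary distribution
  model <- structure(list(
    bin_edges = c(0, 100, 200), bin_values = c(0, 100),
    transition = list(rbind(c(0.5, 0.5), c(0.5, 0.5))),
    per_step = FALSE, day_start_mean = rep(50, 8), n_steps = 8L,
    step_seconds = 900, n_bins = 2L, alpha = 0, n_training_days = 2L),
    class = "transition_model")
  expect_equal(predict_remaining(model, 1, 180), rep(50, 7))
  expect_equal(predict_remaining(model, 3, 0), rep(50, 5))

  # identity matrix: forecast pinned at the current bin's value
  model$transition <- list(diag(2))
  expect_equal(predict_remaining(model, 1, 150), rep(100, 7))

  set.seed(33)
  tr <- irradiance_trace(matrix(runif(6 * 10, 0, 600), 6, 10), 900)
  fit <- fit_sunlight_model(tr, n_bins = 5)
  f <- predict_remaining(fit, 2, 400)
  expect_true(all(f >= min(fit$bin_values) - 1e-12))
  expect_true(all(f <= max(fit$bin_values) + 1e-12))
})

test_that("model survives a JSON round trip", {
  set.seed(5)
  tr <- irradiance_trace(matrix(runif(12 * 8, 0, 500), 12, 8), 900)
  fit <- fit_sunlight_model(tr, n_bins = 4)
  path <- tempfile(fileext = ".json")
  write_sunlight_model(fit, path)
  back <- read_sunlight_model(path)
  expect_equal(back$bin_edges, fit$bin_edges)
  expect_equal(back$bin_values, fit$bin_values)
  expect_equal(back$day_start_mean, fit$day_start_mean)
  expect_equal(length(back$transition), length(fit$transition))
  for (i in seq_along(fit$transition))
    expect_equal(unname(back$transition[[i]]), unname(fit$transition[[i]]),
                 tolerance = 1e-12)
  expect_equal(predict_remaining(back, 2, 250),
               predict_remaining(fit, 2, 250), tolerance = 1e-12)
})

test_that("irradiance CSV round trip preserves the trace", {
  set.seed(6)
  per <- photoperiod_spec()
  tr <- irradiance_trace(matrix(round(runif(2 * 64, 0, 400), 3), 2, 64), 900)
  path <- tempfile(fileext = ".csv")
  write_irradiance_csv(tr, path, per)
  back <- read_irradiance_csv(path, per)
  expect_equal(back$ppfd, tr$ppfd)
  expect_equal(back$day, tr$day)
  expect_equal(back$step, tr$step)
})
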