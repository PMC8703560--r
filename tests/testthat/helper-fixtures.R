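# Shared fixtures and independent oracles.

gt_params <- crop_preset("green_towers")
per64 <- photoperiod_spec()                      # 900 s x 64 = 16 h

# Exhaustive grid-search oracle for the horizon optimization: enumerates all
# per-step supplemental ETR vectors on a regular grid, keeps those meeting
# the ETR-sum requirement, and returns the cheapest objective value. Kept
# independent of solve_lighting (direct objective evaluation).
brute_force_grid <- function(input, grid_step = 0.5) {
  T <- length(input$prices)
  a <- input$params$a; k <- input$params$k
  cap <- pmin(input$etr_cap, a * (1 - 1e-6) - input$sun_etr)
  req <- input$dpi_target / (input$step_seconds * 1e-6) -
    input$credit_etr_sum - sum(input$sun_etr)
  levels <- lapply(seq_len(T), function(t) seq(0, cap[t], by = grid_step))
  grid <- as.matrix(expand.grid(levels))
  ok <- rowSums(grid) >= req - 1e-9
  if (!any(ok)) return(list(feasible = FALSE))
  grid <- grid[ok, , drop = FALSE]
  obj <- as.vector(
    (log(a / (a - sweep(grid, 2, input$sun_etr, "+"))) / k -
       matrix(input$sun_ppfd, nrow(grid), T, byrow = TRUE)) %*%
      input$prices)
  i <- which.min(obj)
  list(feasible = TRUE, objective = obj[i], x = grid[i, ])
}

# Path-enumeration oracle for Markov expectation propagation: expected bin
# value h steps ahead as a sum over all bin paths weighted by their product
# probability.
enum_markov_expect <- function(matrices, start_bin, values, horizon) {
  n <- length(values)
  out <- numeric(horizon)
  paths <- list(list(bins = start_bin, p = 1))
  for (h in seq_len(horizon)) {
    P <- matrices[[min(h, length(matrices))]]
    new <- list()
    for (pa in paths) {
      last <- pa$bins[length(pa$bins)]
      for (b in seq_len(n)) {
        pr <- pa$p * P[last, b]
        if (pr > 0) new[[length(new) + 1L]] <-
            list(bins = c(pa$bins, b), p = pr)
      }
    }
    paths <- new
    out[h] <- sum(vapply(paths, function(pa)
      pa$p * values[pa$bins[length(pa$bins)]], numeric(1)))
  }
  out
}

# Small random horizon instance (T steps, modest cap so the grid oracle
# stays tractable).
random_instance <- function(T = 4, seed = 1, etr_cap = 10) {
  set.seed(seed)
  sun_ppfd <- runif(T, 0, 300)
  prices <- runif(T, 1, 30)
  # requirement between 20% and 90% of total supplemental capacity
  req_frac <- runif(1, 0.2, 0.9)
  sun_etr <- gt_params$a * (1 - exp(-gt_params$k * sun_ppfd))
  req <- sum(sun_etr) + req_frac * T * etr_cap
  dpi <- req * 900 * 1e-6
  p2 <- light_response_params(gt_params$a, gt_params$k, dpi)
  optimization_input(prices, sun_ppfd, p2, step_seconds = 900,
                     etr_cap = etr_cap)
}
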