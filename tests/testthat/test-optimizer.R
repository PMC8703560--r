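test_that("trivial horizon cases solve exactly", {
  p <- gt_params
  # requirement already met by credit: no supplemental light, zero objective
  inp <- optimization_input(rep(10, 4), rep(100, 4), p,
                            credit_etr_sum = 4000)
  plan <- solve_lighting(inp)
  expect_equal(plan$x_etr, rep(0, 4))
  expect_true(plan$feasible)
  expect_equal(plan$objective_value, 0, tolerance = 1e-9)

  # single step, binding constraint below the cap: x equals the requirement
  p40 <- light_response_params(p$a, p$k, 40 * 900 * 1e-6)
  plan1 <- solve_lighting(optimization_input(10, 0, p40, etr_cap = 86.21))
  expect_equal(plan1$x_etr, 40, tolerance = 1e-8)

  # constant price and sunlight: symmetric optimum spreads load equally
  pT <- light_response_params(p$a, p$k, 4 * 30 * 900 * 1e-6)
  plan4 <- solve_lighting(optimization_input(rep(5, 4), rep(50, 4), pT,
                                             etr_cap = 86.21))
  expect_equal(plan4$x_etr, rep(plan4$x_etr[1], 4), tolerance = 1e-7)
  # combined supply meets the requirement exactly (equal positive prices)
  req <- pT$dpi_target / (900 * 1e-6)
  expect_equal(sum(plan4$x_etr) + sum(etr_from_ppfd(rep(50, 4), p)), req,
               tolerance = 1e-6 * req)
})

test_that("free electricity absorbs the load up to its cap", {
  p <- gt_params
  # price vector (1,1,1,0), small requirement: only the free step supplies
  req_etr <- 8
  pr <- light_response_params(p$a, p$k, req_etr * 900 * 1e-6)
  inp <- optimization_input(c(1, 1, 1, 0), rep(0, 4), pr, etr_cap = 10)
  plan <- solve_lighting(inp)
  expect_equal(plan$x_etr, c(0, 0, 0, 8), tolerance = 1e-8)

  # requirement above the free step's cap: remainder goes to priced steps
  pr2 <- light_response_params(p$a, p$k, 14 * 900 * 1e-6)
  plan2 <- solve_lighting(optimization_input(c(1, 1, 1, 0), rep(0, 4), pr2,
                                             etr_cap = 10))
  expect_equal(plan2$x_etr[4], 10, tolerance = 1e-8)
  expect_equal(sum(plan2$x_etr), 14, tolerance = 1e-6)
})

test_that("infeasible horizons return the all-cap plan with shortfall", {
  p <- gt_params
  big <- light_response_params(p$a, p$k, 100 * 900 * 1e-6)
  inp <- optimization_input(c(2, 3), c(0, 0), big, etr_cap = 20)
  plan <- solve_lighting(inp)
  expect_false(plan$feasible)
  expect_equal(plan$x_etr, c(20, 20))
  expect_equal(plan$shortfall, 60, tolerance = 1e-9)
})

test_that("near-saturating sunlight reduces the step cap safely", {
  p <- gt_params
  sun <- c(2500, 0)   # sun ETR ~120.88, within 0.2 of the asymptote
  pr <- light_response_params(p$a, p$k, 40 * 900 * 1e-6)
  inp <- optimization_input(c(1, 1), sun, pr, etr_cap = 86.21)
  plan <- solve_lighting(inp)
  expect_true(all(plan$x_etr + inp$sun_etr < p$a))
  expect_true(all(is.finite(plan$x_ppfd)))
})

test_that("solver matches the exhaustive grid-search oracle on T=4", {
  worst <- 0
  for (seed in 1:12) {
    inp <- random_instance(T = 4, seed = seed, etr_cap = 10)
    plan <- solve_lighting(inp)
    oracle <- brute_force_grid(inp, grid_step = 0.5)
    expect_true(oracle$feasible)
    expect_true(plan$feasible)
    # solver can only be better than any grid point ...
    expect_lte(plan$objective_value, oracle$objective + 1e-6)
    # ... and the grid optimum is within the grid resolution of it
    slope <- max(inp$prices) /
      (inp$params$k * min(inp$params$a - inp$sun_etr - inp$etr_cap))
    expect_lte(oracle$objective - plan$objective_value,
               4 * 0.5 * slope + 1e-6)
    worst <- max(worst, oracle$objective - plan$objective_value)
  }
  expect_gte(worst, 0)
})

test_that("optimal cost responds monotonically to requirement and sunlight", {
  p <- gt_params
  base_dpi <- 30 * 4 * 900 * 1e-6
  cost_at <- function(dpi, sun) {
    pr <- light_response_params(p$a, p$k, dpi)
    solve_lighting(optimization_input(c(3, 8, 2, 6), sun, pr,
                                      etr_cap = 86.21))$objective_value
  }
  sun0 <- rep(30, 4)
  c1 <- cost_at(base_dpi, sun0)
  c2 <- cost_at(base_dpi * 1.3, sun0)
  c3 <- cost_at(base_dpi, rep(60, 4))
  expect_gte(c2, c1 - 1e-9)   # non-decreasing in the DPI target
  expect_lte(c3, c1 + 1e-9)   # non-increasing in sunlight
})

test_that("objective equals price-weighted supplemental PPFD", {
  p <- gt_params
  set.seed(13)
  sun <- runif(8, 0, 350)
  prices <- runif(8, 2, 25)
  inp <- optimization_input(prices, sun, p, etr_cap = 86.21)
  plan <- solve_lighting(inp)
  # zero plan has zero objective (inverse identity cancels the sun term)
  expect_equal(objective_cost(rep(0, 8), inp), 0, tolerance = 1e-9)
  # algebraic identity f = sum C_t * supplemental PPFD_t
  expect_equal(plan$objective_value, sum(prices * plan$x_ppfd),
               tolerance = 1e-8 * max(1, plan$objective_value))
  # linear in prices
  inp2 <- optimization_input(2 * prices, sun, p, etr_cap = 86.21)
  expect_equal(objective_cost(plan$x_etr, inp2),
               2 * objective_cost(plan$x_etr, inp), tolerance = 1e-10)
  expect_error(objective_cost(rep(121, 8), inp), "asymptote")
})

test_that("optimization input validates consistency", {
  p <- gt_params
  expect_error(optimization_input(c(-1, 2), c(0, 0), p), "non-negative")
  expect_error(optimization_input(c(1, 2), c(0, 0), p, etr_cap = 121),
               "etr_cap")
  expect_error(optimization_input(c(1, 2), c(0, 0), p,
                                  sun_etr = c(50, 50)), "inconsistent")
  inp <- optimization_input(c(1, 2), c(100, 200), p)
  expect_equal(inp$sun_etr, etr_from_ppfd(c(100, 200), p))
})
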