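test_that("ordering cost is fixed plus variable", {
  p <- table1_params()
  expect_equal(ordering_cost_per_cycle(77.46, p), 20 + 500 * 77.46)
  expect_equal(ordering_cost_per_cycle(0, p), 20)
  p0 <- table1_params(fixed_order_cost = 0, unit_order_cost = 0)
  expect_equal(ordering_cost_per_cycle(50, p0), 0)
})

test_that("uniform closed form agrees with exact quadrature on random instances", {
  set.seed(202)
  for (i in 1:100) {
    inst <- random_uniform_instance()
    closed <- uniform_annual_cost(inst$policy, inst$params, inst$dist)
    exact <- annual_cost_rate(inst$policy, inst$params, inst$dist,
                              mode = "exact")$annual_rate
    expect_equal(closed, exact, tolerance = 1e-8)
    # and both match an independently coded quadrature oracle
    expect_equal(exact, oracle_annual_cost(inst$policy, inst$params, inst$dist),
                 tolerance = 1e-8)
  }
})

test_that("shortage vanishes when the reorder point covers the whole support", {
  p <- table1_params()
  u <- table1_dist()
  pol <- rq_policy(80, 600 * 0.04)  # r = D b
  expect_equal(expected_shortage_per_cycle(pol, p, u), 0)
  pol2 <- rq_policy(80, 30)         # r > D b
  expect_equal(expected_shortage_per_cycle(pol2, p, u), 0)
  # zero unit shortage cost
  p0 <- table1_params(unit_shortage_cost = 0)
  expect_equal(expected_shortage_per_cycle(rq_policy(77, 20), p0, u), 0)
})

test_that("empty policy has zero holding; zero reorder point still pays shortage", {
  p <- table1_params()
  pol0 <- rq_policy(0, 0)
  expect_equal(expected_holding_per_cycle(pol0, p, table1_dist()), 0)
  # with r = 0 every cycle stocks out for the whole lead time:
  # C E[(DL)^2]/(2D) = C D E[L^2]/2, E[L^2] = (b^3-a^3)/(3(b-a))
  expect_equal(expected_shortage_per_cycle(pol0, p, table1_dist()),
               1000 * 600 * (0.04^3 - 0.01^3) / (3 * 0.03) / 2,
               tolerance = 1e-10)
})

test_that("near-degenerate lead time with C = 0 collapses to the safety-stock EOQ rate", {
  L0 <- 0.02
  eps <- 1e-7
  dist <- lead_time_uniform(L0 - eps, L0 + eps)
  p <- table1_params(unit_shortage_cost = 0)
  Q <- 77.46; r <- 23.58  # r/D = 0.0393 > L0: lot arrives with stock on hand
  cb <- annual_cost_rate(rq_policy(Q, r), p, dist, mode = "exact")
  D <- 600; h <- 4; A <- 20; K <- 500
  expect_equal(cb$annual_rate,
               D * A / Q + K * D + h * (Q / 2 + r - D * L0),
               tolerance = 1e-6)
})

test_that("annual rate equals per-cycle components over cycle time in both modes", {
  cases <- list(
    list(p = table1_params(), d = table1_dist(), pol = rq_policy(77.46, 23.58)),
    list(p = table2_params(), d = table2_dist(), pol = rq_policy(130.92, 69.08)))
  for (cs in cases) for (mode in c("exact", "paper")) {
    cb <- annual_cost_rate(cs$pol, cs$p, cs$d, mode = mode)
    expect_equal(cb$annual_rate,
                 (cb$holding_per_cycle + cb$shortage_per_cycle +
                    cb$ordering_per_cycle) / cb$cycle_time,
                 tolerance = 1e-10)
    expect_equal(cb$cycle_time, cs$pol$order_quantity / cs$p$demand_rate)
    expect_true(all(c(cb$holding_per_cycle, cb$shortage_per_cycle,
                      cb$ordering_per_cycle) >= 0))
  }
})

test_that("the annual cost is strictly convex in Q for fixed r", {
  for (cs in list(list(p = table1_params(), d = table1_dist(), r = 23.58),
                  list(p = table2_params(), d = table2_dist(), r = 69.08))) {
    Q <- seq(max(cs$r, 30), 140, length.out = 40)
    z <- vapply(Q, function(q)
      annual_cost_rate(rq_policy(q, cs$r), cs$p, cs$d, "paper")$annual_rate,
      numeric(1))
    expect_true(all(diff(z, differences = 2) > 0))
  }
})

test_that("shortage is nonincreasing in r and holding nondecreasing in Q", {
  p <- table1_params(); u <- table1_dist()
  r_grid <- seq(0, 24, length.out = 30)
  sh <- vapply(r_grid, function(r)
    expected_shortage_per_cycle(rq_policy(30, r), p, u), numeric(1))
  expect_true(all(diff(sh) <= 1e-12))
  q_grid <- seq(24, 120, length.out = 30)
  ho <- vapply(q_grid, function(q)
    expected_holding_per_cycle(rq_policy(q, 23.58), p, u), numeric(1))
  expect_true(all(diff(ho) >= -1e-12))
})

test_that("exponential exact closed antiderivative matches generic quadrature", {
  p <- table2_params(); e <- table2_dist()
  for (pol in list(rq_policy(130.92, 69.08), rq_policy(80, 40),
                   rq_policy(150, 0), rq_policy(60, 58.68))) {
    expect_equal(exponential_annual_cost(pol, p, e, mode = "exact"),
                 annual_cost_rate(pol, p, e, mode = "exact")$annual_rate,
                 tolerance = 1e-9)
  }
})

test_that("exponential shortage-group coefficients reproduce the published grouping", {
  co_sym <- exponential_coefficients(table2_params(), table2_dist(),
                                     signif_digits = NULL)
  # symbolic values computed inline from C^2 (DW/(lam f) + D^2/lam^2 + W^2/(2 f^2)) etc.
  C <- 1000; D <- 600; W <- 50; f <- 0.3; lam <- 40
  expect_equal(unname(co_sym["c0"]),
               C^2 * (D * W / (lam * f) + D^2 / lam^2 + W^2 / (2 * f^2)))
  expect_equal(unname(co_sym["c1"]), C^2 * (2 * D / lam + W / f))
  expect_equal(unname(co_sym["c2"]), C^2)
  co <- exponential_coefficients(table2_params(), table2_dist())
  expect_equal(unname(co), c(1.66e10, 1.97e8, 1e6))
})

test_that("published exponential objective value is reproduced at the reported point", {
  val <- exponential_annual_cost(rq_policy(130.92, 69.08), table2_params(),
                                 table2_dist(), mode = "paper")
  expect_equal(val, 892566.86, tolerance = 1e-6)
  # exact integration of the same instance disagrees with the published
  # grouping by design (documented inconsistency)
  ex <- annual_cost_rate(rq_policy(130.92, 69.08), table2_params(),
                         table2_dist(), "exact")$annual_rate
  expect_gt(abs(val - ex) / ex, 0.5)
})

test_that("a reorder point beyond the space horizon is rejected as infeasible", {
  p <- table1_params()
  r_too_big <- 600 * space_horizon(p) + 1
  expect_error(
    annual_cost_rate(rq_policy(r_too_big + 1, r_too_big), p, table1_dist(),
                     "exact"),
    class = "pharminv_infeasible")
})

test_that("uniform closed form flags which side condition failed", {
  p <- table1_params()
  u <- table1_dist()
  # r/D > b
  expect_error(uniform_annual_cost(rq_policy(80, 30), p, u), "r/D <= b")
  # a > r/D
  expect_error(uniform_annual_cost(rq_policy(80, 1), p, u), "a <= r/D")
  # b > M
  p_small <- table1_params(total_space = 3)  # M = 1/60 < b
  expect_error(uniform_annual_cost(rq_policy(9, 8), p_small, u),
               "b <= W/\\(fD\\)")
})
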