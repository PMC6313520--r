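test_that("service bounds invert the lead-time quantiles", {
  rb <- service_r_bounds(table2_params(), table2_dist())
  expect_equal(unname(rb["r_min"]), -600 / 40 * log(0.02), tolerance = 1e-10)
  expect_equal(unname(rb["r_max"]), -600 / 40 * log(0.01), tolerance = 1e-10)
  expect_equal(unname(rb), c(58.68, 69.08), tolerance = 1e-4)

  # uniform quantile at 98%
  rb_u <- service_r_bounds(table1_params(), table1_dist())
  expect_equal(unname(rb_u["r_min"]), 600 * (0.01 + 0.98 * 0.03))
  # no upper service bound: capped at D * min(b, M)
  expect_equal(unname(rb_u["r_max"]), 600 * 0.04)

  # lo ~ 0 pins r_min at the support minimum
  p0 <- table1_params(service_level_lo = 1e-12)
  expect_equal(unname(service_r_bounds(p0, table1_dist())["r_min"]), 600 * 0.01,
               tolerance = 1e-6)
})

test_that("shelf life caps the lot size through the lead-time quantile", {
  expect_equal(shelf_life_q_max(table1_params(), table1_dist()),
               600 * (0.25 - 0.04))  # hard bound b + Q/D <= S
  expect_equal(shelf_life_q_max(table2_params(), table2_dist()),
               600 * (1 / 3 - log(100) / 40), tolerance = 1e-10)
  expect_equal(shelf_life_q_max(table2_params(), table2_dist()), 130.92,
               tolerance = 1e-2)
  # shelf life at (or below) the quantile leaves no admissible lot
  p_short <- table1_params(shelf_life = 0.04)
  expect_error(shelf_life_q_max(p_short, table1_dist()),
               class = "pharminv_infeasible")
  # linear in S with slope D
  s <- c(0.1, 0.2, 0.3)
  q <- vapply(s, function(S) shelf_life_q_max(table1_params(shelf_life = S),
                                              table1_dist()), numeric(1))
  expect_equal(diff(q) / diff(s), c(600, 600))
})

test_that("Q*(r) reproduces the published closed forms and the EOQ limit", {
  expect_equal(optimal_q_given_r(23.58, table1_params(), table1_dist()),
               77.46, tolerance = 1e-2)
  # C = 0 reduces to sqrt(2DA/h)
  p0 <- table1_params(unit_shortage_cost = 0)
  expect_equal(optimal_q_given_r(23.58, p0, table1_dist()), sqrt(6000),
               tolerance = 1e-10)
  # exponential instance: unconstrained minimiser clamped by the shelf cap
  q2 <- optimal_q_given_r(69.08, table2_params(), table2_dist())
  expect_equal(q2, shelf_life_q_max(table2_params(), table2_dist()))
  expect_equal(q2, 130.92, tolerance = 1e-2)
})

test_that("Q*(r) equals the argmin of a dense Q-grid of the same objective", {
  cases <- list(
    list(p = table1_params(), d = table1_dist(), r = 23.58, mode = "paper"),
    list(p = table1_params(), d = table1_dist(), r = 23.58, mode = "exact"),
    list(p = table2_params(), d = table2_dist(), r = 60, mode = "paper"),
    list(p = table2_params(), d = table2_dist(), r = 60, mode = "exact"))
  for (cs in cases) {
    qstar <- optimal_q_given_r(cs$r, cs$p, cs$d, mode = cs$mode, clamp = FALSE)
    obj <- function(q) annual_cost_rate(rq_policy(q, cs$r), cs$p, cs$d,
                                        mode = cs$mode)$annual_rate
    # two-stage grid argmin oracle: coarse global pass, fine local pass
    coarse <- seq(max(cs$r, qstar / 3), qstar * 3, length.out = 200)
    q0 <- coarse[which.min(vapply(coarse, obj, numeric(1)))]
    fine <- seq(q0 - diff(coarse[1:2]), q0 + diff(coarse[1:2]), by = 0.005)
    expect_equal(qstar, fine[which.min(vapply(fine, obj, numeric(1)))],
                 tolerance = 0.01)
  }
})

test_that("the constrained optimiser reproduces both published instances", {
  # uniform instance at the published reorder point
  o1 <- optimize_policy(table1_params(), table1_dist(), mode = "paper",
                        r_fixed = 23.58)
  expect_equal(o1$policy$order_quantity, 77.46, tolerance = 5e-3)
  expect_equal(o1$cost$annual_rate, 300344.19, tolerance = 1e-2)
  expect_equal(o1$cycle_time_days, 47.12, tolerance = 5e-3)

  # exponential instance: upper service bound and shelf cap both bind
  o2 <- optimize_policy(table2_params(), table2_dist(), mode = "paper")
  expect_equal(o2$policy$order_quantity, 130.92, tolerance = 5e-3)
  expect_equal(o2$policy$reorder_point, 69.08, tolerance = 5e-3)
  expect_equal(o2$cycle_time_days, 79.6, tolerance = 5e-2)
  expect_true(all(c("shelf_life", "service_hi") %in% o2$binding))
})

test_that("relaxing every constraint recovers the plain EOQ", {
  p <- table1_params(unit_shortage_cost = 0, service_level_lo = 1e-12,
                     shelf_life = 10, expiration_date = 10)
  o <- optimize_policy(p, table1_dist(), mode = "exact", r_step = 0.5)
  expect_equal(o$policy$order_quantity, sqrt(2 * 600 * 20 / 4),
               tolerance = 1e-6)
  expect_identical(o$binding, "none")
})

test_that("no random feasible policy beats the optimiser", {
  set.seed(303)
  p <- table1_params(); d <- table1_dist()
  o <- optimize_policy(p, d, mode = "paper")
  region <- feasible_region(p, d)
  r <- runif(1000, region$r_min, region$r_max)
  q <- vapply(r, function(ri) runif(1, ri, region$q_max_shelf), numeric(1))
  costs <- vapply(seq_along(r), function(i)
    annual_cost_rate(rq_policy(q[i], r[i]), p, d, "paper")$annual_rate,
    numeric(1))
  expect_true(all(o$cost$annual_rate <= costs + 1e-9))
})

test_that("an empty feasible region is reported with the violated constraints", {
  # shelf cap below r_min: Q >= r unattainable
  p <- table2_params(shelf_life = 0.17)  # q_max ~ 32.9 < r_min 58.68
  expect_error(optimize_policy(p, table2_dist()), class = "pharminv_infeasible")
  err <- tryCatch(optimize_policy(p, table2_dist()), error = function(e) e)
  expect_match(conditionMessage(err), "shelf-life cap below r_min")
})
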