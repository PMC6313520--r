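# Worked-instance fixtures built in code, and a random-instance
# generator for property tests.

table1_params <- function(...) {
  args <- utils::modifyList(list(
    demand_rate = 600, holding_cost = 4, fixed_order_cost = 20,
    unit_order_cost = 500, unit_shortage_cost = 1000,
    unit_space = 0.3, total_space = 50,
    shelf_life = 0.25, expiration_date = 0.5,
    shelf_confidence = 1), list(...))
  do.call(drug_parameters, args)
}

table1_dist <- function() lead_time_uniform(0.01, 0.04)

table2_params <- function(...) {
  args <- utils::modifyList(list(
    demand_rate = 600, holding_cost = 4, fixed_order_cost = 20,
    unit_order_cost = 500, unit_shortage_cost = 1000,
    unit_space = 0.3, total_space = 50,
    shelf_life = 1 / 3, expiration_date = 0.5,
    service_level_hi = 0.99, shelf_confidence = 0.99), list(...))
  do.call(drug_parameters, args)
}

table2_dist <- function() lead_time_exponential(40)

# random uniform-lead-time instance satisfying the closed form's side
# condition a <= r/D <= b <= M, with a feasible policy attached
random_uniform_instance <- function() {
  D <- runif(1, 100, 1000)
  a <- runif(1, 0, 0.05)
  b <- a + runif(1, 0.01, 0.1)
  f <- runif(1, 0.1, 1)
  W <- f * D * (b + runif(1, 0.01, 0.3))   # ensures M >= b
  S <- b + runif(1, 0.05, 0.5)
  params <- drug_parameters(demand_rate = D, holding_cost = runif(1, 1, 10),
                            fixed_order_cost = runif(1, 0, 100),
                            unit_order_cost = runif(1, 0, 100),
                            unit_shortage_cost = runif(1, 0, 2000),
                            unit_space = f, total_space = W,
                            shelf_life = S, expiration_date = S + 0.5,
                            shelf_confidence = 1)
  dist <- lead_time_uniform(a, b)
  r <- runif(1, D * a, D * b)
  Q <- r + runif(1, 1, 200)
  list(params = params, dist = dist, policy = rq_policy(Q, r))
}

# independent quadrature oracle for the annual cost of Eq.-15 shape:
# coded against stats::integrate directly, not via the package's
# cost-engine internals
oracle_annual_cost <- function(policy, params, dist) {
  D <- params$demand_rate
  Q <- policy$order_quantity
  r <- policy$reorder_point
  M <- params$total_space / (params$unit_space * D)
  sup <- lt_support(dist)
  lo <- max(0, sup[1]); hi <- min(sup[2], M)
  rd <- min(max(r / D, lo), hi)
  g <- function(t) lt_density(dist, t)
  int <- function(f, l, u) if (u <= l) 0 else
    integrate(f, l, u, rel.tol = 1e-12, abs.tol = 1e-12,
              subdivisions = 500L)$value
  short <- params$unit_shortage_cost * int(function(t) (D * t - r)^2 / 2 * g(t), rd, hi)
  (D * params$fixed_order_cost + short) / Q +
    params$unit_order_cost * D +
    params$holding_cost * Q / 2 * int(g, lo, hi) -
    params$holding_cost * D * int(function(t) t * g(t), lo, rd) +
    params$holding_cost * r * int(g, lo, rd)
}
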