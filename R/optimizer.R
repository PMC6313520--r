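#' Reorder-point bounds from the service-level constraints
#'
#' The type-1 service constraint \eqn{G(r/D) \ge \alpha_{lo}} inverts to
#' \eqn{r \ge D\,G^{-1}(\alpha_{lo})}; an optional upper service bound
#' \eqn{\alpha_{hi}} (a cap on safety stock) gives
#' \eqn{r \le D\,G^{-1}(\alpha_{hi})}. Without an upper bound, `r_max`
#' is capped at \eqn{D \min(\mathrm{support\ max}, M)}, beyond which a
#' larger reorder point cannot change any truncated expectation.
#'
#' @param params A [drug_parameters] object.
#' @param dist A [lead_time] distribution.
#' @return Named vector `c(r_min, r_max)`, packages.
#' @examples
#' p <- drug_parameters(600, 4, 20, 500, 1000, 0.3, 50, 1/3, 0.5,
#'                      service_level_hi = 0.99)
#' service_r_bounds(p, lead_time_exponential(40))  # 58.68, 69.08
#' @export
service_r_bounds <- function(params, dist) {
  D <- params$demand_rate
  r_min <- D * lt_quantile(dist, params$service_level_lo)
  if (!is.finite(r_min))
    stop_infeasible(sprintf(
      "service_level_lo = %g has no finite lead-time quantile",
      params$service_level_lo), violated = "service_lo")
  if (!is.null(params$service_level_hi)) {
    q_hi <- lt_quantile(dist, params$service_level_hi)
    if (!is.finite(q_hi))
      stop_infeasible(sprintf(
        "service_level_hi = %g has no finite lead-time quantile",
        params$service_level_hi), violated = "service_hi")
    r_max <- D * q_hi
  } else {
    r_max <- D * min(lt_support(dist)[2], space_horizon(params))
  }
  c(r_min = r_min, r_max = r_max)
}

#' Largest lot size compatible with the shelf life
#'
#' Stock ordered now must be used up within the shelf life \eqn{S}: the
#' last package of a lot is consumed \eqn{L + Q/D} after ordering, so
#' requiring \eqn{P(L + Q/D \le S) \ge} `shelf_confidence` gives
#' \deqn{Q \le D\,\big(S - G^{-1}(\mathrm{confidence})\big).}
#' With a bounded lead time and confidence 1 this is the hard constraint
#' \eqn{b + Q/D \le S}.
#'
#' @inheritParams service_r_bounds
#' @return Maximum admissible lot size, packages.
#' @examples
#' p <- drug_parameters(600, 4, 20, 500, 1000, 0.3, 50, 0.25, 0.5,
#'                      shelf_confidence = 1)
#' shelf_life_q_max(p, lead_time_uniform(0.01, 0.04))  # 126
#' @export
shelf_life_q_max <- function(params, dist) {
  D <- params$demand_rate
  q_lt <- lt_quantile(dist, params$shelf_confidence)
  if (!is.finite(q_lt))
    stop_infeasible(sprintf(
      "shelf_confidence = %g has no finite lead-time quantile",
      params$shelf_confidence), violated = "shelf_life")
  q_max <- D * (params$shelf_life - q_lt)
  if (q_max <= 0)
    stop_infeasible(sprintf(
      "shelf life %g years is not longer than the %g lead-time quantile (%g years): no positive lot size is admissible",
      params$shelf_life, params$shelf_confidence, q_lt),
      violated = "shelf_life")
  q_max
}

#' Feasible region of the constrained program
#'
#' Collects the reorder-point interval from the service constraints, the
#' shelf-life lot-size cap and the space horizon into one object, noting
#' any constraint that already renders the instance infeasible.
#'
#' @inheritParams service_r_bounds
#' @return An object of class `feasible_region` with fields `r_min`,
#'   `r_max`, `q_max_shelf`, `space_cap` and `notes`.
#' @export
feasible_region <- function(params, dist) {
  rb <- service_r_bounds(params, dist)
  q_max <- shelf_life_q_max(params, dist)
  M <- space_horizon(params)
  notes <- character()
  if (rb[["r_min"]] > rb[["r_max"]] + 1e-12)
    notes <- c(notes, "service bounds cross: r_min > r_max")
  if (q_max < rb[["r_min"]])
    notes <- c(notes, "shelf-life cap below r_min: Q >= r unattainable")
  if (rb[["r_min"]] / params$demand_rate > M)
    notes <- c(notes, "r_min exceeds the space-capped horizon")
  structure(list(r_min = rb[["r_min"]], r_max = rb[["r_max"]],
                 q_max_shelf = q_max, space_cap = M, notes = notes),
            class = "feasible_region")
}

#' @export
print.feasible_region <- function(x, ...) {
  cat(sprintf("Feasible region: r in [%.4f, %.4f], Q <= %.4f, M = %.4f yr\n",
              x$r_min, x$r_max, x$q_max_shelf, x$space_cap))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Cost-minimising lot size for a fixed reorder point
#'
#' For fixed \eqn{r} the annual cost has the EOQ shape
#' \eqn{\alpha(r)/Q + \beta Q + \gamma(r)} and is strictly convex in
#' \eqn{Q}; its unconstrained minimiser is
#' \deqn{Q^*(r) = \sqrt{\frac{2\big(DA + \mathrm{shortage\ numerator}(r)\big)}
#'   {h\,G(M)}},}
#' which specialises to the published square-root formulas for uniform
#' and exponential ("paper" mode) lead times. The result is then clamped
#' into \eqn{[r,\ Q_{max}^{shelf}]}.
#'
#' @param reorder_point Fixed reorder point \eqn{r}, packages.
#' @inheritParams cost_engine
#' @param clamp Clamp into `[r, shelf_life_q_max()]` (default) or return
#'   the unconstrained minimiser.
#' @return Lot size, packages.
#' @examples
#' p <- drug_parameters(600, 4, 20, 500, 1000, 0.3, 50, 0.25, 0.5,
#'                      shelf_confidence = 1)
#' optimal_q_given_r(23.58, p, lead_time_uniform(0.01, 0.04))  # 77.46
#' @export
optimal_q_given_r <- function(reorder_point, params, dist,
                              mode = c("paper", "exact"), clamp = TRUE) {
  mode <- match.arg(mode)
  check_number(reorder_point, "reorder_point", lower = 0)
  D <- params$demand_rate; h <- params$holding_cost
  A <- params$fixed_order_cost; C <- params$unit_shortage_cost
  r <- reorder_point
  M <- space_horizon(params)
  if (mode == "paper" && inherits(dist, "lead_time_uniform")) {
    a <- dist$min; b <- dist$max
    bracket <- r^2 * b - r^3 / (3 * D) - r * D * b^2 + b^3 * D^2 / 3
    radicand <- (2 * D * A + C / (b - a) * bracket) / h
  } else if (mode == "paper" && inherits(dist, "lead_time_exponential")) {
    lam <- dist$rate
    co <- exponential_coefficients(params, dist)
    w <- exp(-lam * r / D) - exp(-lam * M)
    radicand <- (2 * A * D +
                   2 * (co[["c0"]] - co[["c1"]] * r + co[["c2"]] * r^2) * w) /
      (h * (1 - exp(-lam * M)))
  } else {
    # exact objective: alpha/Q + (h/2) G(M) Q + terms free of Q
    sup <- lt_support(dist)
    lo <- max(0, sup[1]); hi <- min(sup[2], M)
    short_num <- C * quad(function(t) (D * t - r)^2 / 2 * lt_density(dist, t),
                          min(max(r / D, lo), hi), hi)
    gM <- lt_cdf(dist, hi) - lt_cdf(dist, lo)
    radicand <- 2 * (D * A + short_num) / (h * gM)
  }
  if (radicand < 0)
    stop("internal error: negative radicand in optimal_q_given_r")
  q <- sqrt(radicand)
  if (!clamp) return(q)
  q_max <- shelf_life_q_max(params, dist)
  if (q_max < r)
    stop_infeasible(sprintf(
      "shelf-life cap Q <= %.4f is below the reorder point r = %.4f",
      q_max, r), violated = "q_ge_r")
  min(max(q, r), q_max)
}

#' Solve the constrained (r, Q) program
#'
#' Minimises the expected annual cost subject to the service-level,
#' shelf-life and \eqn{Q \ge r} constraints. Exploits convexity in
#' \eqn{Q}: for each \eqn{r} on a deterministic grid over
#' \eqn{[r_{min}, r_{max}]} the clamped closed-form \eqn{Q^*(r)} is
#' evaluated, and the cheapest pair wins (ties break toward smaller
#' \eqn{r}). The deterministic grid makes results reproducible without
#' solver tolerances.
#'
#' @inheritParams cost_engine
#' @param r_fixed Optional fixed reorder point overriding the service
#'   bounds (used to reproduce published instances whose printed bound
#'   differs from the service quantile).
#' @param r_step Grid resolution in packages; default 0.01.
#' @return An object of class `rq_optimum`: fields `policy`
#'   ([rq_policy]), `cost` (`cost_breakdown`), `cycle_time_days`,
#'   `binding` (character vector among `service_lo`, `service_hi`,
#'   `shelf_life`, `q_ge_r`, `none`), `region`, `mode`, `r_grid_step`.
#' @examples
#' p <- drug_parameters(600, 4, 20, 500, 1000, 0.3, 50, 1/3, 0.5,
#'                      service_level_hi = 0.99)
#' optimize_policy(p, lead_time_exponential(40), mode = "paper")
#' @export
optimize_policy <- function(params, dist, mode = c("paper", "exact"),
                            r_fixed = NULL, r_step = 0.01) {
  mode <- match.arg(mode)
  region <- feasible_region(params, dist)
  if (length(region$notes))
    stop_infeasible(paste0("empty feasible region: ",
                           paste(region$notes, collapse = "; ")),
                    violated = region$notes)
  if (is.null(r_fixed)) {
    r_grid <- seq(region$r_min, region$r_max, by = r_step)
    if (r_grid[length(r_grid)] < region$r_max)
      r_grid <- c(r_grid, region$r_max)
  } else {
    check_number(r_fixed, "r_fixed", lower = 0)
    r_grid <- r_fixed
  }
  qs <- vapply(r_grid, function(r) optimal_q_given_r(r, params, dist, mode = mode),
               numeric(1))
  costs <- vapply(seq_along(r_grid), function(i)
    annual_cost_rate(rq_policy(qs[i], r_grid[i]), params, dist,
                     mode = mode)$annual_rate, numeric(1))
  i <- which.min(costs)  # first minimum -> smallest r on ties
  policy <- rq_policy(qs[i], r_grid[i])
  cost <- annual_cost_rate(policy, params, dist, mode = mode)
  # a constraint counts as binding only if relaxing it would lower the
  # cost: boundary position plus a directional probe of the objective
  tol <- 1e-6
  delta <- max(r_step, 1e-3)
  probe <- function(r_probe) tryCatch({
    q <- optimal_q_given_r(r_probe, params, dist, mode = mode)
    annual_cost_rate(rq_policy(q, r_probe), params, dist,
                     mode = mode)$annual_rate
  }, error = function(e) Inf)
  q_unclamped <- optimal_q_given_r(policy$reorder_point, params, dist,
                                   mode = mode, clamp = FALSE)
  binding <- character()
  if (is.null(r_fixed)) {
    if (abs(policy$reorder_point - region$r_min) <= tol &&
        region$r_min > 0 &&
        probe(max(region$r_min - delta, 0)) < cost$annual_rate - 1e-9)
      binding <- c(binding, "service_lo")
    if (!is.null(params$service_level_hi) &&
        abs(policy$reorder_point - region$r_max) <= tol &&
        probe(region$r_max + delta) < cost$annual_rate - 1e-9)
      binding <- c(binding, "service_hi")
  }
  if (q_unclamped > region$q_max_shelf + tol)
    binding <- c(binding, "shelf_life")
  if (q_unclamped < policy$reorder_point - tol)
    binding <- c(binding, "q_ge_r")
  if (!length(binding)) binding <- "none"
  structure(list(policy = policy, cost = cost,
                 cycle_time_days = cycle_time(policy$order_quantity,
                                              params$demand_rate) * DAYS_PER_YEAR,
                 binding = binding, region = region, mode = mode,
                 r_fixed = r_fixed, r_grid_step = r_step),
            class = "rq_optimum")
}

#' @export
print.rq_optimum <- function(x, ...) {
  cat(sprintf("Optimal (r, Q) policy [%s mode]\n", x$mode))
  cat(sprintf("  Q = %.2f packages, r = %.2f packages\n",
              x$policy$order_quantity, x$policy$reorder_point))
  cat(sprintf("  annual cost %.2f %s/year; cycle %.2f days\n",
              x$cost$annual_rate, x$cost$currency, x$cycle_time_days))
  cat("  binding constraints:", paste(x$binding, collapse = ", "), "\n")
  if (!is.null(x$r_fixed)) cat(sprintf("  (r fixed at %g)\n", x$r_fixed))
  invisible(x)
}
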