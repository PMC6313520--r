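#' Drug-specific model parameters
#'
#' Bundles the scalar inputs of the single-drug continuous-review model:
#' annual demand, cost coefficients, storage space, shelf life and the
#' service-level requirements. All validation happens here so downstream
#' cost and optimisation code can assume a coherent instance.
#'
#' @param demand_rate Annual demand \eqn{D}, packages/year; `> 0`.
#' @param holding_cost Holding cost \eqn{h}, currency/package/year; `> 0`.
#' @param fixed_order_cost Fixed cost per order \eqn{A}; `>= 0`.
#' @param unit_order_cost Variable ordering cost \eqn{K} per package; `>= 0`.
#' @param unit_shortage_cost Shortage penalty \eqn{C} per package of unmet
#'   demand (lost sales); `>= 0`.
#' @param unit_space Storage space per package \eqn{f}, m^3; `> 0`.
#' @param total_space Total storage space \eqn{W}, m^3; `> 0`.
#' @param shelf_life Shelf life \eqn{S} counted from the moment of
#'   ordering, years; `0 < shelf_life <= expiration_date`.
#' @param expiration_date Registered expiration date \eqn{T_s}, years.
#' @param service_level_lo Lower bound on the type-1 service level
#'   (probability of no stockout within a cycle); default 0.98.
#' @param service_level_hi Optional upper bound on the service level (used
#'   when the hospital caps safety stock); `NULL` to leave unbounded.
#' @param shelf_confidence Confidence with which stock must be consumed
#'   within its shelf life: the ordering cycle may start only if
#'   \eqn{P(L + Q/D \le S)} is at least this value. Default 0.99; set to 1
#'   for bounded lead times to require certainty.
#' @param currency Currency label carried through outputs; default
#'   `"yuan"`.
#'
#' @return An object of class `drug_parameters`.
#' @examples
#' drug_parameters(demand_rate = 600, holding_cost = 4, fixed_order_cost = 20,
#'                 unit_order_cost = 500, unit_shortage_cost = 1000,
#'                 unit_space = 0.3, total_space = 50,
#'                 shelf_life = 0.25, expiration_date = 0.5)
#' @export
drug_parameters <- function(demand_rate, holding_cost, fixed_order_cost,
                            unit_order_cost, unit_shortage_cost,
                            unit_space, total_space,
                            shelf_life, expiration_date,
                            service_level_lo = 0.98,
                            service_level_hi = NULL,
                            shelf_confidence = 0.99,
                            currency = "yuan") {
  check_number(demand_rate, "demand_rate", lower = 0, strict = TRUE)
  check_number(holding_cost, "holding_cost", lower = 0, strict = TRUE)
  check_number(fixed_order_cost, "fixed_order_cost", lower = 0)
  check_number(unit_order_cost, "unit_order_cost", lower = 0)
  check_number(unit_shortage_cost, "unit_shortage_cost", lower = 0)
  check_number(unit_space, "unit_space", lower = 0, strict = TRUE)
  check_number(total_space, "total_space", lower = 0, strict = TRUE)
  check_number(shelf_life, "shelf_life", lower = 0, strict = TRUE)
  check_number(expiration_date, "expiration_date", lower = 0, strict = TRUE)
  if (shelf_life > expiration_date)
    stop_invalid("shelf_life", "cannot exceed `expiration_date`")
  check_number(service_level_lo, "service_level_lo",
               lower = 0, strict = TRUE, upper = 1, upper_strict = TRUE)
  if (!is.null(service_level_hi)) {
    check_number(service_level_hi, "service_level_hi",
                 lower = 0, strict = TRUE, upper = 1)
    if (service_level_lo >= service_level_hi)
      stop_invalid("service_level_hi", "must exceed `service_level_lo`")
  }
  check_number(shelf_confidence, "shelf_confidence",
               lower = 0, strict = TRUE, upper = 1)
  if (!is.character(currency) || length(currency) != 1L)
    stop_invalid("currency", "must be a single string")
  structure(list(
    demand_rate = demand_rate, holding_cost = holding_cost,
    fixed_order_cost = fixed_order_cost, unit_order_cost = unit_order_cost,
    unit_shortage_cost = unit_shortage_cost, unit_space = unit_space,
    total_space = total_space, shelf_life = shelf_life,
    expiration_date = expiration_date,
    service_level_lo = service_level_lo, service_level_hi = service_level_hi,
    shelf_confidence = shelf_confidence, currency = currency
  ), class = "drug_parameters")
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("Drug inventory parameters\n")
  cat(sprintf("  demand D = %g pkg/yr; h = %g, A = %g, K = %g, C = %g (%s)\n",
              x$demand_rate, x$holding_cost, x$fixed_order_cost,
              x$unit_order_cost, x$unit_shortage_cost, x$currency))
  cat(sprintf("  space: f = %g m3/pkg, W = %g m3 (horizon M = %g yr)\n",
              x$unit_space, x$total_space, space_horizon(x)))
  cat(sprintf("  shelf life S = %g yr (confidence %g), expiry Ts = %g yr\n",
              x$shelf_life, x$shelf_confidence, x$expiration_date))
  hi <- if (is.null(x$service_level_hi)) "none" else sprintf("%g", x$service_level_hi)
  cat(sprintf("  service level: lower %g, upper %s\n", x$service_level_lo, hi))
  invisible(x)
}

#' Space-capped time horizon
#'
#' The total storage space \eqn{W} and the per-package space \eqn{f} bound
#' the stock the ward can hold, which in time units caps the lead-time
#' horizon at \eqn{M = W / (f D)} years. All lead-time integrals are
#' truncated at \eqn{M}.
#'
#' @param params A [drug_parameters] object.
#' @return \eqn{M = W/(fD)}, years.
#' @export
space_horizon <- function(params) {
  params$total_space / (params$unit_space * params$demand_rate)
}

#' An (r, Q) replenishment policy
#'
#' Under continuous review, an order of `order_quantity` packages is
#' placed whenever the inventory position falls to `reorder_point`.
#' Both are continuous quantities; no integer rounding is applied in the
#' mathematical core.
#'
#' @param order_quantity Lot size \eqn{Q}, packages; `>= reorder_point`.
#' @param reorder_point Reorder point \eqn{r}, packages; `>= 0`.
#' @return An object of class `rq_policy`.
#' @examples
#' rq_policy(77.46, 23.58)
#' @export
rq_policy <- function(order_quantity, reorder_point) {
  check_number(reorder_point, "reorder_point", lower = 0)
  check_number(order_quantity, "order_quantity", lower = 0)
  if (order_quantity < reorder_point)
    stop_invalid("order_quantity", "lot size Q must be >= reorder point r")
  structure(list(order_quantity = order_quantity, reorder_point = reorder_point),
            class = "rq_policy")
}

#' @export
print.rq_policy <- function(x, ...) {
  cat(sprintf("(r, Q) policy: order Q = %g packages at reorder point r = %g\n",
              x$order_quantity, x$reorder_point))
  invisible(x)
}

#' Ordering cycle time
#'
#' With deterministic demand rate \eqn{D}, each lot of \eqn{Q} packages
#' lasts \eqn{T = Q/D} years regardless of the lead-time realisation.
#'
#' @param order_quantity Lot size \eqn{Q}, packages; `> 0`.
#' @param demand_rate Demand \eqn{D}, packages/year; `> 0`.
#' @return Cycle time in years. Multiply by 365 for days.
#' @examples
#' cycle_time(77.46, 600) * 365   # 47.12 days
#' @export
cycle_time <- function(order_quantity, demand_rate) {
  check_number(order_quantity, "order_quantity", lower = 0, strict = TRUE)
  check_number(demand_rate, "demand_rate", lower = 0, strict = TRUE)
  order_quantity / demand_rate
}

#' Type-1 service level of a reorder point
#'
#' The probability that lead-time demand does not exceed the reorder
#' point, i.e. that the lot arrives before the shelf is empty:
#' \eqn{\alpha = P(L \le r/D) = G(r/D)}.
#'
#' @param reorder_point Reorder point \eqn{r}, packages; `>= 0`.
#' @param demand_rate Demand \eqn{D}, packages/year; `> 0`.
#' @param dist A [lead_time] distribution.
#' @return The cycle no-stockout probability \eqn{G(r/D)}.
#' @examples
#' service_level(58.68, 600, lead_time_exponential(40))  # ~0.98
#' @export
service_level <- function(reorder_point, demand_rate, dist) {
  check_number(reorder_point, "reorder_point", lower = 0)
  check_number(demand_rate, "demand_rate", lower = 0, strict = TRUE)
  lt_cdf(dist, reorder_point / demand_rate)
}

# days per year used for display conversions only
DAYS_PER_YEAR <- 365
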