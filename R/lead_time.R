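#' Lead-time distributions
#'
#' Constructors for the stochastic replenishment lead time \eqn{L} with
#' density \eqn{g(t)}. Two families are supported: uniform on
#' \eqn{[a, b]} (bounded delays, e.g. a contracted delivery window) and
#' exponential with rate \eqn{\lambda} (memoryless delays). Times are in
#' years throughout; days appear only in printed summaries (365 days/year).
#'
#' @param min,max Support bounds of the uniform family, in years;
#'   `0 <= min < max`.
#' @param rate Rate \eqn{\lambda} of the exponential family, per year;
#'   `rate > 0`.
#'
#' @return An object of class `lead_time` (subclass `lead_time_uniform` or
#'   `lead_time_exponential`) supporting [lt_density()], [lt_cdf()],
#'   [lt_quantile()], [lt_mean()], [lt_support()] and [lt_sample()].
#'
#' @examples
#' u <- lead_time_uniform(0.01, 0.04)
#' lt_mean(u)                       # 0.025 years (~9.1 days)
#' e <- lead_time_exponential(40)
#' lt_cdf(e, lt_quantile(e, 0.98))  # 0.98
#' @name lead_time
NULL

#' @rdname lead_time
#' @export
lead_time_uniform <- function(min, max) {
  check_number(min, "min", lower = 0)
  check_number(max, "max")
  if (max <= min) stop_invalid("max", "upper bound must exceed lower bound `min`")
  structure(list(kind = "uniform", min = min, max = max),
            class = c("lead_time_uniform", "lead_time"))
}

#' @rdname lead_time
#' @export
lead_time_exponential <- function(rate) {
  check_number(rate, "rate", lower = 0, strict = TRUE)
  structure(list(kind = "exponential", rate = rate),
            class = c("lead_time_exponential", "lead_time"))
}

#' @rdname lead_time
#' @param kind `"uniform"` or `"exponential"`.
#' @param ... Family parameters passed to the specific constructor.
#' @export
make_distribution <- function(kind = c("uniform", "exponential"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         uniform = lead_time_uniform(...),
         exponential = lead_time_exponential(...))
}

#' Query a lead-time distribution
#'
#' Density, cumulative probability, quantile, mean, support and random
#' sampling for [lead_time] objects. `lt_support()` returns `c(min, max)`
#' with `max = Inf` for unbounded families.
#'
#' @param dist A [lead_time] object.
#' @param t Time, years.
#' @param p Probability in \eqn{[0, 1]}.
#' @param n Number of draws.
#' @return Numeric vector.
#' @name lead_time_query
NULL

#' @rdname lead_time_query
#' @export
lt_density <- function(dist, t) UseMethod("lt_density")
#' @export
lt_density.lead_time_uniform <- function(dist, t) stats::dunif(t, dist$min, dist$max)
#' @export
lt_density.lead_time_exponential <- function(dist, t) stats::dexp(t, dist$rate)

#' @rdname lead_time_query
#' @export
lt_cdf <- function(dist, t) UseMethod("lt_cdf")
#' @export
lt_cdf.lead_time_uniform <- function(dist, t) stats::punif(t, dist$min, dist$max)
#' @export
lt_cdf.lead_time_exponential <- function(dist, t) stats::pexp(t, dist$rate)

#' @rdname lead_time_query
#' @export
lt_quantile <- function(dist, p) UseMethod("lt_quantile")
#' @export
lt_quantile.lead_time_uniform <- function(dist, p) stats::qunif(p, dist$min, dist$max)
#' @export
lt_quantile.lead_time_exponential <- function(dist, p) stats::qexp(p, dist$rate)

#' @rdname lead_time_query
#' @export
lt_mean <- function(dist) UseMethod("lt_mean")
#' @export
lt_mean.lead_time_uniform <- function(dist) (dist$min + dist$max) / 2
#' @export
lt_mean.lead_time_exponential <- function(dist) 1 / dist$rate

#' @rdname lead_time_query
#' @export
lt_support <- function(dist) UseMethod("lt_support")
#' @export
lt_support.lead_time_uniform <- function(dist) c(dist$min, dist$max)
#' @export
lt_support.lead_time_exponential <- function(dist) c(0, Inf)

#' @rdname lead_time_query
#' @param upper Optional truncation point: draws are from the law of
#'   \eqn{L} conditioned on \eqn{L \le} `upper` (inverse-CDF method).
#' @export
lt_sample <- function(dist, n, upper = Inf) {
  stopifnot(n >= 0)
  p_hi <- if (is.finite(upper)) lt_cdf(dist, upper) else 1
  if (p_hi <= 0) stop_infeasible("truncation point is below the lead-time support")
  lt_quantile(dist, stats::runif(n, 0, p_hi))
}

#' @export
print.lead_time <- function(x, ...) {
  if (x$kind == "uniform")
    cat(sprintf("Lead time ~ Uniform[%g, %g] years (mean %g)\n",
                x$min, x$max, lt_mean(x)))
  else
    cat(sprintf("Lead time ~ Exponential(rate = %g/year) (mean %g)\n",
                x$rate, lt_mean(x)))
  invisible(x)
}
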