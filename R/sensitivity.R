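#' Shelf-life sensitivity sweep
#'
#' Recomputes the optimal policy over a grid of shelf lives, holding all
#' other parameters fixed. For each shelf life `S` the lot-size cap
#' \eqn{Q_{max}(S) = D(S - G^{-1}(c))} is rebuilt and the policy
#' re-optimised; while the cap binds, \eqn{Q(S)} grows affinely with
#' slope \eqn{D}, and once the unconstrained optimum fits, \eqn{Q} and
#' the total cost plateau.
#'
#' By default the reorder point is held at `r_fixed` across the sweep
#' (shelf life does not enter the service constraint); set
#' `reoptimize_r = TRUE` to re-run the full optimiser per row. When the
#' cap falls below the reorder point, the row is clamped to
#' \eqn{Q = r = Q_{max}} (the \eqn{Q \ge r} constraint); when no
#' positive lot size is admissible the row is flagged infeasible rather
#' than aborting the sweep.
#'
#' @inheritParams cost_engine
#' @param s_values Ascending shelf lives to evaluate, years.
#' @param r_fixed Reorder point held fixed across rows (required unless
#'   `reoptimize_r = TRUE`).
#' @param reoptimize_r Re-optimise `r` within the service bounds at each
#'   shelf life.
#' @return A `data.frame` of class `shelf_life_table` with columns
#'   `S`, `Q`, `r`, `TC`, `feasible`; attributes `distribution`, `mode`.
#' @examples
#' p <- drug_parameters(600, 4, 20, 500, 1000, 0.3, 50, 0.25, 0.5,
#'                      shelf_confidence = 1)
#' shelf_life_sweep(p, lead_time_uniform(0.01, 0.04),
#'                  s_values = seq(0.08, 0.18, by = 0.02), r_fixed = 23.58)
#' @export
shelf_life_sweep <- function(params, dist, s_values, r_fixed = NULL,
                             mode = c("paper", "exact"),
                             reoptimize_r = FALSE) {
  mode <- match.arg(mode)
  if (!length(s_values)) stop_invalid("s_values", "must be nonempty")
  if (is.unsorted(s_values, strictly = TRUE))
    stop_invalid("s_values", "must be strictly ascending")
  if (is.null(r_fixed) && !reoptimize_r)
    stop_invalid("r_fixed", "required unless reoptimize_r = TRUE")
  rows <- lapply(s_values, function(S) {
    p_s <- params
    p_s$shelf_life <- S
    q_max <- tryCatch(shelf_life_q_max(p_s, dist), pharminv_infeasible = function(e) NA_real_)
    if (is.na(q_max))
      return(data.frame(S = S, Q = NA_real_, r = NA_real_, TC = NA_real_,
                        feasible = FALSE))
    if (reoptimize_r) {
      opt <- tryCatch(optimize_policy(p_s, dist, mode = mode),
                      pharminv_infeasible = function(e) NULL)
      if (is.null(opt)) {
        # service bounds unattainable under this cap: fall back to clamp
        rb <- service_r_bounds(p_s, dist)
        r <- min(rb[["r_min"]], q_max)
      } else {
        return(data.frame(S = S, Q = opt$policy$order_quantity,
                          r = opt$policy$reorder_point,
                          TC = opt$cost$annual_rate, feasible = TRUE))
      }
    } else {
      r <- r_fixed
    }
    if (q_max < r) {
      # Q >= r forces both down to the cap
      q <- r <- q_max
    } else {
      q <- optimal_q_given_r(r, p_s, dist, mode = mode)
    }
    tc <- annual_cost_rate(rq_policy(q, r), p_s, dist, mode = mode)$annual_rate
    data.frame(S = S, Q = q, r = r, TC = tc, feasible = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("shelf_life_table", "data.frame"),
            distribution = dist$kind, mode = mode)
}

#' Elasticities along a shelf-life sweep
#'
#' For each adjacent pair of sweep rows, reports the arc elasticities of
#' the lot size and the total cost with respect to shelf life
#' (\eqn{(\Delta Q/Q)/(\Delta S/S)} and \eqn{(\Delta TC/TC)/(\Delta
#' S/S)}) and labels the regime: `"constrained"` while the shelf-life
#' cap drives \eqn{Q} (unit elasticity: doubling the shelf life doubles
#' the admissible lot), `"plateau"` once the unconstrained optimum fits.
#'
#' @param table A `shelf_life_table` from [shelf_life_sweep()] with at
#'   least 3 feasible rows.
#' @return A `data.frame` with columns `S_from`, `S_to`,
#'   `elasticity_Q`, `elasticity_TC`, `regime`.
#' @export
elasticity_report <- function(table) {
  stopifnot(inherits(table, "shelf_life_table"))
  tab <- table[table$feasible, , drop = FALSE]
  if (nrow(tab) < 3)
    stop_invalid("table", "needs at least 3 feasible rows")
  i <- seq_len(nrow(tab) - 1L)
  dS <- (tab$S[i + 1] - tab$S[i]) / tab$S[i]
  eQ <- ((tab$Q[i + 1] - tab$Q[i]) / tab$Q[i]) / dS
  eTC <- ((tab$TC[i + 1] - tab$TC[i]) / tab$TC[i]) / dS
  data.frame(S_from = tab$S[i], S_to = tab$S[i + 1],
             elasticity_Q = eQ, elasticity_TC = eTC,
             regime = ifelse(abs(eQ) < 0.05, "plateau", "constrained"))
}

#' Write a sweep as CSV
#'
#' Column order `S,Q,r,TC`; costs rounded to 2 decimals at write time
#' only.
#'
#' @param table A `shelf_life_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(table, path) {
  stopifnot(inherits(table, "shelf_life_table"))
  out <- data.frame(S = table$S, Q = round(table$Q, 4),
                    r = round(table$r, 4), TC = round(table$TC, 2))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
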