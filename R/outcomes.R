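# Discounted cost and QALY accrual, and comparative cost-effectiveness.

#' Per-cycle discount factor
#'
#' `(1 + annual_rate)^(-cycle / 12)`; applied identically to costs and
#' QALYs.
#'
#' @param cycle Cycle index (months, >= 0).
#' @param annual_rate Annual discount rate as a fraction.
#' @return Discount factor(s).
#' @examples
#' discount_factor(12, 0.035)  # 1 / 1.035
#' @export
discount_factor <- function(cycle, annual_rate) {
  stopifnot(all(cycle >= 0), annual_rate >= 0)
  (1 + annual_rate)^(-cycle / 12)
}

# per-state utility weights (year-equivalents; death = 0)
state_utilities <- function(params) {
  u_is <- c(none = NA_real_, minor = params$u_is_minor,
            major = params$u_is_major)
  u_ich <- c(none = NA_real_, minor = params$u_ich_minor,
             major = params$u_ich_major)
  vapply(seq_len(N_STATES), function(i) {
    s <- STATE_TABLE[i, ]
    if (!s$alive) return(0)
    if (s$last_event == "none") return(params$u_af)
    # combined states take the worse (minimum) of the component utilities
    min(u_is[s$is_sev], u_ich[s$ich_sev], na.rm = TRUE)
  }, 0)
}

# per-state monthly costs (follow-up + anticoagulation + subscription)
state_monthly_costs <- function(params, strategy) {
  fu_is <- c(none = 0, minor = params$c_fu_is_minor,
             major = params$c_fu_is_major)
  fu_ich <- c(none = 0, minor = params$c_fu_ich_minor,
              major = params$c_fu_ich_major)
  vapply(seq_len(N_STATES), function(i) {
    s <- STATE_TABLE[i, ]
    if (!s$alive) return(0)
    cost <- fu_is[[s$is_sev]] + fu_ich[[s$ich_sev]]
    if (s$anticoag == "OAC") cost <- cost + params$c_anticoag_monthly
    if (strategy == "mhealth") cost <- cost + params$c_mhealth_monthly
    cost
  }, 0)
}

#' Accrue discounted costs and QALYs from a cohort trace
#'
#' Per cycle (evaluated at cycle end, no half-cycle correction): QALYs
#' are state occupancy times state utility / 12, minus the GIB
#' disutility (`du_gib` for 14 days, with a 30.4375-day month) per GIB
#' episode; costs are per-state monthly follow-up (anticoagulation for
#' OAC states only; combined states charge the sum of their components'
#' follow-up), event episode costs from the tolls (fatal events charge
#' the death cost only), the all-cause death cost per new death, and for
#' mHealth-based care the monthly subscription for alive patients plus
#' the one-time setup cost at entry. Everything is multiplied by
#' [discount_factor()].
#'
#' @param trace An `af_trace` produced under `params`.
#' @param strategy `"usual"` or `"mhealth"` (defaults to the trace's).
#' @param params An `af_params` object.
#' @return An `af_econ` object with `cost` and `qaly` totals.
#' @export
accrue_outcomes <- function(trace, strategy = NULL, params) {
  stopifnot(inherits(trace, "af_trace"), inherits(params, "af_params"))
  if (is.null(strategy)) strategy <- trace$strategy
  strategy <- match.arg(strategy, c("usual", "mhealth"))
  if (ncol(trace$occupancy) != N_STATES) {
    stop("trace/params state-count mismatch", call. = FALSE)
  }
  h <- trace$horizon
  if (h == 0) {
    return(structure(list(strategy = strategy, cost = 0, qaly = 0),
                     class = "af_econ"))
  }
  disc <- discount_factor(seq_len(h), params$discount_annual)
  occ <- trace$occupancy[-1L, , drop = FALSE]      # cycles 1..h
  u <- state_utilities(params)
  c_state <- state_monthly_costs(params, strategy)
  gib_qaly_loss <- params$du_gib * (14 / DAYS_PER_MONTH) / 12
  qaly <- sum(disc * (occ %*% u)) / 12 -
    gib_qaly_loss * sum(disc * trace$tolls[, "gib"])
  c_toll <- c(is_minor = params$c_event_is_minor,
              is_major = params$c_event_is_major,
              is_fatal = 0,
              ich_minor = params$c_event_ich_minor,
              ich_major = params$c_event_ich_major,
              ich_fatal = 0,
              gib = params$c_event_gib,
              deaths = params$c_death)
  cost <- sum(disc * (occ %*% c_state)) +
    sum(disc * (trace$tolls %*% c_toll))
  if (strategy == "mhealth") cost <- cost + params$c_mhealth_setup
  structure(list(strategy = strategy, cost = unname(cost),
                 qaly = unname(qaly)),
            class = "af_econ")
}

#' @export
print.af_econ <- function(x, ...) {
  cat(sprintf("<af_econ> %s care: total discounted cost US $%.0f, %.4f QALYs\n",
              x$strategy, x$cost, x$qaly))
  invisible(x)
}

#' Incremental cost-effectiveness of one strategy over another
#'
#' @param a Intervention `af_econ` (mHealth-based care).
#' @param b Comparator `af_econ` (usual care).
#' @param wtp Willingness-to-pay threshold (US $/QALY) for the net
#'   monetary benefit.
#' @return An `af_cea` object: `delta_cost`, `delta_qaly`, `icer` (`NA`
#'   with `icer_defined = FALSE` when the QALY difference is zero),
#'   `nmb = delta_qaly * wtp - delta_cost`, and a `dominance` flag
#'   (`"dominant"` when cheaper and more effective, `"dominated"` for the
#'   converse, else `"none"`).
#' @export
compute_icer <- function(a, b, wtp) {
  stopifnot(inherits(a, "af_econ"), inherits(b, "af_econ"),
            is_scalar_number(wtp))
  dc <- a$cost - b$cost
  dq <- a$qaly - b$qaly
  defined <- dq != 0
  icer <- if (defined) dc / dq else NA_real_
  dominance <- if (dc < 0 && dq > 0) "dominant"
               else if (dc > 0 && dq < 0) "dominated"
               else "none"
  structure(list(intervention = a$strategy, comparator = b$strategy,
                 cost = c(a$cost, b$cost), qaly = c(a$qaly, b$qaly),
                 delta_cost = dc, delta_qaly = dq,
                 icer = icer, icer_defined = defined,
                 nmb = dq * wtp - dc, wtp = wtp, dominance = dominance),
            class = "af_cea")
}

#' @export
print.af_cea <- function(x, ...) {
  cat(sprintf("<af_cea> %s vs %s\n", x$intervention, x$comparator))
  cat(sprintf("  cost: %.0f vs %.0f (delta %.0f); QALYs: %.4f vs %.4f (delta %.4f)\n",
              x$cost[1], x$cost[2], x$delta_cost,
              x$qaly[1], x$qaly[2], x$delta_qaly))
  if (x$icer_defined) {
    cat(sprintf("  ICER US $%.0f/QALY; NMB US $%.0f at WTP $%s; dominance: %s\n",
                x$icer, x$nmb, format(x$wtp, big.mark = ","), x$dominance))
  } else {
    cat(sprintf("  ICER undefined (delta QALY = 0); NMB US $%.0f\n", x$nmb))
  }
  invisible(x)
}

#' Run the base-case analysis
#'
#' Runs both strategies over the full horizon, accrues outcomes, and
#' compares mHealth-based care against usual care at the parameter set's
#' WTP threshold.
#'
#' @param params An `af_params` object (defaults to the shipped
#'   base case).
#' @param horizon Optional cycle-count override.
#' @return A list with both `af_econ` results, both traces, and the
#'   `af_cea` comparison (`$cea`).
#' @examples
#' \donttest{
#' bc <- run_base_case(default_parameters())
#' bc$cea
#' }
#' @export
run_base_case <- function(params = default_parameters(), horizon = NULL) {
  tr_u <- run_cohort("usual", params, horizon)
  tr_m <- run_cohort("mhealth", params, horizon)
  ec_u <- accrue_outcomes(tr_u, "usual", params)
  ec_m <- accrue_outcomes(tr_m, "mhealth", params)
  list(usual = ec_u, mhealth = ec_m,
       trace_usual = tr_u, trace_mhealth = tr_m,
       cea = compute_icer(ec_m, ec_u, params$wtp))
}
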