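# One-way (tornado, threshold) and probabilistic sensitivity analysis.

icer_of <- function(params) run_base_case(params)$cea

#' One-way sensitivity of the ICER to a single parameter
#'
#' Re-runs both strategies with the parameter fixed at each bound
#' (severity-triple members re-normalise the complementary categories,
#' recurrent-type members move their complement; see [set_parameter()])
#' and records the resulting ICERs.
#'
#' @param params An `af_params` object.
#' @param param_id Parameter id accepted by [set_parameter()].
#' @param low,high Bounds to evaluate.
#' @return A one-row data frame: `param`, `low`, `high`, `icer_low`,
#'   `icer_high`, `swing`, and `crosses_wtp` (does the WTP threshold lie
#'   between the two ICERs?).
#' @export
one_way_sa <- function(params, param_id, low, high) {
  stopifnot(low <= high)
  cea_lo <- icer_of(set_parameter(params, param_id, low))
  cea_hi <- icer_of(set_parameter(params, param_id, high))
  icers <- c(cea_lo$icer, cea_hi$icer)
  nmbs <- c(cea_lo$nmb, cea_hi$nmb)
  data.frame(param = param_id, low = low, high = high,
             icer_low = icers[1], icer_high = icers[2],
             swing = abs(icers[2] - icers[1]),
             # NMB changes sign iff the ICER crosses the WTP threshold
             crosses_wtp = prod(sign(nmbs)) < 0)
}

# OWSA inventory: every distributed parameter at its published range;
# mortality bands vary jointly through one multiplier unless per_band
owsa_ranges <- function(params, per_band_mortality = FALSE) {
  out <- list()
  for (id in names(params$dist)) {
    d <- params$dist[[id]]
    if (identical(d$family, "complement")) next
    if (id %in% MORTALITY_PARAM_IDS) {
      if (!per_band_mortality) next
      base <- params$mortality_bands[match(id, MORTALITY_PARAM_IDS)]
      out[[id]] <- c(low = d$low, high = d$high, base = unname(base))
      next
    }
    out[[id]] <- c(low = d$low, high = d$high, base = params[[id]])
  }
  if (!per_band_mortality) {
    # one joint multiplier spanning the common +/-20% band width
    out[["mortality_multiplier"]] <- c(low = 0.8, high = 1.2, base = 1)
  }
  out
}

#' Full one-way sensitivity sweep (tornado table)
#'
#' Evaluates [one_way_sa()] for every parameter with a sampling range:
#' published ranges where Table-style ranges exist, and the seven
#' age-band mortalities varied jointly through a single 0.8-1.2
#' multiplier (set `per_band_mortality = TRUE` for independent band
#' rows). The result is ordered by descending ICER swing, the tornado
#' ordering.
#'
#' @param params An `af_params` object.
#' @param ids Optional subset of parameter ids.
#' @param per_band_mortality Vary mortality bands independently?
#' @return A data frame of class `af_owsa`, ordered by `swing`, with the
#'   base-case ICER in `attr(, "base_icer")`.
#' @export
owsa_table <- function(params, ids = NULL, per_band_mortality = FALSE) {
  ranges <- owsa_ranges(params, per_band_mortality)
  if (!is.null(ids)) ranges <- ranges[intersect(ids, names(ranges))]
  base <- icer_of(params)
  rows <- lapply(names(ranges), function(id) {
    r <- ranges[[id]]
    one_way_sa(params, id, r[["low"]], r[["high"]])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer
  attr(out, "wtp") <- params$wtp
  class(out) <- c("af_owsa", "data.frame")
  out
}

#' @export
print.af_owsa <- function(x, ...) {
  cat(sprintf("One-way sensitivity (base ICER US $%.0f/QALY, WTP $%s)\n",
              attr(x, "base_icer"),
              format(attr(x, "wtp"), big.mark = ",")))
  y <- x
  class(y) <- "data.frame"
  print(head(y, 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Threshold value of a parameter
#'
#' Searches the parameter's domain by bisection for the value at which a
#' decision criterion flips: `"icer_wtp"` (net monetary benefit zero,
#' i.e. ICER equal to the WTP threshold) or `"cost_saving"` (incremental
#' cost zero). Returns `NA` when the criterion has the same sign at both
#' bounds; a coarse scan first checks for sign-change count and warns if
#' the criterion is non-monotone over the grid.
#'
#' @param params An `af_params` object.
#' @param param_id Parameter id accepted by [set_parameter()].
#' @param criterion `"cost_saving"` or `"icer_wtp"`.
#' @param lower,upper Search interval (defaults to the parameter's
#'   sampling range).
#' @param tol Bisection tolerance as a fraction of the interval width.
#' @param grid_n Points in the monotonicity scan.
#' @return The threshold value, or `NA_real_` if no crossing exists.
#' @export
threshold_search <- function(params, param_id,
                             criterion = c("cost_saving", "icer_wtp"),
                             lower = NULL, upper = NULL, tol = 1e-4,
                             grid_n = 9) {
  criterion <- match.arg(criterion)
  if (is.null(lower) || is.null(upper)) {
    d <- params$dist[[param_id]]
    if (is.null(d)) stop("no default range for ", param_id, call. = FALSE)
    if (is.null(lower)) lower <- d$low
    if (is.null(upper)) upper <- d$high
  }
  stopifnot(lower < upper)
  f <- function(x) {
    cea <- icer_of(set_parameter(params, param_id, x))
    if (criterion == "cost_saving") cea$delta_cost else -cea$nmb
  }
  grid <- seq(lower, upper, length.out = grid_n)
  vals <- vapply(grid, f, 0)
  flips <- sum(diff(sign(vals)) != 0)
  if (flips > 1) {
    warning(sprintf("criterion is non-monotone over [%g, %g] for '%s'; grid values: %s",
                    lower, upper, param_id,
                    paste(signif(vals, 4), collapse = ", ")))
  }
  if (sign(vals[1]) == sign(vals[length(vals)])) return(NA_real_)
  lo <- lower; hi <- upper
  f_lo <- vals[1]
  width <- upper - lower
  while (hi - lo > tol * width) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Sampling distributions for the probabilistic sensitivity analysis
#'
#' Fits a `dist_spec` for every varied parameter from its base value,
#' range and family: Beta for probabilities, lognormal for ratios and
#' costs, triangular for the assumed ICH hazard ratio and the mortality
#' bands, uniform for utilities, and a joint Dirichlet for each severity
#' triple. Recurrent-type pairs are sampled through their first member
#' (Beta), the complement being implied.
#'
#' @param params An `af_params` object.
#' @param point_mass Replace every family by a degenerate point mass at
#'   the base value (for degeneracy testing).
#' @return Named list of `dist_spec` objects; the order is the fixed PSA
#'   draw order.
#' @export
psa_distributions <- function(params, point_mass = FALSE) {
  specs <- list()
  done_groups <- character()
  for (id in names(params$dist)) {
    d <- params$dist[[id]]
    if (identical(d$family, "complement")) next
    if (!is.null(d$group)) {
      if (d$group %in% done_groups) next
      members <- PROP_TRIPLES[[d$group]]
      base <- vapply(members, function(f) params[[f]], 0)
      specs[[d$group]] <- fit_distribution(unname(base),
                                           family = "dirichlet")
      done_groups <- c(done_groups, d$group)
      next
    }
    base <- if (id %in% MORTALITY_PARAM_IDS) {
      unname(params$mortality_bands[match(id, MORTALITY_PARAM_IDS)])
    } else {
      params[[id]]
    }
    specs[[id]] <- fit_distribution(base, d$low, d$high, d$family)
  }
  if (point_mass) {
    specs <- lapply(specs, function(s) {
      s$family <- "point"
      s
    })
  }
  specs
}

#' Draw one parameter set for the PSA
#'
#' Draws every varied parameter from its fitted distribution in the
#' fixed order of `specs` (severity triples jointly from their
#' Dirichlet, recurrent-type pairs by complement), using the current
#' state of R's random number generator. Draws violating a parameter-set
#' invariant are rejected and redrawn (bounded retries).
#'
#' @param params The base `af_params` (supplies non-varied fields).
#' @param specs Distribution list from [psa_distributions()].
#' @param max_retries Resampling bound before erroring.
#' @return A validated `af_params` object.
#' @export
sample_parameter_set <- function(params, specs = psa_distributions(params),
                                 max_retries = 100) {
  for (attempt in seq_len(max_retries)) {
    cand <- params
    for (nm in names(specs)) {
      spec <- specs[[nm]]
      if (spec$family == "dirichlet" ||
          (spec$family == "point" && length(spec$base) > 1)) {
        draw <- if (spec$family == "point") spec$base
                else as.vector(sample_distribution(spec, 1))
        members <- PROP_TRIPLES[[nm]]
        for (k in seq_along(members)) cand[[members[k]]] <- draw[k]
      } else if (nm %in% MORTALITY_PARAM_IDS) {
        cand$mortality_bands[match(nm, MORTALITY_PARAM_IDS)] <-
          sample_distribution(spec, 1)
      } else {
        cand[[nm]] <- sample_distribution(spec, 1)
        pr <- params$dist[[nm]]$pair
        if (!is.null(pr)) cand[[pr]] <- 1 - cand[[nm]]
      }
    }
    ok <- tryCatch({
      validate_parameters(cand)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(cand)
  }
  stop("sample_parameter_set: no valid draw after ", max_retries,
       " attempts", call. = FALSE)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: each iteration
#' draws a full parameter set from the fitted distributions, runs both
#' strategies over the full horizon, and records the incremental
#' discounted cost and QALYs. One seeded generator with a fixed draw
#' order makes runs reproducible.
#'
#' @param params An `af_params` object.
#' @param n_iter Number of iterations (>= 1).
#' @param seed Integer seed.
#' @param specs Optional distribution list (defaults to
#'   [psa_distributions()]).
#' @return An `af_psa` object: `draws` (data frame with `delta_cost`,
#'   `delta_qaly`), means with 95% percentile intervals, quadrant
#'   shares, and the seed.
#' @export
run_psa <- function(params, n_iter = 10000, seed = 1,
                    specs = psa_distributions(params)) {
  stopifnot(n_iter >= 1)
  validate_parameters(params)
  set.seed(seed)
  dc <- numeric(n_iter)
  dq <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    p_i <- sample_parameter_set(params, specs)
    cea <- run_base_case(p_i)$cea
    dc[i] <- cea$delta_cost
    dq[i] <- cea$delta_qaly
  }
  draws <- data.frame(delta_cost = dc, delta_qaly = dq)
  quadrants <- c(
    ne = mean(dq > 0 & dc > 0),    # more QALYs at higher cost
    se = mean(dq > 0 & dc <= 0),   # cost saving with QALY gain
    nw = mean(dq <= 0 & dc > 0),
    sw = mean(dq <= 0 & dc <= 0))
  structure(list(
    draws = draws, n_iter = n_iter, seed = seed, wtp = params$wtp,
    mean_delta_cost = mean(dc), mean_delta_qaly = mean(dq),
    ci_delta_cost = unname(quantile(dc, c(0.025, 0.975))),
    ci_delta_qaly = unname(quantile(dq, c(0.025, 0.975))),
    quadrants = quadrants,
    acceptance_at_wtp = mean(dq * params$wtp - dc > 0),
    ne_below_wtp = mean(dq > 0 & dc > 0 & dc / dq < params$wtp)),
    class = "af_psa")
}

#' Probability of cost-effectiveness at a willingness-to-pay value
#'
#' Fraction of PSA iterations with positive net monetary benefit
#' (`delta_qaly * wtp - delta_cost > 0`); ties favour usual care.
#'
#' @param psa An `af_psa` object.
#' @param wtp WTP value(s), US $/QALY.
#' @return Acceptance probability for each `wtp`.
#' @export
psa_acceptance <- function(psa, wtp) {
  stopifnot(inherits(psa, "af_psa"))
  vapply(wtp, function(w)
    mean(psa$draws$delta_qaly * w - psa$draws$delta_cost > 0), 0)
}

#' Cost-effectiveness acceptability curve
#'
#' For each WTP value, the probability that each strategy is preferred
#' (highest net monetary benefit); with two strategies the curves sum to
#' one, ties broken toward usual care.
#'
#' @param psa An `af_psa` object.
#' @param wtp_grid WTP grid, US $/QALY (default US $0-50,000 by $250).
#' @return A data frame of class `af_ceac`: `wtp`, `p_mhealth`,
#'   `p_usual`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 250)) {
  stopifnot(all(wtp_grid >= 0))
  p <- psa_acceptance(psa, wtp_grid)
  out <- data.frame(wtp = wtp_grid, p_mhealth = p, p_usual = 1 - p)
  class(out) <- c("af_ceac", "data.frame")
  out
}

#' WTP at which the strategies are equally likely to be preferred
#'
#' Locates the willingness-to-pay value where the mHealth acceptance
#' probability crosses `target` (default 50%), by bisection on the
#' empirical acceptance function over `wtp_range`.
#'
#' @param psa An `af_psa` object.
#' @param target Crossing probability.
#' @param wtp_range Search interval, US $/QALY.
#' @param tol Absolute tolerance in US $.
#' @return The crossing WTP, or `NA_real_` if none in range.
#' @export
ceac_crossing <- function(psa, target = 0.5, wtp_range = c(0, 50000),
                          tol = 1) {
  g <- function(w) psa_acceptance(psa, w) - target
  lo <- wtp_range[1]; hi <- wtp_range[2]
  g_lo <- g(lo)
  if (sign(g_lo) == sign(g(hi))) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(g(mid)) == sign(g_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.af_psa <- function(x, ...) {
  cat(sprintf("<af_psa> %d iterations (seed %d)\n", x$n_iter, x$seed))
  cat(sprintf("  mean delta cost US $%.0f [%.0f, %.0f]; mean delta QALYs %.4f [%.4f, %.4f]\n",
              x$mean_delta_cost, x$ci_delta_cost[1], x$ci_delta_cost[2],
              x$mean_delta_qaly, x$ci_delta_qaly[1], x$ci_delta_qaly[2]))
  cat(sprintf("  acceptance at WTP $%s: %.2f%%; NE-below-WTP %.2f%%; cost-saving %.2f%%\n",
              format(x$wtp, big.mark = ","), 100 * x$acceptance_at_wtp,
              100 * x$ne_below_wtp, 100 * x$quadrants[["se"]]))
  invisible(x)
}
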