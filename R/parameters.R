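# Model inputs: probability conversions, mortality adjustment, and the
# parameter container with its validator and JSON (de)serialisation.

# Scalar fields of an af_params object, grouped for validation.
PROB_FIELDS <- c("p_is_usual", "p_ich_usual", "p_gib_usual", "compliance",
                 "p_recur_is", "p_recur_ich")
PROP_TRIPLES <- list(
  prop_is  = c("prop_is_minor", "prop_is_major", "prop_is_fatal"),
  prop_ich = c("prop_ich_minor", "prop_ich_major", "prop_ich_fatal")
)
PROP_PAIRS <- list(
  after_is  = c("prop_is_after_is", "prop_ich_after_is"),
  after_ich = c("prop_is_after_ich", "prop_ich_after_ich")
)
RATIO_FIELDS <- c("hr_is", "hr_ich", "hr_gib", "hr_af_mortality",
                  "rr_gib_death")
UTILITY_FIELDS <- c("u_af", "u_is_minor", "u_is_major", "u_ich_minor",
                    "u_ich_major", "du_gib")
COST_FIELDS <- c("c_event_is_minor", "c_event_is_major", "c_event_ich_minor",
                 "c_event_ich_major", "c_event_gib", "c_death",
                 "c_anticoag_monthly", "c_fu_is_minor", "c_fu_is_major",
                 "c_fu_ich_minor", "c_fu_ich_major",
                 "c_mhealth_setup", "c_mhealth_monthly")
ECON_FIELDS <- c("discount_annual", "wtp", "horizon_months",
                 "start_age_years")

PARAM_FIELDS <- c(PROB_FIELDS, unlist(PROP_TRIPLES, use.names = FALSE),
                  unlist(PROP_PAIRS, use.names = FALSE), RATIO_FIELDS,
                  UTILITY_FIELDS, COST_FIELDS, ECON_FIELDS)

#' Convert a cumulative incidence to a per-cycle (monthly) probability
#'
#' Uses the standard rate-to-probability identity `p = 1 - exp(-r t)` with
#' the event rate `r` approximated as the cumulative incidence divided by
#' the observation period, applied over one monthly cycle (`t = 1`). This
#' is the convention that reproduces the published recurrence conversions
#' (5-year 41% -> 0.68%/month for IS; 44% -> 0.73%/month for ICH).
#'
#' @param cum_incidence Cumulative incidence over the observation period,
#'   a fraction in `[0, 1)`.
#' @param duration_months Length of the observation period in months (> 0).
#' @return Monthly probability of the event.
#' @examples
#' monthly_prob_from_cumulative(0.41, 60)  # ~0.0068
#' @export
monthly_prob_from_cumulative <- function(cum_incidence, duration_months) {
  if (!is.numeric(cum_incidence) || any(cum_incidence < 0) ||
      any(cum_incidence >= 1)) {
    stop("cum_incidence must be in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(duration_months) || any(duration_months <= 0)) {
    stop("duration_months must be > 0", call. = FALSE)
  }
  1 - exp(-cum_incidence / duration_months)
}

#' Apply a hazard ratio to a per-cycle probability
#'
#' Converts the probability to a rate, scales the rate by the hazard
#' ratio, and converts back: `1 - (1 - p)^hr`. Satisfies the exact
#' composition law `apply_hazard_ratio(apply_hazard_ratio(p, a), b) ==
#' apply_hazard_ratio(p, a * b)`.
#'
#' @param p Per-cycle probability in `[0, 1)`.
#' @param hr Hazard ratio (`>= 0`; 0 is the fully protective limit).
#' @return Adjusted per-cycle probability.
#' @examples
#' apply_hazard_ratio(0.00244, 0.11)
#' @export
apply_hazard_ratio <- function(p, hr) {
  if (!is.numeric(p) || any(p < 0) || any(p >= 1)) {
    stop("p must be in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(hr) || any(hr < 0)) {
    stop("hr must be >= 0", call. = FALSE)
  }
  if (length(hr) == 1L && hr == 1) return(p)  # exact identity
  res <- 1 - (1 - p)^hr
  one <- rep_len(hr, length(res)) == 1
  res[one] <- rep_len(p, length(res))[one]
  res
}

#' Age- and AF-adjusted monthly all-cause mortality
#'
#' Looks up the cohort's age band in the monthly background-mortality
#' table, applies the AF-vs-no-AF all-cause mortality hazard ratio on the
#' rate scale, and, for a cycle with a gastrointestinal bleed, further
#' applies the relative risk of death with GIB the same way.
#'
#' Ages below the lowest band use the lowest band (the cohort starts at
#' 68); ages above 95 use the terminal band.
#'
#' @param age_years Attained age of the cohort in years.
#' @param params An [af_params] object.
#' @param gib_this_cycle Logical; is this a GIB cycle?
#' @return Monthly probability of death in `[0, 1]`.
#' @export
adjusted_mortality <- function(age_years, params, gib_this_cycle = FALSE) {
  stopifnot(inherits(params, "af_params"))
  band <- mortality_band_index(age_years)
  p <- apply_hazard_ratio(unname(params$mortality_bands[band]),
                          params$hr_af_mortality)
  if (isTRUE(gib_this_cycle)) {
    p <- apply_hazard_ratio(p, params$rr_gib_death)
  }
  p
}

#' Construct a model parameter set
#'
#' Builds an `af_params` object from a named list of values (see
#' [default_parameters()] for the field inventory) and a distribution
#' table, and checks every invariant: probabilities and proportions in
#' `[0, 1]`, severity triples and recurrent-type pairs summing to one,
#' non-negative costs, positive ratios, and a mortality table covering
#' every age reachable from the start age.
#'
#' @param values Named list of scalar parameter values.
#' @param mortality_bands Named numeric vector of 7 monthly mortality
#'   probabilities (bands 65-69 ... >95).
#' @param dist Named list of per-parameter distribution entries
#'   (`family`, `low`, `high`), used by the sensitivity analyses.
#' @return A validated `af_params` object.
#' @export
af_params <- function(values, mortality_bands, dist = list()) {
  obj <- c(values, list(mortality_bands = mortality_bands, dist = dist))
  class(obj) <- "af_params"
  validate_parameters(obj)
}

#' Validate a parameter set
#'
#' Checks all `af_params` invariants and returns the object invisibly
#' unchanged; raises an error naming the offending field otherwise.
#'
#' @param params An `af_params` object.
#' @return `params`, invisibly (visibly when called directly).
#' @export
validate_parameters <- function(params) {
  if (!inherits(params, "af_params")) {
    stop("not an af_params object", call. = FALSE)
  }
  for (f in PARAM_FIELDS) {
    if (is.null(params[[f]]) || !is_scalar_number(params[[f]])) {
      stop_field(f, "missing or not a finite scalar")
    }
  }
  for (f in c(PROB_FIELDS, unlist(PROP_TRIPLES), unlist(PROP_PAIRS))) {
    v <- params[[f]]
    if (v < 0 || v > 1) stop_field(f, sprintf("probability %g not in [0, 1]", v))
  }
  for (grp in names(PROP_TRIPLES)) {
    s <- sum(vapply(PROP_TRIPLES[[grp]], function(f) params[[f]], 0))
    if (abs(s - 1) > 1e-9) {
      stop_field(grp, sprintf("severity proportions sum to %.12g, not 1", s))
    }
  }
  for (grp in names(PROP_PAIRS)) {
    s <- sum(vapply(PROP_PAIRS[[grp]], function(f) params[[f]], 0))
    if (abs(s - 1) > 1e-9) {
      stop_field(grp, sprintf("recurrent-type pair sums to %.12g, not 1", s))
    }
  }
  for (f in RATIO_FIELDS) {
    # hr = 0 is the fully protective limit (the ICH hazard ratio's
    # published range is 0-1)
    if (params[[f]] < 0) stop_field(f, "ratio must be >= 0")
  }
  for (f in UTILITY_FIELDS) {
    v <- params[[f]]
    if (v < 0 || v > 1) stop_field(f, "utility weight not in [0, 1]")
  }
  for (f in COST_FIELDS) {
    if (params[[f]] < 0) stop_field(f, "cost must be >= 0")
  }
  if (params$discount_annual < 0) stop_field("discount_annual", "must be >= 0")
  if (params$horizon_months < 1 ||
      params$horizon_months != round(params$horizon_months)) {
    stop_field("horizon_months", "must be an integer >= 1")
  }
  mb <- params$mortality_bands
  if (length(mb) != 7L || !identical(names(mb), MORTALITY_BAND_NAMES)) {
    stop_field("mortality_bands",
               "must contain the 7 named bands 65-69 ... >95")
  }
  if (any(mb < 0 | mb > 1)) {
    stop_field("mortality_bands", "monthly probabilities not in [0, 1]")
  }
  # the terminal open band guarantees coverage of every reachable age
  invisible(params)
}

load_params_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$parameters)) {
    stop("config has no 'parameters' block: ", path, call. = FALSE)
  }
  entries <- cfg$parameters
  need <- c(setdiff(PARAM_FIELDS, character()), MORTALITY_PARAM_IDS)
  missing <- setdiff(need, names(entries))
  # mortality_* ids are not scalar fields; PARAM_FIELDS has no mortality
  missing <- setdiff(missing, "mortality_bands")
  if (length(missing)) {
    stop("config is missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  values <- list()
  dist <- list()
  for (id in names(entries)) {
    e <- entries[[id]]
    if (is.null(e$value) || !is_scalar_number(e$value)) {
      stop_field(id, "entry has no numeric 'value'")
    }
    if (!is.null(e$dist) && !(e$dist %in% c("fixed", "complement"))) {
      if (is.null(e$low) || is.null(e$high)) {
        stop_field(id, "distribution entry needs 'low' and 'high'")
      }
      if (!(e$low <= e$value && e$value <= e$high)) {
        stop_field(id, sprintf("range [%g, %g] does not bracket value %g",
                               e$low, e$high, e$value))
      }
      dist[[id]] <- list(family = e$dist, low = e$low, high = e$high,
                         group = e$group, pair = e$pair, band = e$band)
    } else if (identical(e$dist, "complement")) {
      dist[[id]] <- list(family = "complement", low = e$low, high = e$high,
                         pair = e$pair)
    }
    values[[id]] <- e$value
  }
  mb <- setNames(vapply(MORTALITY_PARAM_IDS, function(id) values[[id]], 0),
                 MORTALITY_BAND_NAMES)
  values[MORTALITY_PARAM_IDS] <- NULL
  af_params(values, mb, dist)
}

#' Load a parameter set from a JSON config
#'
#' Reads a config conforming to the shipped schema
#' (`afcea-parameters-v1`), checks every invariant on load, and returns a
#' validated [af_params] object. `save_parameters()` followed by
#' `load_parameters()` is the identity.
#'
#' @param path Path to a JSON parameter file.
#' @return An `af_params` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  load_params_json(path)
}

#' The shipped base-case parameter set
#'
#' Loads the packaged base-case fixture: monthly event probabilities,
#' hazard ratios, compliance, event-type proportions, recurrence inputs,
#' age-specific mortality, utilities and costs, together with the
#' economic settings (3.5%/yr discounting, WTP US $33,438/QALY, 360
#' monthly cycles, start age 68).
#'
#' @return An `af_params` object.
#' @examples
#' p <- default_parameters()
#' p$p_is_usual
#' @export
default_parameters <- function() {
  path <- system.file("extdata", "af_parameters.json", package = "afcea",
                      mustWork = TRUE)
  load_parameters(path)
}

#' Save a parameter set to a JSON config
#'
#' Writes the schema used by [load_parameters()]; the round trip restores
#' an identical parameter set.
#'
#' @param params An `af_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  validate_parameters(params)
  entries <- list()
  for (f in setdiff(PARAM_FIELDS, "mortality_bands")) {
    e <- list(value = params[[f]])
    d <- params$dist[[f]]
    if (is.null(d)) {
      e$dist <- "fixed"
    } else {
      e$dist <- d$family
      e$low <- d$low
      e$high <- d$high
      if (!is.null(d$group)) e$group <- d$group
      if (!is.null(d$pair)) e$pair <- d$pair
    }
    entries[[f]] <- e
  }
  for (i in seq_along(MORTALITY_PARAM_IDS)) {
    id <- MORTALITY_PARAM_IDS[i]
    e <- list(value = unname(params$mortality_bands[i]))
    d <- params$dist[[id]]
    if (is.null(d)) {
      e$dist <- "fixed"
    } else {
      e$dist <- d$family
      e$low <- d$low
      e$high <- d$high
    }
    e$band <- MORTALITY_BAND_NAMES[i]
    entries[[id]] <- e
  }
  jsonlite::write_json(list(schema = "afcea-parameters-v1",
                            parameters = entries),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Set a single parameter, preserving the composition invariants
#'
#' Scalar parameters are assigned directly. A member of a severity triple
#' is set to `value` and the remaining two members are rescaled
#' proportionally so the triple still sums to one. A member of a
#' recurrent-type pair sets its complement to `1 - value`. The pseudo-id
#' `"mortality_multiplier"` scales all seven mortality bands jointly
#' (capped at 1).
#'
#' @param params An `af_params` object.
#' @param id Parameter id (a field name, a triple/pair member, a
#'   `mortality_*` band id, or `"mortality_multiplier"`).
#' @param value New value (multiplier for `"mortality_multiplier"`).
#' @return The modified, re-validated `af_params` object.
#' @export
set_parameter <- function(params, id, value) {
  stopifnot(inherits(params, "af_params"), is_scalar_number(value))
  if (id == "mortality_multiplier") {
    params$mortality_bands <- pmin(params$mortality_bands * value, 1)
    return(validate_parameters(params))
  }
  if (id %in% MORTALITY_PARAM_IDS) {
    params$mortality_bands[match(id, MORTALITY_PARAM_IDS)] <- value
    return(validate_parameters(params))
  }
  triple <- Filter(function(m) id %in% m, PROP_TRIPLES)
  if (length(triple)) {
    members <- triple[[1]]
    others <- setdiff(members, id)
    rest <- sum(vapply(others, function(f) params[[f]], 0))
    params[[id]] <- value
    if (rest > 0) {
      scale <- (1 - value) / rest
      for (f in others) params[[f]] <- params[[f]] * scale
    } else {
      for (f in others) params[[f]] <- (1 - value) / length(others)
    }
    return(validate_parameters(params))
  }
  pair <- Filter(function(m) id %in% m, PROP_PAIRS)
  if (length(pair)) {
    other <- setdiff(pair[[1]], id)
    params[[id]] <- value
    params[[other]] <- 1 - value
    return(validate_parameters(params))
  }
  if (!id %in% PARAM_FIELDS) stop("unknown parameter id: ", id, call. = FALSE)
  params[[id]] <- value
  validate_parameters(params)
}

#' @export
print.af_params <- function(x, ...) {
  cat("<af_params> AF cost-effectiveness model inputs\n")
  cat(sprintf("  horizon: %d monthly cycles from age %g; discount %.1f%%/yr; WTP US $%s/QALY\n",
              x$horizon_months, x$start_age_years,
              100 * x$discount_annual, format(x$wtp, big.mark = ",")))
  cat(sprintf("  monthly first-event probs (usual care): IS %.5f, ICH %.5f, GIB %.5f\n",
              x$p_is_usual, x$p_ich_usual, x$p_gib_usual))
  cat(sprintf("  mHealth HRs: IS %.2f, ICH %.2f, GIB %.2f; compliance %.3f\n",
              x$hr_is, x$hr_ich, x$hr_gib, x$compliance))
  cat(sprintf("  %d parameters with sampling distributions\n",
              length(x$dist)))
  invisible(x)
}
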