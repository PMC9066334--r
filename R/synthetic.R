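# Randomised but internally consistent parameter sets for property
# testing, plus a perturbation fuzzer.

#' Describe a synthetic parameter scenario
#'
#' A scenario captures the knobs of the synthetic generator: magnitude
#' scales for event probabilities, hazard ratios and costs, horizon and
#' start-age overrides, and degeneracy switches (zero mortality, zero
#' events, identity hazard ratios, point-mass distributions) that
#' produce analytically known behaviour.
#'
#' @param seed Integer seed; the generator is deterministic given the
#'   spec.
#' @param prob_scale,hr_scale,cost_scale Positive magnitude multipliers.
#' @param horizon_months,start_age_years Cohort settings.
#' @param zero_mortality,zero_events,identity_hr,point_mass Degeneracy
#'   switches.
#' @param order_utilities Impose the clinical ordering
#'   major <= minor <= event-free (default); switch off for adversarial
#'   tests.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(seed = 1, prob_scale = 1, hr_scale = 1,
                          cost_scale = 1, horizon_months = 360,
                          start_age_years = 68,
                          zero_mortality = FALSE, zero_events = FALSE,
                          identity_hr = FALSE, point_mass = FALSE,
                          order_utilities = TRUE) {
  if (prob_scale <= 0 || hr_scale <= 0 || cost_scale <= 0) {
    stop("scenario scales must be positive", call. = FALSE)
  }
  structure(list(seed = seed, prob_scale = prob_scale,
                 hr_scale = hr_scale, cost_scale = cost_scale,
                 horizon_months = horizon_months,
                 start_age_years = start_age_years,
                 zero_mortality = zero_mortality,
                 zero_events = zero_events, identity_hr = identity_hr,
                 point_mass = point_mass,
                 order_utilities = order_utilities),
            class = "scenario_spec")
}

synth_dist_entry <- function(value, family, ...) {
  lo <- value * 0.8
  hi <- value * 1.2
  if (value == 0) family <- "uniform"           # degenerate range [0, 0]
  if (family == "uniform" || family == "triangular") {
    hi <- min(hi, 1)
  }
  c(list(family = family, low = lo, high = hi), list(...))
}

#' Generate a random, internally consistent parameter set
#'
#' Draws event probabilities, severity and recurrent-type proportions
#' (normalised), hazard ratios, mortality bands (non-decreasing with
#' age), utilities (ordered major <= minor <= event-free unless switched
#' off) and costs within the scenario's magnitude scales, attaches
#' sampling ranges (+/-20% around the drawn values), and validates the
#' result. Deterministic given the scenario seed.
#'
#' @param spec A [scenario_spec()].
#' @return A validated `af_params` object.
#' @export
synth_params <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  ps <- spec$prob_scale
  v <- list()
  v$p_is_usual <- min(runif(1, 1e-4, 5e-3) * ps, 0.5)
  v$p_ich_usual <- min(runif(1, 5e-5, 1e-3) * ps, 0.5)
  v$p_gib_usual <- min(runif(1, 1e-4, 1e-3) * ps, 0.5)
  v$p_recur_is <- min(runif(1, 2e-3, 1e-2) * ps, 0.5)
  v$p_recur_ich <- min(runif(1, 2e-3, 1e-2) * ps, 0.5)
  v$hr_is <- runif(1, 0.05, 1.2) * spec$hr_scale
  v$hr_ich <- runif(1, 0.05, 1.2) * spec$hr_scale
  v$hr_gib <- runif(1, 0.05, 1.2) * spec$hr_scale
  if (spec$identity_hr) v$hr_is <- v$hr_ich <- v$hr_gib <- 1
  if (spec$zero_events) {
    v$p_is_usual <- v$p_ich_usual <- v$p_gib_usual <- 0
    v$p_recur_is <- v$p_recur_ich <- 0
  }
  v$compliance <- runif(1, 0.3, 1)
  tri_is <- runif(3); tri_is <- tri_is / sum(tri_is)
  tri_ich <- runif(3); tri_ich <- tri_ich / sum(tri_ich)
  v$prop_is_minor <- tri_is[1]; v$prop_is_major <- tri_is[2]
  v$prop_is_fatal <- tri_is[3]
  v$prop_ich_minor <- tri_ich[1]; v$prop_ich_major <- tri_ich[2]
  v$prop_ich_fatal <- tri_ich[3]
  v$prop_is_after_is <- runif(1, 0.2, 0.95)
  v$prop_ich_after_is <- 1 - v$prop_is_after_is
  v$prop_is_after_ich <- runif(1, 0.2, 0.95)
  v$prop_ich_after_ich <- 1 - v$prop_is_after_ich
  v$hr_af_mortality <- runif(1, 1, 2.5)
  v$rr_gib_death <- runif(1, 1, 4)
  mb <- sort(runif(7, 5e-4, 0.03))
  if (spec$zero_mortality) mb <- rep(0, 7)
  mb <- setNames(mb, MORTALITY_BAND_NAMES)
  u_free <- runif(1, 0.75, 1)
  u_minor <- runif(2, 0.4, if (spec$order_utilities) u_free else 1)
  u_major <- runif(2, 0.05, if (spec$order_utilities) min(u_minor) else 1)
  v$u_af <- u_free
  v$u_is_minor <- u_minor[1]; v$u_ich_minor <- u_minor[2]
  v$u_is_major <- u_major[1]; v$u_ich_major <- u_major[2]
  v$du_gib <- runif(1, 0.05, 0.3)
  cs <- spec$cost_scale
  v$c_event_is_minor <- runif(1, 1000, 5000) * cs
  v$c_event_is_major <- runif(1, 4000, 10000) * cs
  v$c_event_ich_minor <- runif(1, 2000, 8000) * cs
  v$c_event_ich_major <- runif(1, 6000, 15000) * cs
  v$c_event_gib <- runif(1, 1000, 5000) * cs
  v$c_death <- runif(1, 3000, 8000) * cs
  v$c_anticoag_monthly <- runif(1, 100, 400) * cs
  v$c_fu_is_minor <- runif(1, 100, 500) * cs
  v$c_fu_is_major <- runif(1, 300, 1000) * cs
  v$c_fu_ich_minor <- runif(1, 200, 800) * cs
  v$c_fu_ich_major <- runif(1, 500, 1500) * cs
  v$c_mhealth_setup <- runif(1, 20, 200) * cs
  v$c_mhealth_monthly <- runif(1, 5, 50) * cs
  v$discount_annual <- 0.035
  v$wtp <- 33438
  v$horizon_months <- spec$horizon_months
  v$start_age_years <- spec$start_age_years
  dist <- list()
  prob_ids <- c(PROB_FIELDS, "p_recur_is", "p_recur_ich")
  for (id in unique(prob_ids)) {
    dist[[id]] <- synth_dist_entry(v[[id]], "beta")
  }
  for (id in c("hr_is", "hr_gib", "hr_af_mortality", "rr_gib_death")) {
    dist[[id]] <- synth_dist_entry(v[[id]], "lognormal")
  }
  dist$hr_ich <- synth_dist_entry(v$hr_ich, "triangular")
  for (grp in names(PROP_TRIPLES)) {
    for (id in PROP_TRIPLES[[grp]]) {
      dist[[id]] <- synth_dist_entry(v[[id]], "dirichlet", group = grp)
    }
  }
  dist$prop_is_after_is <- synth_dist_entry(
    v$prop_is_after_is, "beta", pair = "prop_ich_after_is")
  dist$prop_ich_after_is <- list(family = "complement",
                                 pair = "prop_is_after_is")
  dist$prop_is_after_ich <- synth_dist_entry(
    v$prop_is_after_ich, "beta", pair = "prop_ich_after_ich")
  dist$prop_ich_after_ich <- list(family = "complement",
                                  pair = "prop_is_after_ich")
  for (i in seq_along(MORTALITY_PARAM_IDS)) {
    dist[[MORTALITY_PARAM_IDS[i]]] <-
      synth_dist_entry(unname(mb[i]), "triangular", band = MORTALITY_BAND_NAMES[i])
  }
  for (id in UTILITY_FIELDS) dist[[id]] <- synth_dist_entry(v[[id]], "uniform")
  for (id in COST_FIELDS) dist[[id]] <- synth_dist_entry(v[[id]], "lognormal")
  # degenerate probabilities get a point-like beta (zero-width range)
  for (id in names(dist)) {
    if (!is.null(dist[[id]]$low) && dist[[id]]$low == 0 &&
        dist[[id]]$high == 0 && dist[[id]]$family %in% c("beta", "lognormal")) {
      dist[[id]]$family <- "uniform"
    }
  }
  af_params(v, mb, dist)
}

#' Perturb a parameter set multiplicatively
#'
#' Multiplies every varied input by an independent `1 + U(-relative,
#' relative)` factor, re-normalising proportion triples and pairs and
#' clipping (with a warning) any value pushed outside its legal domain.
#' Sampling ranges are widened where needed so they still bracket the
#' perturbed values. Used for regression fuzzing of ICER stability.
#'
#' @param params An `af_params` object.
#' @param relative Maximum relative perturbation, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A validated `af_params` object.
#' @export
perturb_params <- function(params, relative, seed = 1) {
  stopifnot(inherits(params, "af_params"),
            is_scalar_number(relative), relative >= 0, relative < 1)
  validate_parameters(params)
  if (relative == 0) return(params)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  jitter <- function(x) x * (1 + runif(length(x), -relative, relative))
  clipped <- character()
  clip01 <- function(x, id) {
    if (x > 1) { clipped <<- c(clipped, id); x <- 1 }
    x
  }
  for (id in c(PROB_FIELDS, UTILITY_FIELDS)) {
    params[[id]] <- clip01(jitter(params[[id]]), id)
  }
  for (id in c(RATIO_FIELDS, COST_FIELDS)) params[[id]] <- jitter(params[[id]])
  for (grp in names(PROP_TRIPLES)) {
    members <- PROP_TRIPLES[[grp]]
    x <- jitter(unname(vapply(members, function(f) params[[f]], 0)))
    x <- x / sum(x)
    for (k in seq_along(members)) params[[members[k]]] <- x[k]
  }
  for (grp in names(PROP_PAIRS)) {
    members <- PROP_PAIRS[[grp]]
    x <- clip01(jitter(params[[members[1]]]), members[1])
    params[[members[1]]] <- x
    params[[members[2]]] <- 1 - x
  }
  params$mortality_bands <- pmin(jitter(params$mortality_bands), 1)
  if (length(clipped)) {
    warning("perturbed value(s) clipped to the legal domain: ",
            paste(unique(clipped), collapse = ", "))
  }
  # keep sampling ranges bracketing the perturbed base values
  for (id in names(params$dist)) {
    d <- params$dist[[id]]
    if (is.null(d$low)) next
    base <- if (id %in% MORTALITY_PARAM_IDS) {
      unname(params$mortality_bands[match(id, MORTALITY_PARAM_IDS)])
    } else {
      params[[id]]
    }
    params$dist[[id]]$low <- min(d$low, base)
    params$dist[[id]]$high <- max(d$high, base)
  }
  validate_parameters(params)
}
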