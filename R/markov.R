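# Transition-matrix construction and cohort propagation.

TOLL_NAMES <- c("is_minor", "is_major", "is_fatal",
                "ich_minor", "ich_major", "ich_fatal", "gib", "deaths")

#' Per-cycle event probabilities for a health state
#'
#' The well states use the first-event monthly probabilities; post-stroke
#' states use the recurrence probability keyed by the most recent event
#' type, split into IS/ICH by the recurrent-type proportions. GIB can
#' occur from every alive state. Under mHealth-based care each
#' probability is the compliance mixture
#' `c * apply_hazard_ratio(p, hr) + (1 - c) * p`: non-adherent patients
#' experience usual-care risks in that cycle.
#'
#' @param state State index or name (see [enumerate_states()]).
#' @param strategy `"usual"` or `"mhealth"`.
#' @param params An `af_params` object.
#' @return Named vector `c(is =, ich =, gib =)` of monthly probabilities.
#' @export
event_probabilities <- function(state, strategy = c("usual", "mhealth"),
                                params) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(params, "af_params"))
  i <- if (is.character(state)) match(state, STATE_TABLE$name) else as.integer(state)
  if (is.na(i) || i < 1 || i > N_STATES) stop("unknown state", call. = FALSE)
  s <- STATE_TABLE[i, ]
  if (!s$alive) stop("event probabilities are defined for alive states only",
                     call. = FALSE)
  if (s$last_event == "none") {
    p_is <- params$p_is_usual
    p_ich <- params$p_ich_usual
  } else if (s$last_event == "IS") {
    p_is <- params$p_recur_is * params$prop_is_after_is
    p_ich <- params$p_recur_is * params$prop_ich_after_is
  } else {
    p_is <- params$p_recur_ich * params$prop_is_after_ich
    p_ich <- params$p_recur_ich * params$prop_ich_after_ich
  }
  p_gib <- params$p_gib_usual
  if (strategy == "mhealth") {
    cmp <- params$compliance
    mix <- function(p, hr) cmp * apply_hazard_ratio(p, hr) + (1 - cmp) * p
    p_is <- mix(p_is, params$hr_is)
    p_ich <- mix(p_ich, params$hr_ich)
    p_gib <- mix(p_gib, params$hr_gib)
  }
  c(is = unname(p_is), ich = unname(p_ich), gib = unname(p_gib))
}

# Per-state monthly IS/ICH/GIB probabilities as an N x 3 matrix (zero on
# the death row); the vectorised core behind event_probabilities().
state_event_probs <- function(params, strategy) {
  p_is <- ifelse(STATE_TABLE$last_event == "none", params$p_is_usual,
          ifelse(STATE_TABLE$last_event == "IS",
                 params$p_recur_is * params$prop_is_after_is,
                 params$p_recur_ich * params$prop_is_after_ich))
  p_ich <- ifelse(STATE_TABLE$last_event == "none", params$p_ich_usual,
           ifelse(STATE_TABLE$last_event == "IS",
                  params$p_recur_is * params$prop_ich_after_is,
                  params$p_recur_ich * params$prop_ich_after_ich))
  p_gib <- rep(params$p_gib_usual, N_STATES)
  if (strategy == "mhealth") {
    cmp <- params$compliance
    mix <- function(p, hr) cmp * apply_hazard_ratio(p, hr) + (1 - cmp) * p
    p_is <- mix(p_is, params$hr_is)
    p_ich <- mix(p_ich, params$hr_ich)
    p_gib <- mix(p_gib, params$hr_gib)
  }
  ev <- cbind(is = p_is, ich = p_ich, gib = p_gib)
  ev[!STATE_TABLE$alive, ] <- 0
  ev
}

# Transition matrix M and toll matrix A for one age band and strategy.
# A[s, ] are the per-occupant expected event tolls when starting the
# cycle in state s (deaths are recovered from the occupancy difference).
cycle_components <- function(params, strategy, band_idx) {
  ev <- state_event_probs(params, strategy)
  if (any(ev[, "is"] + ev[, "ich"] > 1)) {
    stop("model-consistency error: IS + ICH probability exceeds 1",
         call. = FALSE)
  }
  m1 <- apply_hazard_ratio(unname(params$mortality_bands[band_idx]),
                           params$hr_af_mortality)
  m2 <- apply_hazard_ratio(m1, params$rr_gib_death)
  alive <- STATE_TABLE$alive
  # background death, with GIB-cycle excess mortality weighted by the
  # state's GIB probability
  p_death_bg <- ((1 - ev[, "gib"]) * m1 + ev[, "gib"] * m2) * alive
  surv <- (1 - p_death_bg) * alive
  is_split <- c(params$prop_is_minor, params$prop_is_major,
                params$prop_is_fatal)
  ich_split <- c(params$prop_ich_minor, params$prop_ich_major,
                 params$prop_ich_fatal)
  p_none <- surv * (1 - ev[, "is"] - ev[, "ich"])
  gib_mass <- p_none * ev[, "gib"]
  A <- cbind(is_minor = surv * ev[, "is"] * is_split[1],
             is_major = surv * ev[, "is"] * is_split[2],
             is_fatal = surv * ev[, "is"] * is_split[3],
             ich_minor = surv * ev[, "ich"] * ich_split[1],
             ich_major = surv * ev[, "ich"] * ich_split[2],
             ich_fatal = surv * ev[, "ich"] * ich_split[3],
             gib = gib_mass)
  rownames(A) <- STATE_TABLE$name
  M <- matrix(0, N_STATES, N_STATES,
              dimnames = list(STATE_TABLE$name, STATE_TABLE$name))
  idx <- seq_len(N_STATES)
  add <- function(dest, mass) {
    ij <- cbind(idx, dest)
    M[ij] <<- M[ij] + mass
  }
  add(rep(DEATH_STATE, N_STATES),
      p_death_bg + A[, "is_fatal"] + A[, "ich_fatal"])
  add(ROUTES$IS_minor, A[, "is_minor"])
  add(ROUTES$IS_major, A[, "is_major"])
  add(ROUTES$ICH_minor, A[, "ich_minor"])
  add(ROUTES$ICH_major, A[, "ich_major"])
  add(ROUTES$asa, gib_mass)
  add(idx, p_none - gib_mass)
  M[DEATH_STATE, ] <- 0
  M[DEATH_STATE, DEATH_STATE] <- 1
  list(M = M, A = A)
}

#' Build the one-cycle transition matrix
#'
#' Constructs the row-stochastic transition matrix over the expanded
#' state space for one monthly cycle, combining background mortality at
#' the cohort's attained age (`start_age + cycle / 12`, truncated to the
#' band table), IS/ICH events with severity splits and escalation
#' routing, and the GIB toll with its permanent aspirin switch.
#' Competing risks are resolved in that order: death first, then at most
#' one neurological event (IS and ICH are mutually exclusive within a
#' cycle), then GIB.
#'
#' @param cycle Zero-based cycle index (the transition from cycle to
#'   cycle + 1).
#' @param strategy `"usual"` or `"mhealth"`.
#' @param params An `af_params` object.
#' @return An `N x N` matrix; rows sum to one, the death row is the
#'   identity on death.
#' @export
build_transition_matrix <- function(cycle, strategy = c("usual", "mhealth"),
                                    params) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(params, "af_params"), cycle >= 0)
  age <- params$start_age_years + cycle / 12
  cycle_components(params, strategy, mortality_band_index(age))$M
}

#' Run the cohort simulation
#'
#' Starts the full cohort in the well-with-AF state on anticoagulation
#' and propagates the occupancy vector through `horizon` monthly cycles
#' with the age-updated transition matrix, recording per-cycle event
#' tolls (new minor/major/fatal IS and ICH, GIB episodes, deaths) as
#' cohort fractions.
#'
#' @param strategy `"usual"` or `"mhealth"`.
#' @param params An `af_params` object.
#' @param horizon Number of cycles (defaults to `params$horizon_months`).
#' @return An `af_trace` object: `occupancy` is a `(horizon + 1) x N`
#'   matrix (row 1 is cycle 0), `tolls` a `horizon x 8` matrix.
#' @examples
#' tr <- run_cohort("usual", default_parameters(), horizon = 24)
#' head(as.data.frame(tr))
#' @export
run_cohort <- function(strategy = c("usual", "mhealth"), params,
                       horizon = NULL) {
  strategy <- match.arg(strategy)
  validate_parameters(params)
  if (is.null(horizon)) horizon <- params$horizon_months
  stopifnot(horizon >= 0, horizon == round(horizon))
  horizon <- as.integer(horizon)
  occ <- matrix(0, horizon + 1L, N_STATES,
                dimnames = list(NULL, STATE_TABLE$name))
  tolls <- matrix(0, horizon, length(TOLL_NAMES),
                  dimnames = list(NULL, TOLL_NAMES))
  occ[1L, WELL_OAC] <- 1
  if (horizon > 0) {
    bands <- mortality_band_index(params$start_age_years +
                                  (seq_len(horizon) - 1L) / 12)
    comp_cache <- lapply(sort(unique(bands)), function(b)
      cycle_components(params, strategy, b))
    names(comp_cache) <- as.character(sort(unique(bands)))
    x <- occ[1L, ]
    for (t in seq_len(horizon)) {
      cc <- comp_cache[[as.character(bands[t])]]
      tolls[t, -ncol(tolls)] <- x %*% cc$A
      x_new <- as.vector(x %*% cc$M)
      tolls[t, "deaths"] <- x_new[DEATH_STATE] - x[DEATH_STATE]
      occ[t + 1L, ] <- x_new
      x <- x_new
    }
  }
  structure(list(occupancy = occ, tolls = tolls, strategy = strategy,
                 horizon = horizon,
                 start_age_years = params$start_age_years,
                 states = enumerate_states()),
            class = "af_trace")
}

#' @export
print.af_trace <- function(x, ...) {
  surv <- 1 - x$occupancy[nrow(x$occupancy), DEATH_STATE]
  cat(sprintf("<af_trace> %s care, %d monthly cycles from age %g\n",
              x$strategy, x$horizon, x$start_age_years))
  cat(sprintf("  final survival %.3f; cumulative IS %.4f, ICH %.4f, GIB %.4f\n",
              surv,
              sum(x$tolls[, c("is_minor", "is_major", "is_fatal")]),
              sum(x$tolls[, c("ich_minor", "ich_major", "ich_fatal")]),
              sum(x$tolls[, "gib"])))
  invisible(x)
}

#' @export
as.data.frame.af_trace <- function(x, ...) {
  h <- x$horizon
  data.frame(cycle = 0:h,
             as.data.frame(x$occupancy),
             rbind(NA_real_ * numeric(ncol(x$tolls)), x$tolls),
             check.names = FALSE)
}

#' Export a cohort trace as CSV
#'
#' One row per cycle with every state occupancy and toll counter (toll
#' columns are empty at cycle 0: tolls belong to the transition into the
#' cycle).
#'
#' @param trace An `af_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path) {
  stopifnot(inherits(trace, "af_trace"))
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
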