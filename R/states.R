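# The expanded health-state space and the event-routing rule.
#
# A state records the worst severity reached for each stroke type
# (IS = ischemic stroke, ICH = intracranial hemorrhage), which type
# occurred most recently (keys the recurrence inputs), and the
# antithrombotic (OAC until a first ICH or GIB forces a permanent switch
# to aspirin). GIB is a transient within-cycle toll, not a state. Death
# is a single absorbing state.
#
# Structural rules: a second minor event of the same type escalates that
# type to major; a major-class event (new or by escalation) in a patient
# who already has a major severity of either type is fatal; fatal-class
# events go straight to death. Two-major combinations are therefore
# unreachable and excluded.

STATE_TABLE <- local({
  df <- rbind(
    data.frame(is_sev = "none",  ich_sev = "none",  last_event = "none",
               anticoag = c("OAC", "ASA")),
    data.frame(is_sev = "minor", ich_sev = "none",  last_event = "IS",
               anticoag = c("OAC", "ASA")),
    data.frame(is_sev = "major", ich_sev = "none",  last_event = "IS",
               anticoag = c("OAC", "ASA")),
    data.frame(is_sev = "none",  ich_sev = c("minor", "major"),
               last_event = "ICH", anticoag = "ASA"),
    data.frame(is_sev = "minor", ich_sev = "minor",
               last_event = c("IS", "ICH"), anticoag = "ASA"),
    data.frame(is_sev = "minor", ich_sev = "major",
               last_event = c("IS", "ICH"), anticoag = "ASA"),
    data.frame(is_sev = "major", ich_sev = "minor",
               last_event = c("IS", "ICH"), anticoag = "ASA"),
    data.frame(is_sev = "dead",  ich_sev = "dead",  last_event = "dead",
               anticoag = "dead")
  )
  df$alive <- df$is_sev != "dead"
  df$name <- ifelse(!df$alive, "death",
                    paste0("is:", df$is_sev, "|ich:", df$ich_sev,
                           "|last:", df$last_event, "|", df$anticoag))
  rownames(df) <- df$name
  df
})

N_STATES <- nrow(STATE_TABLE)
DEATH_STATE <- which(!STATE_TABLE$alive)
WELL_OAC <- 1L

# index lookup by the four coordinates
state_index <- function(is_sev, ich_sev, last_event, anticoag) {
  i <- which(STATE_TABLE$is_sev == is_sev &
             STATE_TABLE$ich_sev == ich_sev &
             STATE_TABLE$last_event == last_event &
             STATE_TABLE$anticoag == anticoag)
  if (length(i) != 1L) {
    stop(sprintf("no such state: (%s, %s, %s, %s)", is_sev, ich_sev,
                 last_event, anticoag), call. = FALSE)
  }
  i
}

#' Enumerate the Markov health states
#'
#' Returns the fixed, documented ordering of the expanded state space:
#' the well-with-AF states (on OAC, and on aspirin after a GIB), the
#' single-type post-stroke states (minor/major IS or ICH, by
#' antithrombotic where reachable), the combined "IS and ICH" states
#' (minor+minor, minor+major, major+minor, keyed by the most recent
#' type), and one absorbing death state. ICH states exist only on
#' aspirin (the switch is immediate and permanent), and two-major
#' combinations are excluded (a second major event is fatal).
#'
#' @return A data frame with columns `name`, `is_sev`, `ich_sev`,
#'   `last_event`, `anticoag`, `alive`; row order is the state index used
#'   by every matrix and trace in the package.
#' @examples
#' enumerate_states()
#' @export
enumerate_states <- function() {
  df <- STATE_TABLE[, c("name", "is_sev", "ich_sev", "last_event",
                        "anticoag", "alive")]
  rownames(df) <- NULL
  df
}

# destination of a non-fatal-class event; returns the state index (death
# for events realising the two-major rule)
route_event <- function(from, type, class) {
  s <- STATE_TABLE[from, ]
  stopifnot(s$alive, type %in% c("IS", "ICH"),
            class %in% c("minor", "major"))
  sev_field <- if (type == "IS") "is_sev" else "ich_sev"
  other_field <- if (type == "IS") "ich_sev" else "is_sev"
  cur <- s[[sev_field]]
  new_sev <- if (class == "major") {
    "major"
  } else if (cur == "none") {
    "minor"
  } else if (cur == "minor") {
    "major"                     # second minor event of a type escalates
  } else {
    "major"                     # minor event on an already-major type
  }
  already_major <- cur == "major" || s[[other_field]] == "major"
  if (new_sev == "major" && already_major && !(class == "minor" && cur == "major")) {
    # a second major-class event (incl. escalation into a second major)
    return(DEATH_STATE)
  }
  anticoag <- if (type == "ICH") "ASA" else s$anticoag
  vals <- list(is_sev = s$is_sev, ich_sev = s$ich_sev)
  vals[[sev_field]] <- new_sev
  state_index(vals$is_sev, vals$ich_sev, type, anticoag)
}

# the same state after the permanent OAC -> ASA switch (GIB cycle)
asa_switch <- function(from) {
  s <- STATE_TABLE[from, ]
  if (!s$alive || s$anticoag == "ASA") return(from)
  state_index(s$is_sev, s$ich_sev, s$last_event, "ASA")
}

# Precomputed routing tables (the state space is static): destination of
# each (state, event type, event class) and of the aspirin switch.
ROUTES <- local({
  alive <- which(STATE_TABLE$alive)
  tab <- list()
  for (type in c("IS", "ICH")) {
    for (class in c("minor", "major")) {
      dest <- rep(DEATH_STATE, N_STATES)
      for (i in alive) dest[i] <- route_event(i, type, class)
      tab[[paste(type, class, sep = "_")]] <- dest
    }
  }
  tab$asa <- vapply(seq_len(N_STATES), asa_switch, 0L)
  tab
})
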