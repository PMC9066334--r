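# State space, transition matrices, and cohort propagation.

test_that("state enumeration has the documented structure", {
  st <- enumerate_states()
  st2 <- enumerate_states()
  expect_identical(st, st2)                      # deterministic ordering
  expect_equal(nrow(st), 15)
  expect_equal(sum(!st$alive), 1)                # single death state
  expect_true(any(st$is_sev == "none" & st$ich_sev == "none" &
                  st$anticoag == "OAC"))         # well on OAC
  # combined IS-and-ICH state with IS most recent, post-switch
  expect_true(any(st$is_sev == "minor" & st$ich_sev == "minor" &
                  st$last_event == "IS" & st$anticoag == "ASA"))
  # two-major combinations are excluded
  expect_false(any(st$is_sev == "major" & st$ich_sev == "major" & st$alive))
  # ICH states exist only on aspirin
  expect_true(all(st$anticoag[st$alive & st$ich_sev != "none"] == "ASA"))
  # last_event is none iff both severities are none
  expect_identical(st$last_event[st$alive] == "none",
                   (st$is_sev == "none" & st$ich_sev == "none")[st$alive])
})

test_that("event probabilities follow first-event, recurrence and compliance rules", {
  p <- base_params()
  well <- event_probabilities("is:none|ich:none|last:none|OAC", "usual", p)
  expect_equal(unname(well), c(0.00244, 0.00024, 0.00034))

  # full compliance reduces to the pure hazard-ratio adjustment
  p_full <- set_parameter(p, "compliance", 1)
  mh <- event_probabilities(1, "mhealth", p_full)
  expect_equal(mh[["is"]], apply_hazard_ratio(0.00244, 0.11))
  expect_equal(mh[["gib"]], apply_hazard_ratio(0.00034, 0.37))

  # partial compliance is the mixture
  mh2 <- event_probabilities(1, "mhealth", p)
  expect_equal(mh2[["is"]],
               0.708 * apply_hazard_ratio(0.00244, 0.11) + 0.292 * 0.00244)

  # post-IS states recur at the recurrence probability, split 91/9
  post_is <- event_probabilities("is:minor|ich:none|last:IS|OAC", "usual", p)
  expect_equal(post_is[["is"]], 0.0068 * 0.91)
  expect_equal(post_is[["ich"]], 0.0068 * 0.09)
  post_ich <- event_probabilities("is:none|ich:minor|last:ICH|ASA", "usual", p)
  expect_equal(post_ich[["is"]], 0.0073 * 0.44)
  expect_equal(post_ich[["ich"]], 0.0073 * 0.56)

  expect_error(event_probabilities("death", "usual", p), "alive")
})

test_that("transition matrices are row-stochastic with an absorbing death state", {
  p <- base_params()
  st <- enumerate_states()
  for (strat in c("usual", "mhealth")) {
    for (cyc in c(0, 100, 359)) {
      M <- build_transition_matrix(cyc, strat, p)
      expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-10)
      expect_true(all(M >= 0 & M <= 1))
      death <- which(!st$alive)
      expect_equal(unname(M[death, ]),
                   as.numeric(seq_len(nrow(M)) == death))
    }
  }
})

test_that("no-flow parameters give the identity matrix", {
  p0 <- synth_params(scenario_spec(seed = 7, zero_mortality = TRUE,
                                   zero_events = TRUE))
  M <- build_transition_matrix(0, "usual", p0)
  expect_equal(unname(M), diag(nrow(M)), tolerance = 1e-14)
})

test_that("event routing escalates, combines, and switches to aspirin", {
  p <- base_params()
  M <- build_transition_matrix(0, "usual", p)
  m1 <- adjusted_mortality(68, p)
  m2 <- adjusted_mortality(68, p, gib_this_cycle = TRUE)

  # second minor IS escalates to major IS (minor- and major-class events
  # both land there from the minor-IS state)
  from <- "is:minor|ich:none|last:IS|OAC"
  ev <- event_probabilities(from, "usual", p)
  surv <- 1 - ((1 - ev[["gib"]]) * m1 + ev[["gib"]] * m2)
  expect_equal(M[from, "is:major|ich:none|last:IS|OAC"],
               surv * ev[["is"]] * (p$prop_is_minor + p$prop_is_major))
  # cross-type minor ICH creates the combined state and forces aspirin
  expect_equal(M[from, "is:minor|ich:minor|last:ICH|ASA"],
               surv * ev[["ich"]] * p$prop_ich_minor)

  # from a major state, any major-class event is fatal; a fatal-class
  # event is always fatal
  from2 <- "is:major|ich:none|last:IS|OAC"
  ev2 <- event_probabilities(from2, "usual", p)
  surv2 <- 1 - ((1 - ev2[["gib"]]) * m1 + ev2[["gib"]] * m2)
  expect_equal(M[from2, "death"],
               (1 - surv2) +
                 surv2 * ev2[["is"]] * (p$prop_is_major + p$prop_is_fatal) +
                 surv2 * ev2[["ich"]] * (p$prop_ich_major + p$prop_ich_fatal))

  # GIB leaves the persistent state apart from the permanent OAC -> ASA
  # switch
  well <- "is:none|ich:none|last:none|OAC"
  evw <- event_probabilities(well, "usual", p)
  survw <- 1 - ((1 - evw[["gib"]]) * m1 + evw[["gib"]] * m2)
  expect_equal(M[well, "is:none|ich:none|last:none|ASA"],
               survw * (1 - evw[["is"]] - evw[["ich"]]) * evw[["gib"]])
})

test_that("cohort propagation conserves mass with monotone death", {
  p <- base_params()
  for (strat in c("usual", "mhealth")) {
    tr <- run_cohort(strat, p, horizon = 120)
    expect_equal(unname(tr$occupancy[1, ]),
                 as.numeric(seq_len(ncol(tr$occupancy)) == 1))
    expect_equal(unname(rowSums(tr$occupancy)),
                 rep(1, nrow(tr$occupancy)), tolerance = 1e-9)
    death <- tr$occupancy[, "death"]
    expect_true(all(diff(death) >= -1e-15))
    expect_true(all(tr$tolls >= -1e-15))
    expect_equal(unname(tr$tolls[, "deaths"]), unname(diff(death)),
                 tolerance = 1e-12)
  }
})

test_that("identity hazard ratios make the strategies clinically identical", {
  p <- base_params()
  for (id in c("hr_is", "hr_ich", "hr_gib")) p <- set_parameter(p, id, 1)
  p <- set_parameter(p, "compliance", 0.37)  # arbitrary compliance
  tr_u <- run_cohort("usual", p, horizon = 90)
  tr_m <- run_cohort("mhealth", p, horizon = 90)
  expect_equal(tr_u$occupancy, tr_m$occupancy, tolerance = 1e-14)
  expect_equal(tr_u$tolls, tr_m$tolls, tolerance = 1e-14)
})

test_that("raising the IS hazard ratio weakly increases mHealth IS events", {
  p <- base_params()
  cum_is <- vapply(c(0.11, 0.5, 1, 1.5), function(hr) {
    tr <- run_cohort("mhealth", set_parameter(p, "hr_is", hr), horizon = 120)
    sum(tr$tolls[, c("is_minor", "is_major", "is_fatal")])
  }, 0)
  expect_true(all(diff(cum_is) > 0))
})

test_that("cohort propagation agrees with the microsimulation oracle", {
  p <- base_params()
  n_walk <- 20000
  for (strat in c("usual", "mhealth")) {
    cohort <- run_cohort(strat, p, horizon = 360)
    micro <- microsim_trace(p, strat, n_walkers = n_walk, horizon = 360,
                            seed = 2024)
    for (cp in c(12, 60, 180, 360)) {
      pc <- cohort$occupancy[cp + 1, ]
      pm <- micro[cp + 1, ]
      tol <- 3 * sqrt(pc * (1 - pc) / n_walk) + 3 / n_walk
      expect_true(all(abs(pc - pm) <= tol),
                  label = sprintf("%s occupancy at cycle %d", strat, cp))
    }
  }
})

test_that("trace export writes one row per cycle with all counters", {
  tr <- run_cohort("usual", base_params(), horizon = 12)
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_trace(tr, tmp)
  df <- read.csv(tmp, check.names = FALSE)
  expect_equal(nrow(df), 13)
  expect_true(all(c("cycle", "death", "gib", "deaths") %in% names(df)))
  expect_equal(df$cycle, 0:12)
})
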