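# Probability conversions, mortality adjustment, distribution fitting,
# and the parameter container.

test_that("rate-to-probability conversion reproduces the published recurrence values", {
  # 5-year cumulative recurrence 41% (IS) and 44% (ICH) -> monthly
  expect_equal(round(100 * monthly_prob_from_cumulative(0.41, 60), 2), 0.68)
  expect_equal(round(100 * monthly_prob_from_cumulative(0.44, 60), 2), 0.73)
  expect_identical(monthly_prob_from_cumulative(0, 60), 0)
  expect_equal(monthly_prob_from_cumulative(0.41, 60),
               1 - exp(-0.41 / 60))
  expect_error(monthly_prob_from_cumulative(1, 60), "\\[0, 1\\)")
  expect_error(monthly_prob_from_cumulative(0.4, 0), "> 0")
})

test_that("conversion is monotone and bounded by the rate", {
  cums <- seq(0.05, 0.9, by = 0.05)
  for (t in c(6, 18, 60)) {
    p <- monthly_prob_from_cumulative(cums, t)
    expect_true(all(diff(p) > 0))          # increasing in incidence
    expect_true(all(p < cums / t + 1e-12)) # p <= rate
  }
  durs <- c(6, 12, 24, 60, 120)
  p <- monthly_prob_from_cumulative(0.41, durs)
  expect_true(all(diff(p) < 0))            # decreasing in duration
})

test_that("hazard-ratio application matches the rate-scale closed form", {
  expect_identical(apply_hazard_ratio(0.2, 1), 0.2)
  expect_identical(apply_hazard_ratio(0.2, 0), 0)
  # oracle: 1 - exp(hr * log(1 - p))
  expect_equal(apply_hazard_ratio(0.00244, 0.11),
               1 - exp(0.11 * log(1 - 0.00244)), tolerance = 1e-12)
  expect_equal(apply_hazard_ratio(0.00244, 0.11), 2.6869e-4,
               tolerance = 1e-4)
  expect_error(apply_hazard_ratio(1, 0.5), "\\[0, 1\\)")
  expect_error(apply_hazard_ratio(0.1, -1), ">= 0")
})

test_that("hazard-ratio application is monotone and composes exactly", {
  ps <- c(0.001, 0.01, 0.1, 0.5)
  hrs <- c(0.11, 0.5, 1, 1.87, 3.5)
  for (p in ps) {
    vals <- apply_hazard_ratio(p, hrs)
    expect_true(all(diff(vals) > 0))       # increasing in hr
    for (a in hrs) {
      for (b in hrs) {
        expect_equal(apply_hazard_ratio(apply_hazard_ratio(p, a), b),
                     apply_hazard_ratio(p, a * b), tolerance = 1e-9)
      }
    }
  }
  expect_true(all(diff(apply_hazard_ratio(ps, 0.37)) > 0)) # increasing in p
})

test_that("age-banded AF-adjusted mortality composes band, AF and GIB effects", {
  p <- base_params()
  expect_equal(adjusted_mortality(68, p),
               apply_hazard_ratio(0.0010, 1.87), tolerance = 1e-12)
  expect_equal(adjusted_mortality(68, p), 0.001869, tolerance = 1e-3)
  p1 <- set_parameter(p, "hr_af_mortality", 1)
  expect_equal(adjusted_mortality(68, p1), 0.0010, tolerance = 1e-12)
  expect_equal(adjusted_mortality(68, p, gib_this_cycle = TRUE),
               apply_hazard_ratio(adjusted_mortality(68, p), 3.5),
               tolerance = 1e-12)
  # band boundaries; below-range ages use the lowest band, >95 the last
  expect_equal(adjusted_mortality(60, p), adjusted_mortality(68, p))
  expect_equal(adjusted_mortality(97.9, p),
               apply_hazard_ratio(0.0181, 1.87), tolerance = 1e-12)
  expect_gt(adjusted_mortality(70, p), adjusted_mortality(69.99, p))
})

test_that("distribution fitting matches the documented conventions", {
  u <- fit_distribution(0.9, 0.8, 1.0, "uniform")
  expect_identical(u$family, "uniform")
  expect_identical(c(u$low, u$high), c(0.8, 1.0))

  ln <- fit_distribution(0.11, 0.05, 0.27, "lognormal")
  expect_equal(ln$meanlog, log(0.11), tolerance = 1e-12)
  expect_equal(ln$sdlog, (log(0.27) - log(0.05)) / 3.92, tolerance = 1e-12)
  expect_equal(ln$meanlog, -2.2073, tolerance = 1e-4)
  expect_equal(ln$sdlog, 0.4302, tolerance = 1e-4)

  tri <- fit_distribution(0.5, 0, 1, "triangular")
  expect_identical(c(tri$low, tri$base, tri$high), c(0, 0.5, 1))

  be <- fit_distribution(0.708, 0.50, 1.00, "beta")
  m <- be$shape1 / (be$shape1 + be$shape2)
  v <- be$shape1 * be$shape2 /
    ((be$shape1 + be$shape2)^2 * (be$shape1 + be$shape2 + 1))
  expect_equal(m, 0.708, tolerance = 1e-12)
  expect_equal(sqrt(v), (1.00 - 0.50) / 3.92, tolerance = 1e-12)

  di <- fit_distribution(c(0.516, 0.402, 0.082), family = "dirichlet")
  expect_equal(sum(di$alpha), 100)
  expect_equal(di$alpha / sum(di$alpha), c(0.516, 0.402, 0.082))

  expect_error(fit_distribution(0.5, 0, 1, "lognormal"), "positive")
  expect_error(fit_distribution(0.5, -3, 4, "beta"), "infeasible")
  expect_error(fit_distribution(0.5, 0.6, 1, "uniform"), "low <= base")
})

test_that("sampled draws stay in their legal domain with the fitted mean", {
  set.seed(101)
  p <- base_params()
  specs <- psa_distributions(p)
  n <- 10000
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    x <- sample_distribution(spec, n)
    if (spec$family == "dirichlet") {
      expect_true(all(x >= 0 & x <= 1), label = nm)
      expect_equal(rowSums(x), rep(1, n), tolerance = 1e-12)
      mu <- dist_mean(spec)
      for (k in seq_along(mu)) {
        se <- stats::sd(x[, k]) / sqrt(n)
        expect_lt(abs(mean(x[, k]) - mu[k]), 3 * se + 1e-6)
      }
    } else {
      if (spec$family %in% c("uniform", "triangular")) {
        expect_true(all(x >= spec$low & x <= spec$high), label = nm)
      }
      if (spec$family == "beta") expect_true(all(x > 0 & x < 1), label = nm)
      if (spec$family == "lognormal") expect_true(all(x > 0), label = nm)
      se <- stats::sd(x) / sqrt(n)
      expect_lt(abs(mean(x) - dist_mean(spec)), 3 * se + 1e-9)
    }
  }
})

test_that("the shipped fixture loads with the published base values", {
  p <- base_params()
  expect_s3_class(p, "af_params")
  expect_equal(p$p_is_usual, 0.00244)
  expect_equal(p$compliance, 0.708)
  expect_equal(p$wtp, 33438)
  expect_equal(p$horizon_months, 360)
  expect_equal(unname(p$mortality_bands[1]), 0.0010)
  expect_equal(unname(p$mortality_bands[7]), 0.0181)
  expect_equal(p$prop_is_minor + p$prop_is_major + p$prop_is_fatal, 1)
})

test_that("save/load round trip is the identity and invariants are enforced", {
  p <- base_params()
  tmp <- withr::local_tempfile(fileext = ".json")
  save_parameters(p, tmp)
  q <- load_parameters(tmp)
  for (f in afcea:::PARAM_FIELDS) expect_equal(q[[f]], p[[f]], label = f)
  expect_equal(q$mortality_bands, p$mortality_bands)

  bad <- p
  bad$prop_is_minor <- 0.6
  bad$prop_is_major <- 0.6
  bad$prop_is_fatal <- 0.2
  expect_error(validate_parameters(bad), "prop_is")
  bad2 <- p
  bad2$c_death <- -1
  expect_error(validate_parameters(bad2), "c_death")
  expect_error(load_parameters("/nonexistent/params.json"), "no such")
})

test_that("set_parameter preserves composition invariants", {
  p <- base_params()
  q <- set_parameter(p, "prop_is_fatal", 0.163)
  expect_equal(q$prop_is_minor + q$prop_is_major + q$prop_is_fatal, 1)
  # remaining members keep their relative proportions
  expect_equal(q$prop_is_minor / q$prop_is_major,
               p$prop_is_minor / p$prop_is_major, tolerance = 1e-12)

  q2 <- set_parameter(p, "prop_is_after_is", 0.73)
  expect_equal(q2$prop_ich_after_is, 0.27)

  q3 <- set_parameter(p, "mortality_multiplier", 1.2)
  expect_equal(unname(q3$mortality_bands), unname(p$mortality_bands) * 1.2)
  expect_error(set_parameter(p, "no_such_param", 1), "unknown parameter")
})
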