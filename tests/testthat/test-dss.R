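test_that("flat curves score the endpoints of the DSS scale", {
  flat100 <- logistic_fit(100, 100, 2, 0, x_min = 0, x_max = 4)
  expect_equal(dss_score(flat100)$dss, 0)
  flat0 <- logistic_fit(0, 0, 2, 0, x_min = 0, x_max = 4)
  expect_equal(dss_score(flat0)$dss, 100)
  # viability above 100% contributes zero, not negative, area
  flat110 <- logistic_fit(110, 110, 2, 0, x_min = 0, x_max = 4)
  expect_equal(dss_score(flat110)$dss, 0)
})

test_that("the reference curve reproduces the frozen trapezoid oracle value", {
  fit <- logistic_fit(100, 0, 2, 1, x_min = 0, x_max = 4)
  res <- dss_score(fit, dss_config(viability_floor = 10))
  expect_equal(res$dss, 53.8016768, tolerance = 1e-3 / 53.8)
  # x_stop is where viability first reaches the 10% floor: v = 10 at
  # x = 2 + log10(9)
  expect_equal(res$x_stop, 2 + log10(9), tolerance = 1e-6)
})

test_that("quadrature agrees with the dense-trapezoid oracle on random fits", {
  set.seed(42)
  worst <- 0
  for (i in 1:200) {
    top <- runif(1, 80, 120)
    bottom <- runif(1, 0, 1) * top
    e <- runif(1, -1, 5)
    h <- runif(1, 0, 8)
    fit <- logistic_fit(top, bottom, e, h, x_min = 0, x_max = 4)
    got <- dss_score(fit)$dss
    ref <- dss_trapezoid(top, bottom, e, h, 0, 4)
    worst <- max(worst, abs(got - ref))
  }
  expect_lt(worst, 1e-3)
})

test_that("DSS is monotone in potency and efficacy", {
  set.seed(43)
  for (i in 1:1000) {
    top <- runif(1, 90, 110)
    bottom <- runif(1, 0, 0.8) * top
    h <- runif(1, 0.3, 5)
    e <- sort(runif(2, -1, 5))
    more_potent <- dss_score(logistic_fit(top, bottom, e[1], h, 0, 4))$dss
    less_potent <- dss_score(logistic_fit(top, bottom, e[2], h, 0, 4))$dss
    expect_gte(more_potent, less_potent - 1e-9)
    b2 <- sort(runif(2, 0, top))
    deeper <- dss_score(logistic_fit(top, b2[1], e[1], h, 0, 4))$dss
    shallower <- dss_score(logistic_fit(top, b2[2], e[1], h, 0, 4))$dss
    expect_gte(deeper, shallower - 1e-9)
  }
})

test_that("DSS stays in [0, 100] and is invariant to the tested-range location", {
  set.seed(44)
  for (i in 1:50) {
    top <- runif(1, 0, 120)
    bottom <- runif(1, 0, 1) * top
    e <- runif(1, -2, 6)
    h <- runif(1, 0, 10)
    d <- dss_score(logistic_fit(top, bottom, e, h, 0, 4))$dss
    expect_gte(d, 0)
    expect_lte(d, 100)
    # same curve shape shifted with its window: equal score over equal
    # log-width windows (drug-specific ranges stay comparable)
    shift <- runif(1, -3, 3)
    d2 <- dss_score(logistic_fit(top, bottom, e + shift, h,
                                 0 + shift, 4 + shift))$dss
    expect_equal(d, d2, tolerance = 1e-6)
  }
})

test_that("the literal dose-window variant is available and labeled", {
  fit <- logistic_fit(100, 0, 2, 1, x_min = 0, x_max = 4)
  base <- dss_score(fit, dss_config(apply_window_factor = FALSE))
  win <- dss_score(fit, dss_config(apply_window_factor = TRUE))
  factor <- (win$x_stop - 0) / 4
  expect_equal(win$dss, base$dss * factor, tolerance = 1e-9)
  expect_match(win$metric_label, "window")
  expect_false(grepl("window", base$metric_label))
})

test_that("dss_table aggregates per-experiment scores with mean and sd", {
  mk <- function(e, dssv) {
    # build a curve whose DSS is known: flat at viability 100 - dssv * 0.9
    logistic_fit(100 - dssv * 0.9, 100 - dssv * 0.9, 2, 0, 0, 4,
                 sample_id = "S1", treatment_id = "d", experiment = e)
  }
  tab <- dss_table(list(mk("e1", 60), mk("e2", 70)))
  expect_equal(tab$summary$dss_mean, 65)
  expect_equal(tab$summary$dss_sd, sd(c(60, 70)))
  expect_equal(tab$summary$n_experiments, 2L)

  single <- dss_table(list(mk("e1", 42)))
  expect_equal(single$summary$dss_mean, 42)
  expect_true(is.na(single$summary$dss_sd))

  empty <- dss_table(list())
  expect_equal(nrow(empty$summary), 0)
})

test_that("a 10x more potent drug at equal efficacy scores higher through the full pipeline", {
  lib <- library_from_targets(list(A = "T1", B = "T2"))
  truth <- data.frame(sample_id = "S1", treatment_id = c("A", "B"),
                      top = 100, bottom = 0,
                      log10_ic50 = c(1.5, 2.5),  # A is 10x more potent
                      hill = 1.5, stringsAsFactors = FALSE)
  st <- simulate_screen(truth, lib, n_replicates = 2, noise_sd = 0, seed = 7)
  fits <- fit_screen(normalize_viability(st, "S1"))
  tab <- dss_table(fits)
  s <- tab$summary
  expect_gt(s$dss_mean[s$treatment_id == "A"],
            s$dss_mean[s$treatment_id == "B"])
})
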