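test_that("decay curves interpolate, clamp at the window end and reject negative times", {
  flat <- decay_curve("constant", p0 = 0.3, p_floor = 0.3, t_max = 400)
  expect_equal(curve_value(flat, 100), 0.3)

  lin <- decay_curve("linear", p0 = 0.6, p_floor = 0.2, t_max = 400)
  expect_equal(curve_value(lin, 200), 0.4)  # midpoint of the interpolation
  expect_equal(curve_value(lin, 400), 0.2)  # window-end clamp
  expect_equal(curve_value(lin, 1000), 0.2)

  lgs <- decay_curve("logistic", p0 = 0.5, p_floor = 0.1, t_max = 360,
                     shape = 60)
  expect_equal(curve_value(lgs, 0), 0.5)
  expect_equal(curve_value(lgs, 360), 0.1)
  expect_error(curve_value(lin, -1), ">= 0")
  expect_error(decay_curve("linear", p0 = 0.1, p_floor = 0.5, t_max = 100))
})

test_that("decay curves are non-increasing and bounded for all forms", {
  set.seed(11)
  tt <- sort(runif(200, 0, 600))
  for (kind in c("logistic", "linear", "constant")) {
    p0 <- runif(1, 0.5, 1)
    pf <- runif(1, 0, if (kind == "constant") 1 else p0)
    if (kind == "constant") pf <- p0
    cv <- decay_curve(kind, p0 = p0, p_floor = pf, t_max = runif(1, 100, 500),
                      shape = runif(1, 20, 120))
    v <- curve_value(cv, tt)
    expect_true(all(diff(v) <= 1e-12), info = kind)
    expect_true(all(v >= 0 & v <= 1), info = kind)
    expect_true(all(v[tt >= cv$t_max] == cv$p_floor), info = kind)
  }
})

test_that("degenerate cohort mixes collapse the expectation as expected", {
  curves <- fixture_curves()
  zero_curves <- lapply(curves, function(x)
    decay_curve("constant", 0, 0, x$t_max))
  mix0 <- cohort_mix(p_lvo = 0.5, p_nlvo = 0.3, p_good_other = 0,
                     p_good_lvo_untreated = 0, p_good_nlvo_untreated = 0)
  expect_equal(expected_good_outcome(90, 190, mix0, treatment_rates(),
                                     zero_curves), 0)

  mix1 <- cohort_mix(p_lvo = 1, p_nlvo = 0)
  half <- curves
  half$evt <- decay_curve("constant", 0.5, 0.5, 400)
  r1 <- treatment_rates(evt_rate = 1)
  for (tn in c(50, 150, 260)) {
    expect_equal(expected_good_outcome(tn, 200, mix1, r1, half), 0.5)
  }
})

test_that("hand-expanded expectation matches for the reference case", {
  # term-by-term: 0.6*(0.9*0.41 + 0.1*(0.8*0.31 + 0.2*0.05))
  #             + 0.3*(0.8*0.58 + 0.2*0.25) + 0.1*0.9
  expect_equal(
    expected_good_outcome(90, 190, fixture_mix(), treatment_rates(),
                          fixture_curves()),
    0.48108)
})

test_that("expectation equals an independent term-by-term oracle on random draws", {
  set.seed(42)
  mix <- fixture_mix()
  rates <- treatment_rates()
  curves <- fixture_curves()
  for (i in seq_len(1000)) {
    tn <- runif(1, 0, 500)
    tg <- tn + runif(1, 0, 300)
    expect_equal(
      expected_good_outcome(tn, tg, mix, rates, curves),
      oracle_expected_good_outcome(tn, tg, mix, rates, curves))
  }
  # vectorised call agrees with scalar oracle
  tn <- runif(50, 0, 500); tg <- tn + runif(50, 0, 300)
  expect_equal(expected_good_outcome(tn, tg, mix, rates, curves),
               mapply(oracle_expected_good_outcome, tn, tg,
                      MoreArgs = list(mix = mix, rates = rates,
                                      curves = curves)))
})

test_that("expectation is monotone in both times and always in [0, 1]", {
  mix <- fixture_mix(); rates <- treatment_rates(); curves <- fixture_curves()
  tn <- seq(30, 500, by = 10)
  v_needle <- expected_good_outcome(tn, 520, mix, rates, curves)
  expect_true(all(diff(v_needle) <= 1e-12))
  tg <- seq(100, 600, by = 10)
  v_groin <- expected_good_outcome(90, tg, mix, rates, curves)
  expect_true(all(diff(v_groin) <= 1e-12))
  expect_true(all(c(v_needle, v_groin) >= 0 & c(v_needle, v_groin) <= 1))
})

test_that("beyond the IVT window the result ignores the IVT curves", {
  mix <- fixture_mix(); rates <- treatment_rates()
  a <- fixture_curves()
  b <- a
  b$ivt_lvo <- decay_curve("constant", 1, 1, 10)
  b$ivt_nlvo <- decay_curve("constant", 0, 0, 10)
  for (tn in c(270, 300, 400)) {  # window limit is strict: 270 is out
    expect_equal(expected_good_outcome(tn, tn + 60, mix, rates, a),
                 expected_good_outcome(tn, tn + 60, mix, rates, b))
  }
  expect_false(isTRUE(all.equal(
    expected_good_outcome(269, 329, mix, rates, a),
    expected_good_outcome(269, 329, mix, rates, b))))
})

test_that("a missing curve for a needed pathway is a configuration error", {
  curves <- fixture_curves()
  curves$evt <- NULL
  expect_error(
    expected_good_outcome(90, 190, fixture_mix(), treatment_rates(), curves),
    "missing")
  # no EVT pathway -> the EVT curve is not needed
  expect_silent(
    expected_good_outcome(90, NA, fixture_mix(), treatment_rates(), curves))
})

test_that("cohort mix validates probabilities and derives the remainder", {
  m <- cohort_mix(p_lvo = 0.6, p_nlvo = 0.25)
  expect_equal(m$p_lvo + m$p_nlvo + m$p_other, 1, tolerance = 1e-9)
  expect_error(cohort_mix(p_lvo = 0.8, p_nlvo = 0.4), "exceed")
  expect_error(cohort_mix(p_lvo = 1.2), "\\[0, 1\\]")
  expect_error(treatment_rates(ivt_window = 0), "> 0")
})
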