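# shared fixtures: linear-curve model, small regions, and independently
# coded oracles the vectorised implementation is checked against

fixture_curves <- function() {
  list(
    evt      = decay_curve("linear", p0 = 0.6, p_floor = 0.2, t_max = 400),
    ivt_lvo  = decay_curve("linear", p0 = 0.4, p_floor = 0.1, t_max = 300),
    ivt_nlvo = decay_curve("linear", p0 = 0.7, p_floor = 0.3, t_max = 300)
  )
}

fixture_mix <- function() {
  # untreated outcomes sit at or below the corresponding curve floors, as
  # clinically expected (treatment never harms in this model)
  cohort_mix(p_lvo = 0.6, p_nlvo = 0.3, p_good_other = 0.9,
             p_good_lvo_untreated = 0.05, p_good_nlvo_untreated = 0.25)
}

fixture_config <- function() {
  model_config(cohort = fixture_mix(), rates = treatment_rates(),
               curves = fixture_curves())
}

# literal term-by-term expansion of the conditional-probability
# composition; deliberately scalar and structured differently from the
# vectorised implementation
oracle_expected_good_outcome <- function(t_needle, t_groin, mix, rates,
                                         curves) {
  ivt_elig <- !is.na(t_needle) && t_needle < rates$ivt_window
  p_ivt <- if (ivt_elig) rates$ivt_rate else 0

  # LVO branch
  if (!is.na(t_groin)) {
    p_evt_treated <- curve_value(curves$evt, t_groin)
    lvo_evt <- rates$evt_rate * p_evt_treated
    w_no_evt <- 1 - rates$evt_rate
  } else {
    lvo_evt <- 0
    w_no_evt <- 1
  }
  lvo_ivt <- if (ivt_elig) p_ivt * curve_value(curves$ivt_lvo, t_needle) else 0
  lvo_untr <- (1 - p_ivt) * mix$p_good_lvo_untreated
  p_lvo_good <- lvo_evt + w_no_evt * (lvo_ivt + lvo_untr)

  # non-LVO branch
  nlvo_ivt <- if (ivt_elig) p_ivt * curve_value(curves$ivt_nlvo, t_needle) else 0
  p_nlvo_good <- nlvo_ivt + (1 - p_ivt) * mix$p_good_nlvo_untreated

  mix$p_lvo * p_lvo_good + mix$p_nlvo * p_nlvo_good +
    mix$p_other * mix$p_good_other
}

# independent per-cell classifier: loops cells, uses only the public
# scalar API (nearest_hospital, the three timeline constructors,
# expected_good_outcome); priority mothership > DS > DD on 12-decimal ties
oracle_classify <- function(region, profiles, config, day_type, hour,
                            deltas = NULL) {
  g <- region$grid
  net <- region$network
  tv <- region$travel
  if (is.null(deltas)) {
    deltas <- paradigm_deltas(profiles, day_type, hour)
  }
  w <- config$workflow
  labels <- character(nrow(g))
  have <- function(lv) any(net$level %in% lv)
  for (i in seq_len(nrow(g))) {
    if (!g$routable[i]) {
      labels[i] <- "unroutable"
      next
    }
    probs <- c(mothership = -Inf, drip_and_ship = -Inf,
               drip_and_drive = -Inf)
    if (have(c("CSC", "CSC_PLUS"))) {
      ms <- nearest_hospital(g$x[i], g$y[i], net, tv, c("CSC", "CSC_PLUS"))
      tl <- mothership_timeline(ms$minutes, deltas$mothership, w)
      probs["mothership"] <- expected_good_outcome(
        tl$t_needle, tl$t_groin, config$cohort, config$rates, config$curves)
    }
    if (have("PSC")) {
      psc <- nearest_hospital(g$x[i], g$y[i], net, tv, "PSC")
      if (have(c("CSC", "CSC_PLUS"))) {
        tr <- nearest_hospital(psc$x, psc$y, net, tv, c("CSC", "CSC_PLUS"))
        tl <- drip_and_ship_timeline(psc$minutes, tr$minutes, deltas$ds, w)
        probs["drip_and_ship"] <- expected_good_outcome(
          tl$t_needle, tl$t_groin, config$cohort, config$rates,
          config$curves)
      }
      if (have("CSC_PLUS")) {
        iv <- nearest_hospital(psc$x, psc$y, net, tv, "CSC_PLUS")
        tl <- drip_and_drive_timeline(psc$minutes, iv$minutes, deltas$dd, w)
        probs["drip_and_drive"] <- expected_good_outcome(
          tl$t_needle, tl$t_groin, config$cohort, config$rates,
          config$curves)
      }
    }
    labels[i] <- names(probs)[which.max(round(probs, 12))]
  }
  labels
}
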