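#' Cohort mix of a screen-positive population
#'
#' Composition of the patient population that screens positive for a
#' probable large-vessel occlusion (RACE score >= 5): a fraction with a
#' true LVO, a fraction with a non-LVO ischemic stroke, and the remainder
#' (mimics and other diagnoses). Outcome probabilities for untreated and
#' mimic patients are fixed constants. The numeric defaults are synthetic
#' but deliberately plausible; P(LVO | screen positive) is not a published
#' constant of this model and must be configured for real use.
#'
#' @param p_lvo Fraction of screen-positives with LVO.
#' @param p_nlvo Fraction with non-LVO ischemic stroke.
#' @param p_good_other Good-outcome probability for mimics/other.
#' @param p_good_lvo_untreated Good-outcome probability for untreated LVO.
#' @param p_good_nlvo_untreated Good-outcome probability for untreated
#'   non-LVO stroke.
#' @return Object of class `cohort_mix`; `p_other` is derived as
#'   `1 - p_lvo - p_nlvo`.
#' @export
cohort_mix <- function(p_lvo = 0.60, p_nlvo = 0.25,
                       p_good_other = 0.85,
                       p_good_lvo_untreated = 0.10,
                       p_good_nlvo_untreated = 0.25) {
  .chk_num(p_lvo, "p_lvo", 0, 1)
  .chk_num(p_nlvo, "p_nlvo", 0, 1)
  .chk_num(p_good_other, "p_good_other", 0, 1)
  .chk_num(p_good_lvo_untreated, "p_good_lvo_untreated", 0, 1)
  .chk_num(p_good_nlvo_untreated, "p_good_nlvo_untreated", 0, 1)
  p_other <- 1 - p_lvo - p_nlvo
  if (p_other < -1e-9) {
    stop("`p_lvo` + `p_nlvo` must not exceed 1", call. = FALSE)
  }
  p_other <- max(p_other, 0)
  structure(
    list(p_lvo = p_lvo, p_nlvo = p_nlvo, p_other = p_other,
         p_good_other = p_good_other,
         p_good_lvo_untreated = p_good_lvo_untreated,
         p_good_nlvo_untreated = p_good_nlvo_untreated),
    class = "cohort_mix"
  )
}

#' Treatment rates and IVT eligibility window
#'
#' 90% of LVO patients are assumed to receive EVT and 80% of patients with
#' LVO or non-LVO occlusions receive IVT when the onset-to-needle time is
#' under 4.5 h (270 minutes, strict inequality).
#'
#' @param evt_rate Probability an LVO patient receives EVT.
#' @param ivt_rate Probability an eligible patient receives IVT.
#' @param ivt_window Onset-to-needle eligibility limit in minutes.
#' @return Object of class `treatment_rates`.
#' @export
treatment_rates <- function(evt_rate = 0.90, ivt_rate = 0.80,
                            ivt_window = 270) {
  .chk_num(evt_rate, "evt_rate", 0, 1)
  .chk_num(ivt_rate, "ivt_rate", 0, 1)
  .chk_num(ivt_window, "ivt_window")
  if (ivt_window <= 0) stop("`ivt_window` must be > 0", call. = FALSE)
  structure(list(evt_rate = evt_rate, ivt_rate = ivt_rate,
                 ivt_window = ivt_window),
            class = "treatment_rates")
}

#' Expected probability of good outcome for a screen-positive patient
#'
#' Conditional-probability composition over the cohort mix: LVO patients
#' receive EVT with probability `evt_rate` (outcome from the EVT decay
#' curve at the onset-to-groin time), otherwise IVT if eligible, otherwise
#' their untreated outcome; non-LVO stroke patients receive IVT if
#' eligible; mimics/other contribute a constant. IVT eligibility requires
#' an onset-to-needle time strictly below `ivt_window`. The composition is
#' a reconstruction built to honour those constraints; EVT-treated outcome
#' is attributed to the EVT curve alone (no IVT additivity).
#'
#' Vectorised over `t_needle` and `t_groin` (recycled to a common length).
#'
#' @param t_needle Onset-to-needle time(s) in minutes, or `NA` if there is
#'   no IVT pathway.
#' @param t_groin Onset-to-groin time(s) in minutes, or `NA` if there is
#'   no EVT pathway.
#' @param mix A [cohort_mix()].
#' @param rates A [treatment_rates()].
#' @param curves Named list of [decay_curve()]s with elements `evt`,
#'   `ivt_lvo`, `ivt_nlvo`. A curve may be omitted only if its pathway is
#'   absent for every element of the corresponding time vector.
#' @return Probability vector in `[0, 1]`.
#' @export
expected_good_outcome <- function(t_needle, t_groin, mix, rates, curves) {
  stopifnot(inherits(mix, "cohort_mix"), inherits(rates, "treatment_rates"),
            is.list(curves))
  n <- max(length(t_needle), length(t_groin))
  t_needle <- rep_len(as.numeric(t_needle), n)
  t_groin <- rep_len(as.numeric(t_groin), n)
  if (any(t_needle < 0, na.rm = TRUE) || any(t_groin < 0, na.rm = TRUE)) {
    stop("times must be >= 0 when present", call. = FALSE)
  }

  evt_path <- !is.na(t_groin)
  ivt_elig <- !is.na(t_needle) & t_needle < rates$ivt_window

  need <- c(evt = any(evt_path), ivt_lvo = any(ivt_elig),
            ivt_nlvo = any(ivt_elig))
  for (nm in names(need)) {
    if (need[[nm]] && (is.null(curves[[nm]]) ||
                       !inherits(curves[[nm]], "decay_curve"))) {
      stop(sprintf("curve `%s` is required for this pathway but missing", nm),
           call. = FALSE)
    }
  }

  p_ivt <- ifelse(ivt_elig, rates$ivt_rate, 0)
  safe_eval <- function(curve, t, use) {
    out <- numeric(length(t))
    if (any(use)) out[use] <- curve_value(curve, t[use])
    out
  }
  p_evt_t <- safe_eval(curves$evt, t_groin, evt_path)
  p_ivt_lvo_t <- safe_eval(curves$ivt_lvo, t_needle, ivt_elig)
  p_ivt_nlvo_t <- safe_eval(curves$ivt_nlvo, t_needle, ivt_elig)

  lvo_no_evt <- p_ivt * p_ivt_lvo_t + (1 - p_ivt) * mix$p_good_lvo_untreated
  evt_rate_eff <- ifelse(evt_path, rates$evt_rate, 0)
  lvo <- evt_rate_eff * p_evt_t + (1 - evt_rate_eff) * lvo_no_evt
  nlvo <- p_ivt * p_ivt_nlvo_t + (1 - p_ivt) * mix$p_good_nlvo_untreated

  mix$p_lvo * lvo + mix$p_nlvo * nlvo + mix$p_other * mix$p_good_other
}
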