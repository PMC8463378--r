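#' Model configuration
#'
#' Bundles everything the catchment classifier needs besides geography and
#' traffic: the cohort mix, treatment rates, one decay curve per treatment
#' pathway, the workflow time constants, and the traffic delta mode.
#'
#' @param cohort A [cohort_mix()].
#' @param rates A [treatment_rates()].
#' @param curves Named list with [decay_curve()]s `evt`, `ivt_lvo`,
#'   `ivt_nlvo`.
#' @param workflow A [workflow_times()].
#' @param delta_mode `"absolute"` (default) or `"proportional"` traffic
#'   generalisation.
#' @return Object of class `model_config`.
#' @export
model_config <- function(cohort = cohort_mix(),
                         rates = treatment_rates(),
                         curves = default_curves(),
                         workflow = workflow_times(),
                         delta_mode = c("absolute", "proportional")) {
  delta_mode <- match.arg(delta_mode)
  stopifnot(inherits(cohort, "cohort_mix"),
            inherits(rates, "treatment_rates"),
            inherits(workflow, "workflow_times"))
  for (nm in c("evt", "ivt_lvo", "ivt_nlvo")) {
    if (!inherits(curves[[nm]], "decay_curve")) {
      stop(sprintf("`curves$%s` must be a decay_curve", nm), call. = FALSE)
    }
  }
  structure(list(cohort = cohort, rates = rates, curves = curves,
                 workflow = workflow, delta_mode = delta_mode),
            class = "model_config")
}

#' Default synthetic decay curves
#'
#' Logistic good-outcome decay curves for the three treatment pathways.
#' These are synthetic placeholders with plausible shapes (EVT benefit
#' decaying over a 6-h window, IVT over 4.5 h); published coefficients
#' must be supplied for real use.
#'
#' @return Named list of [decay_curve()]s (`evt`, `ivt_lvo`, `ivt_nlvo`).
#' @export
default_curves <- function() {
  list(
    evt      = decay_curve("logistic", p0 = 0.50, p_floor = 0.10,
                           t_max = 360, shape = 90),
    ivt_lvo  = decay_curve("logistic", p0 = 0.25, p_floor = 0.10,
                           t_max = 270, shape = 70),
    ivt_nlvo = decay_curve("logistic", p0 = 0.55, p_floor = 0.25,
                           t_max = 270, shape = 70)
  )
}

.cfg_known <- list(
  top = c("cohort", "rates", "curves", "workflow", "traffic"),
  cohort = c("p_lvo", "p_nlvo", "p_good_other", "p_good_lvo_untreated",
             "p_good_nlvo_untreated"),
  rates = c("evt_rate", "ivt_rate", "ivt_window"),
  curve = c("kind", "p0", "p_floor", "t_max", "shape"),
  workflow = c("onset_to_fmr", "on_scene", "dtn_psc", "ntd_psc", "dtn_csc",
               "dtg_csc", "dtg_csc_fast", "reimage_window", "ntl_dd",
               "arr_to_groin_dd", "imaging_offset_psc"),
  traffic = "delta_mode"
)

.cfg_reject_unknown <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

#' Read a model configuration file
#'
#' Accepts YAML (`.yaml`/`.yml`) or JSON (`.json`). The schema has blocks
#' `cohort`, `rates`, `curves` (with `evt`, `ivt_lvo`, `ivt_nlvo`),
#' `workflow` and optional `traffic: {delta_mode}`; unknown keys are
#' rejected. Missing blocks fall back to package defaults.
#'
#' @param path Configuration file path.
#' @return A [model_config()].
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be .yaml/.yml or .json", call. = FALSE))
  .cfg_reject_unknown(raw, .cfg_known$top, "config")
  cohort <- if (is.null(raw$cohort)) cohort_mix() else {
    .cfg_reject_unknown(raw$cohort, .cfg_known$cohort, "cohort")
    do.call(cohort_mix, raw$cohort)
  }
  rates <- if (is.null(raw$rates)) treatment_rates() else {
    .cfg_reject_unknown(raw$rates, .cfg_known$rates, "rates")
    do.call(treatment_rates, raw$rates)
  }
  curves <- if (is.null(raw$curves)) default_curves() else {
    .cfg_reject_unknown(raw$curves, c("evt", "ivt_lvo", "ivt_nlvo"), "curves")
    lapply(raw$curves, function(cv) {
      .cfg_reject_unknown(cv, .cfg_known$curve, "curve")
      do.call(decay_curve, cv)
    })
  }
  workflow <- if (is.null(raw$workflow)) workflow_times() else {
    .cfg_reject_unknown(raw$workflow, .cfg_known$workflow, "workflow")
    do.call(workflow_times, raw$workflow)
  }
  delta_mode <- if (is.null(raw$traffic)) "absolute" else {
    .cfg_reject_unknown(raw$traffic, .cfg_known$traffic, "traffic")
    raw$traffic$delta_mode
  }
  model_config(cohort, rates, curves, workflow, delta_mode)
}

#' Write a model configuration to YAML
#'
#' @param config A [model_config()].
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  out <- list(
    cohort = strip(config$cohort)[.cfg_known$cohort],
    rates = strip(config$rates),
    curves = lapply(config$curves, strip),
    workflow = strip(config$workflow),
    traffic = list(delta_mode = config$delta_mode)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
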