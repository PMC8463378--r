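#' Treatment-effect decay curve
#'
#' Probability of good outcome (mRS 0--1 at 90 days) as a monotone
#' non-increasing function of onset-to-treatment time, clamped to a
#' treatment window: the curve starts at `p0` at `t = 0` and equals
#' `p_floor` at and beyond `t_max` minutes. Both IVT and EVT benefit decay
#' with time; the functional form and coefficients are configuration —
#' the defaults shipped with this package are synthetic placeholders and
#' must be replaced by published coefficients for real use.
#'
#' Supported forms:
#' * `"logistic"`: a logistic ramp centred at `t_max / 2` with scale
#'   `shape` (minutes), rescaled so the value is exactly `p0` at 0 and
#'   exactly `p_floor` at `t_max`;
#' * `"linear"`: straight-line interpolation from `p0` to `p_floor`;
#' * `"constant"`: `p0` on `[0, t_max)`, `p_floor` afterwards (use
#'   `p0 == p_floor` for a flat curve).
#'
#' @param kind Curve form, one of `"logistic"`, `"linear"`, `"constant"`.
#' @param p0 Probability at `t = 0`, in `[0, 1]`.
#' @param p_floor Probability at/after the window end, in `[0, 1]`,
#'   `p_floor <= p0`.
#' @param t_max Treatment-window length in minutes, `> 0`.
#' @param shape Scale of the logistic ramp in minutes (`> 0`); ignored for
#'   the other forms. Defaults to `t_max / 8`.
#' @return An object of class `decay_curve`.
#' @seealso [curve_value()]
#' @examples
#' cv <- decay_curve("linear", p0 = 0.6, p_floor = 0.2, t_max = 400)
#' curve_value(cv, c(0, 200, 400, 600))
#' @export
decay_curve <- function(kind = c("logistic", "linear", "constant"),
                        p0, p_floor, t_max, shape = NULL) {
  kind <- match.arg(kind)
  .chk_num(p0, "p0", 0, 1)
  .chk_num(p_floor, "p_floor", 0, 1)
  .chk_num(t_max, "t_max")
  if (t_max <= 0) stop("`t_max` must be > 0", call. = FALSE)
  if (p0 < p_floor) stop("`p0` must be >= `p_floor`", call. = FALSE)
  if (kind == "logistic") {
    if (is.null(shape)) shape <- t_max / 8
    .chk_num(shape, "shape")
    if (shape <= 0) stop("`shape` must be > 0", call. = FALSE)
  }
  structure(
    list(kind = kind, p0 = p0, p_floor = p_floor, t_max = t_max,
         shape = shape),
    class = "decay_curve"
  )
}

#' Evaluate a decay curve
#'
#' @param curve A [decay_curve()].
#' @param t Onset-to-treatment time(s) in minutes, all `>= 0`.
#' @return Probabilities in `[p_floor, p0]`; `p_floor` for `t >= t_max`.
#' @export
curve_value <- function(curve, t) {
  stopifnot(inherits(curve, "decay_curve"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric", call. = FALSE)
  }
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  tt <- pmin(t, curve$t_max)
  val <- switch(curve$kind,
    constant = ifelse(t >= curve$t_max, curve$p_floor, curve$p0),
    linear   = curve$p0 + (curve$p_floor - curve$p0) * tt / curve$t_max,
    logistic = {
      raw <- function(u) 1 / (1 + exp((u - curve$t_max / 2) / curve$shape))
      g <- (raw(tt) - raw(curve$t_max)) / (raw(0) - raw(curve$t_max))
      curve$p_floor + (curve$p0 - curve$p_floor) * pmin(pmax(g, 0), 1)
    }
  )
  pmin(pmax(val, curve$p_floor), curve$p0)
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve %s: p0=%.3f p_floor=%.3f t_max=%g%s>\n",
              x$kind, x$p0, x$p_floor, x$t_max,
              if (!is.null(x$shape)) sprintf(" shape=%g", x$shape) else ""))
  invisible(x)
}
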