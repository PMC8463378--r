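#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero
#' (`0.5 -> 1`, `-0.5 -> -1`), the convention used for all reported
#' percentages in this package. Base `round()` rounds half to even and
#' would turn, e.g., `6.5` into `6`.
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers (as doubles).
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 6.25))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# scalar numeric check; lo/hi inclusive
.chk_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lo || x > hi) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                 format(lo), format(hi), format(x)), call. = FALSE)
  }
  invisible(x)
}

# run code with a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
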