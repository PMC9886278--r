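#' sarcopaint: band-position analysis for DNA-PAINT imaging of sarcomeres
#'
#' Pipeline for extracting epitope distances from the sarcomeric Z-disc out
#' of single-molecule localization tables: multi-emitter filtering on PSF
#' fit widths, projection of picked myofibrils onto their axis, Z-disc
#' detection under the sarcomere-period constraint, Gaussian band
#' refinement, and bootstrap statistics. Includes a synthetic-data
#' generator with known ground truth.
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers user randomness.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Normalize an orientation angle to (-pi/2, pi/2]
#'
#' A myofibril axis is a line, not a direction, so orientations are only
#' defined modulo pi. All pick angles are stored in this canonical range.
#'
#' @param angle Angle(s) in radians.
#' @return Angle(s) in `(-pi/2, pi/2]`.
#' @export
normalize_angle <- function(angle) {
  a <- angle %% pi
  ifelse(a > pi / 2, a - pi, a)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
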