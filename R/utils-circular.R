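#' Angle helpers on the circle
#'
#' Small utilities used throughout the tuning analyses. All user-facing
#' angles are in degrees; internal trigonometry is in radians.
#'
#' `ang_diff_signed()` returns the minimal signed difference `a - b` wrapped
#' to (-180, 180]; `ang_diff()` its absolute value in \[0, 180\];
#' `circ_mean_deg()` the direction of the (optionally weighted) resultant
#' vector in \[0, 360).
#'
#' @param a,b angles in degrees.
#' @param theta angles in degrees.
#' @param w non-negative weights (recycled); defaults to equal weights.
#' @return Degrees, as described above.
#' @examples
#' ang_diff(350, 10)        # 20
#' circ_mean_deg(c(350, 10)) # 0
#' @export
ang_diff <- function(a, b) abs(ang_diff_signed(a, b))

#' @rdname ang_diff
#' @export
ang_diff_signed <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' @rdname ang_diff
#' @export
circ_mean_deg <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  th <- theta * pi / 180
  ang <- atan2(sum(w * sin(th)), sum(w * cos(th))) * 180 / pi
  ang %% 360
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Run `expr` under an explicit seed without touching global RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

## Deterministic sub-seed derivation so nested stages draw from independent
## streams while the whole run is governed by one user-supplied seed.
## Double arithmetic keeps intermediates exact (< 2^53) before the modulus.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483562) + 1L
}
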