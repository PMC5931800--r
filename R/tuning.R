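#' Direction tuning curve from spike responses
#'
#' Total spike count per motion direction across all trials at one contrast,
#' optionally restricted to the ON or OFF response phase of the trial (the
#' window before/after a previously determined ON/OFF temporal boundary, see
#' [split_on_off()]).
#'
#' @param rs a `spike_response_set`.
#' @param cell cell id present in `rs`.
#' @param contrast Weber contrast(s) present in the protocol; counts are
#'   pooled over the contrasts given.
#' @param phase `"ALL"`, `"ON"` or `"OFF"`.
#' @param boundary ON/OFF boundary time in seconds; required when
#'   `phase != "ALL"`.
#' @return A `tuning_curve`: list with `directions` (degrees), `counts`
#'   (spikes summed over trials), `n_trials`, `contrast`, `phase`.
#' @export
compute_tuning_curve <- function(rs, cell, contrast,
                                 phase = c("ALL", "ON", "OFF"),
                                 boundary = NULL) {
  stopifnot(inherits(rs, "spike_response_set"))
  phase <- match.arg(phase)
  if (!cell %in% rs$cells) stop("unknown cell: ", cell)
  if (!all(contrast %in% rs$protocol$contrasts))
    stop("unknown contrast: ", paste(contrast, collapse = ", "))
  if (phase != "ALL" && is.null(boundary))
    stop("phase-restricted curves need an ON/OFF boundary time")
  sp <- rs$spikes
  keep <- sp$cell_id == cell & sp$contrast_pct %in% contrast
  dirs <- sp$direction_deg[keep]
  if (phase != "ALL") {
    tt <- sp$spike_time_s[keep]
    dirs <- if (phase == "ON") dirs[tt < boundary] else dirs[tt >= boundary]
  }
  counts <- tabulate(match(dirs, rs$protocol$directions),
                     nbins = length(rs$protocol$directions))
  tuning_curve(rs$protocol$directions, counts,
               n_trials = rs$protocol$n_trials,
               contrast = contrast, phase = phase)
}

#' Construct a tuning curve from direction/count pairs
#'
#' @param directions equally spaced directions, degrees.
#' @param counts non-negative spike counts, same length.
#' @param n_trials,contrast,phase metadata carried along.
#' @return A `tuning_curve` object.
#' @export
tuning_curve <- function(directions, counts, n_trials = NA_integer_,
                         contrast = NA_real_, phase = "ALL") {
  stopifnot(length(directions) == length(counts), all(counts >= 0))
  structure(list(directions = directions, counts = as.numeric(counts),
                 n_trials = n_trials, contrast = contrast, phase = phase),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat("tuning_curve (", x$phase, ", contrast ",
      paste(x$contrast, collapse = "+"), "%): ", sum(x$counts),
      " spikes over ", length(x$directions), " directions\n", sep = "")
  invisible(x)
}

#' Direction selectivity index
#'
#' The magnitude of the spike-count-weighted vector sum over directions,
#' normalized by the total spike count:
#' \deqn{DSI = \frac{\lVert \sum_i n_i \hat u(\theta_i) \rVert}{\sum_i n_i}}
#' 0 for an untuned cell, 1 when all spikes fall in one direction.
#'
#' @param tc a [tuning_curve()].
#' @return DSI in \[0, 1\]; `NaN` with a warning for an all-zero curve.
#' @export
compute_dsi <- function(tc) {
  stopifnot(inherits(tc, "tuning_curve"))
  n <- sum(tc$counts)
  if (n == 0) {
    warning("all-zero tuning curve: DSI undefined")
    return(NaN)
  }
  th <- deg2rad(tc$directions)
  sqrt(sum(tc$counts * cos(th))^2 + sum(tc$counts * sin(th))^2) / n
}

#' Circular summary statistics of a tuning curve
#'
#' Treats the curve as a count-weighted distribution on the circle and
#' returns the mean resultant length \eqn{\bar R}, the circular mean
#' (the preferred direction), and the circular standard deviation
#' \eqn{\sigma_{circ} = \sqrt{-2 \ln \bar R}} used as the tuning width.
#'
#' @param tc a [tuning_curve()].
#' @return List with `r_bar`, `mean_deg` (preferred direction, \[0, 360)),
#'   `sigma_circ` (radians) and `sigma_circ_deg`. `r_bar = 0` yields an
#'   `Inf` width sentinel; `r_bar = 1` yields 0.
#' @export
circular_stats <- function(tc) {
  stopifnot(inherits(tc, "tuning_curve"))
  n <- sum(tc$counts)
  if (n == 0) {
    warning("all-zero tuning curve: circular statistics undefined")
    return(list(r_bar = NaN, mean_deg = NaN, sigma_circ = NaN,
                sigma_circ_deg = NaN))
  }
  th <- deg2rad(tc$directions)
  cx <- sum(tc$counts * cos(th)) / n
  sx <- sum(tc$counts * sin(th)) / n
  r_bar <- sqrt(cx^2 + sx^2)
  # exact cancellation lands at ~1e-16 in floating point; treat as zero
  sigma <- if (r_bar < 1e-12) Inf
           else if (r_bar >= 1) 0 else sqrt(-2 * log(r_bar))
  list(r_bar = r_bar, mean_deg = rad2deg(atan2(sx, cx)) %% 360,
       sigma_circ = sigma, sigma_circ_deg = rad2deg(sigma))
}

#' Invert the mean resultant length to a von Mises concentration
#'
#' Solves \eqn{\bar R = I_1(\kappa)/I_0(\kappa)} for \eqn{\kappa} using
#' Fisher's piecewise approximation followed by a bisection polish of the
#' Bessel-ratio equation.
#'
#' @param r_bar mean resultant length in \[0, 1).
#' @return kappa >= 0.
#' @export
kappa_from_rbar <- function(r_bar) {
  stopifnot(r_bar >= 0, r_bar < 1)
  if (r_bar == 0) return(0)
  k <- if (r_bar < 0.53) {
    2 * r_bar + r_bar^3 + 5 * r_bar^5 / 6
  } else if (r_bar < 0.85) {
    -0.4 + 1.39 * r_bar + 0.43 / (1 - r_bar)
  } else {
    1 / (r_bar^3 - 4 * r_bar^2 + 3 * r_bar)
  }
  a1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  f <- function(k) a1(k) - r_bar
  lo <- max(k / 2, 1e-8); hi <- k * 2 + 1e-6
  while (f(lo) > 0) lo <- lo / 2
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Fit a von Mises curve to a direction tuning curve
#'
#' Nonlinear least squares of
#' \eqn{A \exp(\kappa \cos(\theta - \mu)) / (2 \pi I_0(\kappa))}
#' to the counts, initialized at the circular mean and at the concentration
#' obtained by inverting \eqn{\bar R \approx I_1(\kappa)/I_0(\kappa)}.
#'
#' @param tc a [tuning_curve()] with at least 3 nonzero directions.
#' @return List with `mu_deg`, `kappa`, `amplitude`, `converged` and
#'   `fitted`. On non-convergence the initialization values are returned
#'   with `converged = FALSE`.
#' @export
fit_von_mises <- function(tc) {
  stopifnot(inherits(tc, "tuning_curve"))
  if (sum(tc$counts) == 0) stop("all-zero tuning curve: nothing to fit")
  if (sum(tc$counts > 0) < 3)
    stop("need >= 3 nonzero directions for a stable von Mises fit")
  cs <- circular_stats(tc)
  k0 <- kappa_from_rbar(min(cs$r_bar, 0.999))
  mu0 <- deg2rad(cs$mean_deg)
  # Riemann sum of A * f(theta) over the direction grid equals A
  a0 <- sum(tc$counts) * 2 * pi / length(tc$directions)
  th <- deg2rad(tc$directions)
  y <- tc$counts
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(kappa * cos(th - mu)) / (2 * pi * besselI(kappa, 0)),
      start = list(A = a0, kappa = k0, mu = mu0),
      lower = c(A = 0, kappa = 0, mu = -2 * pi),
      upper = c(A = Inf, kappa = 500, mu = 4 * pi),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(mu_deg = cs$mean_deg, kappa = k0,
                amplitude = a0, converged = FALSE,
                fitted = a0 * exp(k0 * cos(th - mu0)) /
                  (2 * pi * besselI(k0, 0))))
  }
  co <- coef(fit)
  list(mu_deg = rad2deg(co[["mu"]]) %% 360, kappa = co[["kappa"]],
       amplitude = co[["A"]], converged = TRUE,
       fitted = as.numeric(fitted(fit)))
}

#' Direction tuning strength
#'
#' Normalized preferred-minus-null response difference. The preferred
#' direction \eqn{\theta_{PD}} is the resultant-vector angle of the curve and
#' generally falls between sampled directions, so the preferred response is
#' estimated as a cosine-weighted sum over the two sampled directions nearest
#' \eqn{\theta_{PD}}; the null response analogously around
#' \eqn{\theta_{ND} = \theta_{PD} + 180°}:
#' \deqn{S = \frac{\sum_{i=1}^{2} r_i \cos|\theta_{PD}-\theta_i| -
#'                \sum_{j=1}^{2} r_j \cos|\theta_{ND}-\theta_j|}
#'               {\sum_{i=1}^{2} r_i \cos|\theta_{PD}-\theta_i| +
#'                \sum_{j=1}^{2} r_j \cos|\theta_{ND}-\theta_j|}}
#' with angular differences taken on the circle. For well-tuned cells the
#' index lies in \[0, 1\].
#'
#' @param tc a [tuning_curve()].
#' @return List with `strength`, `pref_dir_deg`, `null_dir_deg`,
#'   `preferred_response`, `null_response`. A perfectly balanced curve
#'   (zero resultant) has no preferred direction and returns strength 0;
#'   `NaN` with a warning when both two-term responses are zero.
#' @export
tuning_strength <- function(tc) {
  stopifnot(inherits(tc, "tuning_curve"))
  if (sum(tc$counts) == 0) {
    warning("all-zero tuning curve: tuning strength undefined")
    return(list(strength = NaN, pref_dir_deg = NaN, null_dir_deg = NaN,
                preferred_response = NaN, null_response = NaN))
  }
  cs <- circular_stats(tc)
  if (cs$r_bar < 1e-12) {
    # no resultant direction: the curve is balanced, so P = N by symmetry
    return(list(strength = 0, pref_dir_deg = NaN, null_dir_deg = NaN,
                preferred_response = NaN, null_response = NaN))
  }
  pd <- cs$mean_deg
  nd <- (pd + 180) %% 360
  two_term <- function(axis) {
    d <- ang_diff(tc$directions, axis)
    idx <- order(d)[1:2]
    sum(tc$counts[idx] * cos(deg2rad(d[idx])))
  }
  p <- two_term(pd)
  n <- two_term(nd)
  if (p + n == 0) {
    warning("zero preferred and null responses: tuning strength undefined")
    s <- NaN
  } else s <- (p - n) / (p + n)
  list(strength = s, pref_dir_deg = pd, null_dir_deg = nd,
       preferred_response = p, null_response = n)
}
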