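#' Stimulus protocol for moving-bar experiments
#'
#' Describes the drifting-bar protocol assumed by the generators and the
#' tuning analyses: a bright bar crossing the receptive field along each of
#' `n_directions` equally spaced directions, at each Weber contrast, for
#' `n_trials` repeats.
#'
#' @param directions motion directions in degrees. Default: 12 equally
#'   spaced directions, 0 to 330 in 30-degree steps.
#' @param contrasts Weber contrasts in percent; all positive.
#' @param n_trials trials per condition.
#' @param bar_speed_um_s bar speed in micrometers per second.
#' @param bar_width_um bar width in micrometers. The ON (leading edge) and
#'   OFF (trailing edge) response lobes of an ooDSGC are separated by about
#'   `bar_width_um / bar_speed_um_s` seconds.
#' @param trial_duration_s trial window in seconds; must contain both lobes.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(directions = seq(0, 330, by = 30),
                              contrasts = c(5, 10, 20, 40, 80, 150, 300),
                              n_trials = 8,
                              bar_speed_um_s = 400,
                              bar_width_um = 1200,
                              trial_duration_s = 5) {
  stopifnot(length(directions) >= 2, n_trials >= 1, all(contrasts > 0),
            bar_speed_um_s > 0, bar_width_um > 0, trial_duration_s > 0)
  directions <- sort(directions %% 360)
  gaps <- diff(c(directions, directions[1] + 360))
  if (any(abs(gaps - 360 / length(directions)) > 1e-8))
    stop("directions must be equally spaced and cover [0, 360)")
  structure(list(directions = directions, contrasts = contrasts,
                 n_trials = as.integer(n_trials),
                 bar_speed_um_s = bar_speed_um_s,
                 bar_width_um = bar_width_um,
                 trial_duration_s = trial_duration_s),
            class = "stimulus_protocol")
}

#' Ground-truth parameters for one synthetic cell
#'
#' Parameterizes the firing model of a synthetic retinal ganglion cell: a
#' bilobed (ON then OFF) response to a bright moving bar, with von Mises
#' direction tuning per lobe, Poisson spike counts and a saturating contrast
#' response.
#'
#' The expected spike count of a lobe on one trial is
#' `max(gain * exp(kappa * (cos(theta - mu) - 1)), null_rate) * s(c)`,
#' where `s(c)` is a Naka-Rushton contrast function normalized to 1 at the
#' protocol's maximum contrast, so `gain` is the expected preferred-direction
#' count per trial at maximum contrast and `null_rate` the count floor
#' opposite the preferred direction.
#'
#' @param cell_id identifier (coerced to character).
#' @param is_ds logical; `FALSE` forces both kappas to 0 (untuned).
#' @param mu_on,mu_off preferred directions of the ON and OFF lobes, degrees.
#' @param kappa_on,kappa_off von Mises concentrations (>= 0).
#' @param gain_on,gain_off expected spikes per preferred-direction trial at
#'   maximum contrast, per lobe. `gain` sets both at once.
#' @param gain shared lobe gain, used when the per-lobe gains are not given.
#' @param null_rate floor on the expected per-trial lobe count (spikes/trial).
#' @param on_peak_time,off_peak_time lobe peak times in seconds;
#'   `off_peak_time` defaults to `on_peak_time + bar_width/speed` at protocol
#'   defaults and must exceed `on_peak_time`.
#' @param lobe_sd_s temporal SD of each Gaussian response lobe, seconds.
#' @param baseline_rate_hz stimulus-independent background firing rate, Hz.
#' @param contrast_semisaturation Weber contrast (percent) at which the
#'   unnormalized contrast response reaches half its asymptote.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(cell_id, is_ds = TRUE,
                        mu_on = 0, mu_off = mu_on,
                        kappa_on = 2, kappa_off = kappa_on,
                        gain = 30, gain_on = gain, gain_off = gain,
                        null_rate = 0.5,
                        on_peak_time = 0.8, off_peak_time = 3.8,
                        lobe_sd_s = 0.15,
                        baseline_rate_hz = 0,
                        contrast_semisaturation = 20) {
  if (!is_ds) kappa_on <- kappa_off <- 0
  stopifnot(kappa_on >= 0, kappa_off >= 0,
            gain_on >= 0, gain_off >= 0, null_rate >= 0,
            off_peak_time > on_peak_time, lobe_sd_s > 0,
            baseline_rate_hz >= 0, contrast_semisaturation > 0)
  if (null_rate > max(gain_on, gain_off))
    stop("null_rate must not exceed the lobe gain")
  structure(list(cell_id = as.character(cell_id), is_ds = is_ds,
                 mu_on = mu_on %% 360, mu_off = mu_off %% 360,
                 kappa_on = kappa_on, kappa_off = kappa_off,
                 gain_on = gain_on, gain_off = gain_off,
                 null_rate = null_rate,
                 on_peak_time = on_peak_time, off_peak_time = off_peak_time,
                 lobe_sd_s = lobe_sd_s, baseline_rate_hz = baseline_rate_hz,
                 contrast_semisaturation = contrast_semisaturation),
            class = "cell_params")
}

#' Ground truth for a synthetic population
#'
#' @param cells a list of [cell_params()] objects.
#' @param protocol a [stimulus_protocol()].
#' @param seed integer seed; the same truth always generates byte-identical
#'   output.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(cells, protocol = stimulus_protocol(), seed = 1L) {
  stopifnot(length(cells) >= 1,
            all(vapply(cells, inherits, logical(1), "cell_params")),
            inherits(protocol, "stimulus_protocol"))
  ids <- vapply(cells, `[[`, character(1), "cell_id")
  if (anyDuplicated(ids)) stop("duplicate cell_id in truth")
  structure(list(cells = cells, protocol = protocol, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Saturating (Naka-Rushton) contrast response
#'
#' `contrast / (contrast + c50)`, rescaled to equal 1 at `c_max` so that
#' generator gains are expressed at the protocol's top contrast.
#'
#' @param contrast Weber contrast(s), percent.
#' @param c50 semisaturation contrast, percent.
#' @param c_max contrast at which the response is normalized to 1.
#' @return Values in (0, 1].
#' @export
contrast_response <- function(contrast, c50 = 20, c_max = 300) {
  stopifnot(all(contrast > 0), c50 > 0, c_max > 0)
  (contrast / (contrast + c50)) / (c_max / (c_max + c50))
}

## von Mises direction profile normalized to 1 at mu.
vm_profile <- function(theta_deg, mu_deg, kappa) {
  exp(kappa * (cos(deg2rad(theta_deg - mu_deg)) - 1))
}

#' Analytic expected per-trial spike counts under the generator's rate law
#'
#' The closed-form mean of the Poisson counts drawn by
#' [generate_population()], per lobe and in total, for one cell across the
#' protocol's directions at one contrast. Used as the oracle against which
#' empirical counts are checked.
#'
#' @param params a [cell_params()] object.
#' @param protocol a [stimulus_protocol()].
#' @param contrast one Weber contrast, percent.
#' @return A data frame with columns `direction_deg`, `lambda_on`,
#'   `lambda_off`, `lambda_baseline`, `lambda_total`.
#' @export
expected_counts <- function(params, protocol = stimulus_protocol(),
                            contrast = max(protocol$contrasts)) {
  stopifnot(inherits(params, "cell_params"))
  s <- contrast_response(contrast, params$contrast_semisaturation,
                         max(protocol$contrasts))
  l_on <- pmax(params$gain_on * vm_profile(protocol$directions,
                                           params$mu_on, params$kappa_on),
               if (params$gain_on > 0) params$null_rate else 0) * s
  l_off <- pmax(params$gain_off * vm_profile(protocol$directions,
                                             params$mu_off, params$kappa_off),
                if (params$gain_off > 0) params$null_rate else 0) * s
  l_base <- params$baseline_rate_hz * protocol$trial_duration_s
  data.frame(direction_deg = protocol$directions,
             lambda_on = l_on, lambda_off = l_off,
             lambda_baseline = l_base,
             lambda_total = l_on + l_off + l_base)
}

## Exact truncated-normal draws on [lo, hi] via inverse CDF (vectorized).
rtnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

#' Generate a synthetic spike-response population
#'
#' Draws spike trains for every (cell, direction, contrast, trial) condition
#' of the truth's protocol from an inhomogeneous Poisson process with two
#' Gaussian temporal lobes (ON then OFF) plus a uniform baseline. Per-trial
#' lobe counts are Poisson with the mean given by [expected_counts()]; spike
#' times are truncated-normal around the lobe peaks within the trial window.
#'
#' Output is reproducible: the same truth (including its seed) yields an
#' identical spike table, and global RNG state is left untouched.
#'
#' @param truth a [synthetic_truth()].
#' @return A `spike_response_set`: list with `spikes` (long data frame with
#'   columns `cell_id`, `direction_deg`, `contrast_pct`, `speed_um_s`,
#'   `trial`, `spike_time_s`), `protocol`, `cells` (cell ids) and `truth`.
#' @export
generate_population <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  pr <- truth$protocol
  with_seed(truth$seed, {
    tabs <- lapply(truth$cells, function(p) generate_cell_spikes(p, pr))
  })
  spikes <- do.call(rbind, tabs)
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, protocol = pr,
                 cells = vapply(truth$cells, `[[`, character(1), "cell_id"),
                 truth = truth),
            class = "spike_response_set")
}

generate_cell_spikes <- function(p, pr) {
  grid <- expand.grid(trial = seq_len(pr$n_trials),
                      direction_deg = pr$directions,
                      contrast_pct = pr$contrasts,
                      KEEP.OUT.ATTRS = FALSE)
  s <- contrast_response(grid$contrast_pct, p$contrast_semisaturation,
                         max(pr$contrasts))
  l_on <- pmax(p$gain_on * vm_profile(grid$direction_deg, p$mu_on, p$kappa_on),
               if (p$gain_on > 0) p$null_rate else 0) * s
  l_off <- pmax(p$gain_off * vm_profile(grid$direction_deg, p$mu_off,
                                        p$kappa_off),
                if (p$gain_off > 0) p$null_rate else 0) * s
  l_base <- p$baseline_rate_hz * pr$trial_duration_s
  n_on <- rpois(nrow(grid), l_on)
  n_off <- rpois(nrow(grid), l_off)
  n_base <- if (l_base > 0) rpois(nrow(grid), l_base) else integer(nrow(grid))

  lobe_times <- function(n_per_row, peak) {
    tot <- sum(n_per_row)
    if (tot == 0) return(list(row = integer(0), t = numeric(0)))
    row <- rep.int(seq_along(n_per_row), n_per_row)
    list(row = row,
         t = rtnorm(tot, peak, p$lobe_sd_s, 0, pr$trial_duration_s))
  }
  on <- lobe_times(n_on, p$on_peak_time)
  off <- lobe_times(n_off, p$off_peak_time)
  nb <- sum(n_base)
  base <- list(row = rep.int(seq_len(nrow(grid)), n_base),
               t = runif(nb, 0, pr$trial_duration_s))
  row <- c(on$row, off$row, base$row)
  tt <- c(on$t, off$t, base$t)
  o <- order(row, tt)
  row <- row[o]; tt <- tt[o]
  data.frame(cell_id = p$cell_id,
             direction_deg = grid$direction_deg[row],
             contrast_pct = grid$contrast_pct[row],
             speed_um_s = pr$bar_speed_um_s,
             trial = grid$trial[row],
             spike_time_s = tt)
}

#' Assemble a spike-response set from a long-form spike table
#'
#' The entry point for recorded (or externally simulated) data: one row per
#' spike with its condition labels. Cells or conditions with no spikes are
#' legal; list every recorded cell in `cells` so they are retained.
#'
#' @param spikes data frame with columns `cell_id`, `direction_deg`,
#'   `contrast_pct`, `trial`, `spike_time_s` (and optionally `speed_um_s`).
#' @param protocol the [stimulus_protocol()] under which they were recorded.
#' @param cells character vector of all recorded cell ids; defaults to the
#'   ids present in `spikes`.
#' @return A `spike_response_set`.
#' @export
spike_response_set <- function(spikes, protocol, cells = NULL) {
  stopifnot(is.data.frame(spikes), inherits(protocol, "stimulus_protocol"),
            all(c("cell_id", "direction_deg", "contrast_pct", "trial",
                  "spike_time_s") %in% names(spikes)))
  spikes$cell_id <- as.character(spikes$cell_id)
  if (is.null(cells)) cells <- unique(spikes$cell_id)
  if (!all(spikes$direction_deg %in% protocol$directions))
    stop("spike table contains directions not in the protocol")
  if (!all(spikes$contrast_pct %in% protocol$contrasts))
    stop("spike table contains contrasts not in the protocol")
  if (any(spikes$spike_time_s < 0 |
          spikes$spike_time_s > protocol$trial_duration_s))
    stop("spike times outside the trial window")
  structure(list(spikes = spikes, protocol = protocol,
                 cells = as.character(cells), truth = NULL),
            class = "spike_response_set")
}

#' @export
print.spike_response_set <- function(x, ...) {
  cat("spike_response_set:", length(x$cells), "cells,",
      length(x$protocol$directions), "directions x",
      length(x$protocol$contrasts), "contrasts x",
      x$protocol$n_trials, "trials;",
      nrow(x$spikes), "spikes\n")
  invisible(x)
}

#' Retrieve spike times for one condition
#'
#' @param rs a `spike_response_set`.
#' @param cell cell id.
#' @param direction,contrast condition selectors; `NULL` pools over that
#'   dimension.
#' @return A list of numeric vectors, one per trial (length `n_trials` when
#'   a single condition is selected, pooled across conditions otherwise).
#' @export
condition_spikes <- function(rs, cell, direction = NULL, contrast = NULL) {
  stopifnot(inherits(rs, "spike_response_set"))
  if (!cell %in% rs$cells) stop("unknown cell: ", cell)
  sp <- rs$spikes
  keep <- sp$cell_id == cell
  if (!is.null(direction)) keep <- keep & sp$direction_deg %in% direction
  if (!is.null(contrast)) keep <- keep & sp$contrast_pct %in% contrast
  sp <- sp[keep, , drop = FALSE]
  lapply(seq_len(rs$protocol$n_trials),
         function(tr) sp$spike_time_s[sp$trial == tr])
}
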