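#' Smoothed peri-stimulus time histogram
#'
#' Spike times pooled over the selected conditions, binned at `bin_s`
#' (1 ms by default) and smoothed with a Gaussian kernel. Rates are in Hz per
#' trial-condition.
#'
#' @param rs a `spike_response_set`.
#' @param cell cell id.
#' @param contrast contrast(s) to pool; default all.
#' @param bin_s bin width in seconds.
#' @param smooth_sd_s Gaussian smoothing SD in seconds (0 disables).
#' @return List with `time_s` (bin centers), `rate_hz` (smoothed),
#'   `counts` (raw per-bin counts), `n_sweeps` (trial-conditions pooled).
#' @export
psth <- function(rs, cell, contrast = NULL, bin_s = 0.001,
                 smooth_sd_s = 0.025) {
  stopifnot(inherits(rs, "spike_response_set"))
  if (!cell %in% rs$cells) stop("unknown cell: ", cell)
  pr <- rs$protocol
  if (is.null(contrast)) contrast <- pr$contrasts
  sp <- rs$spikes
  keep <- sp$cell_id == cell & sp$contrast_pct %in% contrast
  tt <- sp$spike_time_s[keep]
  edges <- seq(0, pr$trial_duration_s, by = bin_s)
  if (tail(edges, 1) < pr$trial_duration_s)
    edges <- c(edges, pr$trial_duration_s)
  counts <- if (length(tt)) {
    tabulate(findInterval(tt, edges, rightmost.closed = TRUE),
             nbins = length(edges) - 1)
  } else integer(length(edges) - 1)
  n_sweeps <- length(pr$directions) * length(contrast) * pr$n_trials
  rate <- counts / (bin_s * n_sweeps)
  if (smooth_sd_s > 0) {
    half <- ceiling(4 * smooth_sd_s / bin_s)
    kern <- dnorm(seq(-half, half) * bin_s, sd = smooth_sd_s)
    kern <- kern / sum(kern)
    # zero-padded convolution keeps the vector length and avoids wrap-around
    padded <- c(numeric(half), rate, numeric(half))
    sm <- stats::filter(padded, kern, sides = 2)
    rate <- as.numeric(sm[(half + 1):(half + length(rate))])
  }
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  list(time_s = mids, rate_hz = rate, counts = counts, n_sweeps = n_sweeps)
}

## Plateau-aware local maxima of a numeric series. Returns index (plateau
## center, possibly fractional), height, and prominence (height above the
## higher of the two flanking minima separating the peak from higher ground
## or the series ends).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(data.frame(index = numeric(0), height = numeric(0),
                               prominence = numeric(0)))
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  idx <- numeric(0); hgt <- numeric(0)
  for (i in seq_len(k)) {
    left_ok <- i == 1 || r$values[i - 1] < r$values[i]
    right_ok <- i == k || r$values[i + 1] < r$values[i]
    if (left_ok && right_ok && !(i == 1 && i == k)) {
      idx <- c(idx, (starts[i] + ends[i]) / 2)
      hgt <- c(hgt, r$values[i])
    }
  }
  prom <- vapply(seq_along(idx), function(p) {
    i <- idx[p]; h <- hgt[p]
    left <- y[seq_len(max(1, floor(i)))]
    right <- y[min(n, ceiling(i)):n]
    higher_l <- which(left > h)
    higher_r <- which(right > h)
    base_l <- if (length(higher_l)) min(left[max(higher_l):length(left)])
              else min(left)
    base_r <- if (length(higher_r)) min(right[1:min(higher_r)])
              else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  data.frame(index = idx, height = hgt, prominence = prom)
}

#' Segment ON and OFF responses of an ooDSGC
#'
#' Builds a direction-pooled PSTH at high contrast, locates the two largest
#' temporal response peaks (ON first, OFF second), and sets the ON/OFF
#' boundary halfway between the two peak times. The same boundary is then
#' applicable at every contrast. ON and OFF tuning curves are computed from
#' the spikes before/after the boundary at `curve_contrast`.
#'
#' @param rs a `spike_response_set`.
#' @param cell cell id.
#' @param contrast_high high contrast(s) used to define the boundary;
#'   defaults to the two highest contrasts of the protocol.
#' @param curve_contrast contrast at which the phase tuning curves are
#'   computed; defaults to the protocol maximum.
#' @param min_separation_s minimum time between the two peaks.
#' @param min_prominence_frac a candidate peak must rise above its flanking
#'   minima by at least this fraction of the tallest peak's rate, so ripples
#'   on a single lobe's flank do not count as a second lobe.
#' @param bin_s,smooth_sd_s PSTH parameters (see [psth()]).
#' @return An `on_off_split`: list with `boundary_time`, `on_peak_time`,
#'   `off_peak_time`, `on_peak_rate`, `off_peak_rate`, `peak_ratio`
#'   (smaller/larger), `bilobed` (logical: two separable peaks found),
#'   `on_curve`, `off_curve`. When fewer than two separable peaks exist the
#'   split is returned with `bilobed = FALSE` and `NULL` curves; such cells
#'   are not ooDSGCs (see [isolate_oods()]).
#' @export
split_on_off <- function(rs, cell,
                         contrast_high = NULL,
                         curve_contrast = NULL,
                         min_separation_s = 0.5,
                         min_prominence_frac = 0.1,
                         bin_s = 0.001, smooth_sd_s = 0.025) {
  stopifnot(inherits(rs, "spike_response_set"))
  pr <- rs$protocol
  if (is.null(contrast_high))
    contrast_high <- tail(sort(pr$contrasts), 2)
  if (is.null(curve_contrast)) curve_contrast <- max(pr$contrasts)
  ph <- psth(rs, cell, contrast = contrast_high, bin_s = bin_s,
             smooth_sd_s = smooth_sd_s)
  pk <- local_maxima(ph$rate_hz)
  if (nrow(pk))
    pk <- pk[pk$height > 0 &
               pk$prominence >= min_prominence_frac * max(pk$height), ,
             drop = FALSE]
  res <- list(boundary_time = NA_real_, on_peak_time = NA_real_,
              off_peak_time = NA_real_, on_peak_rate = NA_real_,
              off_peak_rate = NA_real_, peak_ratio = NA_real_,
              bilobed = FALSE, on_curve = NULL, off_curve = NULL,
              cell = cell)
  if (nrow(pk) >= 2) {
    pk <- pk[order(-pk$height), , drop = FALSE]
    t1 <- ph$time_s[pmin(length(ph$time_s), round(pk$index[1]))]
    # second peak: highest one far enough from the first
    far <- abs(ph$time_s[pmin(length(ph$time_s), round(pk$index))] - t1) >=
      min_separation_s
    if (any(far)) {
      j <- which(far)[1]
      t2 <- ph$time_s[pmin(length(ph$time_s), round(pk$index[j]))]
      on_t <- min(t1, t2); off_t <- max(t1, t2)
      h1 <- pk$height[1]; h2 <- pk$height[j]
      res$boundary_time <- (on_t + off_t) / 2
      res$on_peak_time <- on_t
      res$off_peak_time <- off_t
      res$on_peak_rate <- if (t1 < t2) h1 else h2
      res$off_peak_rate <- if (t1 < t2) h2 else h1
      res$peak_ratio <- min(h1, h2) / max(h1, h2)
      res$bilobed <- TRUE
      res$on_curve <- compute_tuning_curve(rs, cell, curve_contrast,
                                           phase = "ON",
                                           boundary = res$boundary_time)
      res$off_curve <- compute_tuning_curve(rs, cell, curve_contrast,
                                            phase = "OFF",
                                            boundary = res$boundary_time)
    }
  }
  structure(res, class = "on_off_split")
}

#' ON-OFF preferred-direction difference
#'
#' The minimal angular difference, in \[0, 180\] degrees, between the
#' preferred directions (resultant-vector angles) of the ON and OFF tuning
#' curves of one cell.
#'
#' @param split an `on_off_split` from [split_on_off()].
#' @return Degrees in \[0, 180\]; `NaN` with a warning when either phase
#'   curve is all-zero or the split is not bilobed.
#' @export
delta_phi <- function(split) {
  stopifnot(inherits(split, "on_off_split"))
  if (!isTRUE(split$bilobed) || is.null(split$on_curve) ||
      is.null(split$off_curve)) {
    warning("no bilobed ON/OFF split: delta-phi undefined")
    return(NaN)
  }
  if (sum(split$on_curve$counts) == 0 || sum(split$off_curve$counts) == 0) {
    warning("empty ON or OFF phase curve: delta-phi undefined")
    return(NaN)
  }
  on_pd <- circular_stats(split$on_curve)$mean_deg
  off_pd <- circular_stats(split$off_curve)$mean_deg
  ang_diff(on_pd, off_pd)
}

#' Per-cell tuning metrics table
#'
#' Convenience driver: for each cell computes the full-response tuning curve
#' at `contrast`, DSI, preferred direction, circular-SD width, tuning
#' strength, and (for bilobed cells) the ON-OFF preferred-direction
#' difference.
#'
#' @param rs a `spike_response_set`.
#' @param contrast contrast at which metrics are computed; default protocol
#'   maximum.
#' @param cells subset of cell ids; default all.
#' @param split logical: run [split_on_off()] per cell for `delta_phi`.
#' @return Data frame with one row per cell: `cell_id`, `contrast`, `dsi`,
#'   `pref_dir_deg`, `width_deg`, `strength`, `r_bar`, `bilobed`,
#'   `peak_ratio`, `delta_phi_deg`.
#' @export
cell_metrics <- function(rs, contrast = NULL, cells = NULL, split = TRUE) {
  stopifnot(inherits(rs, "spike_response_set"))
  if (is.null(contrast)) contrast <- max(rs$protocol$contrasts)
  if (is.null(cells)) cells <- rs$cells
  rows <- lapply(cells, function(cl) {
    tc <- compute_tuning_curve(rs, cl, contrast)
    empty <- sum(tc$counts) == 0
    cs <- if (empty) list(r_bar = NaN, mean_deg = NaN, sigma_circ_deg = NaN)
          else circular_stats(tc)
    st <- if (empty) list(strength = NaN) else tuning_strength(tc)
    dsi <- if (empty) NaN else compute_dsi(tc)
    dphi <- NaN; bil <- NA; ratio <- NA_real_
    if (split && !empty) {
      so <- split_on_off(rs, cl, curve_contrast = contrast)
      bil <- so$bilobed
      ratio <- so$peak_ratio
      if (so$bilobed) dphi <- suppressWarnings(delta_phi(so))
    }
    data.frame(cell_id = cl, contrast = contrast, dsi = dsi,
               pref_dir_deg = cs$mean_deg, width_deg = cs$sigma_circ_deg,
               strength = st$strength, r_bar = cs$r_bar,
               bilobed = bil, peak_ratio = ratio, delta_phi_deg = dphi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
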