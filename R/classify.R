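#' Spike-train quality-control filter
#'
#' Excludes units whose spike trains suggest poor isolation: estimated
#' contamination (fraction of inter-spike intervals shorter than the
#' refractory period) above `contamination_max`, or mean firing rate below
#' `min_rate_hz`.
#'
#' @param spike_times spike times in seconds (one continuous train), or a
#'   list of per-trial trains; ISIs are computed within trains.
#' @param duration_s total recorded time in seconds.
#' @param refractory_ms refractory window in milliseconds.
#' @param contamination_max maximum tolerated contamination fraction.
#' @param min_rate_hz minimum mean firing rate in Hz.
#' @return List with `qc_pass`, `qc_reason` (`""`, `"contamination"` or
#'   `"rate"`), `contamination`, `rate_hz`.
#' @export
qc_filter <- function(spike_times, duration_s, refractory_ms = 1.5,
                      contamination_max = 0.10, min_rate_hz = 1) {
  stopifnot(duration_s > 0)
  trains <- if (is.list(spike_times)) spike_times else list(spike_times)
  isis <- unlist(lapply(trains, function(x) diff(sort(x))))
  n <- sum(lengths(trains))
  contamination <- if (length(isis)) mean(isis < refractory_ms / 1000) else 0
  rate <- n / duration_s
  reason <- ""
  if (contamination > contamination_max) reason <- "contamination"
  else if (rate < min_rate_hz) reason <- "rate"
  list(qc_pass = reason == "", qc_reason = reason,
       contamination = contamination, rate_hz = rate)
}

#' Gate direction-selective cells from a DSI distribution
#'
#' The DSI histogram of a recorded RGC population is bimodal: non-DS cells
#' form a low mode and DSGCs a high mode. A two-component Gaussian mixture is
#' fit to the DSI values and the threshold is set at the density crossing
#' between the components; cells above threshold are labeled DS. When the
#' fit is not convincingly bimodal (component means closer than the pooled
#' SD), or with fewer than 20 cells, a fixed fallback threshold is used.
#'
#' @param dsi_values numeric DSI values in \[0, 1\].
#' @param fallback_threshold fixed threshold used on the fallback path
#'   (default 0.25).
#' @param seed seed for the mixture fit's initialization.
#' @return List of class `dsi_mixture`: `threshold`, `is_ds` (logical per
#'   input), `used_fallback`, `weights`, `means`, `sds` (low component
#'   first; `NA` on the fallback path).
#' @export
gate_dsgc <- function(dsi_values, fallback_threshold = 0.25, seed = 1L) {
  dsi_values <- as.numeric(dsi_values)
  stopifnot(all(is.finite(dsi_values)))
  fallback <- function(why) {
    structure(list(threshold = fallback_threshold,
                   is_ds = dsi_values > fallback_threshold,
                   used_fallback = TRUE, fallback_reason = why,
                   weights = NA_real_, means = NA_real_, sds = NA_real_),
              class = "dsi_mixture")
  }
  if (length(dsi_values) < 20) {
    warning("fewer than 20 cells: using fixed DSI threshold ",
            fallback_threshold)
    return(fallback("too_few_cells"))
  }
  if (sd(dsi_values) < 1e-10) return(fallback("degenerate"))
  # Mclust resolves mclustBIC in the calling frame; bind it locally
  mclustBIC <- mclust::mclustBIC
  fit <- with_seed(seed, tryCatch(
    mclust::Mclust(dsi_values, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL))
  if (is.null(fit)) return(fallback("fit_failed"))
  mns <- as.numeric(fit$parameters$mean)
  sds <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sds) == 1) sds <- rep(sds, 2)
  wts <- as.numeric(fit$parameters$pro)
  o <- order(mns)
  mns <- mns[o]; sds <- sds[o]; wts <- wts[o]
  pooled_sd <- sqrt(sum(wts * sds^2))
  if (diff(mns) <= pooled_sd) return(fallback("not_bimodal"))
  f <- function(x) wts[1] * dnorm(x, mns[1], sds[1]) -
    wts[2] * dnorm(x, mns[2], sds[2])
  thr <- tryCatch({
    if (f(mns[1]) * f(mns[2]) < 0) uniroot(f, mns, tol = 1e-9)$root else NA
  }, error = function(e) NA)
  if (!is.finite(thr)) return(fallback("no_crossing"))
  structure(list(threshold = thr, is_ds = dsi_values > thr,
                 used_fallback = FALSE, fallback_reason = "",
                 weights = wts, means = mns, sds = sds),
            class = "dsi_mixture")
}

#' @export
print.dsi_mixture <- function(x, ...) {
  cat("dsi_mixture: threshold", signif(x$threshold, 4),
      if (x$used_fallback) paste0("(fallback: ", x$fallback_reason, ")")
      else "(mixture crossing)",
      "-", sum(x$is_ds), "of", length(x$is_ds), "cells DS\n")
  invisible(x)
}

#' Isolate ON-OFF DSGCs from gated DS cells
#'
#' A DS cell is an ooDSGC when its response to a bar entering and exiting
#' the receptive field has two separable temporal lobes (ON and OFF) whose
#' smaller peak is at least `ratio_min` of the larger; ON-only DS cells fail
#' this test.
#'
#' @param rs a `spike_response_set`.
#' @param ds_cells cell ids previously labeled DS.
#' @param ratio_min minimum smaller/larger peak-rate ratio.
#' @param ... passed to [split_on_off()].
#' @return Data frame: `cell_id`, `is_oods`, `peak_ratio`, `boundary_time`.
#' @export
isolate_oods <- function(rs, ds_cells, ratio_min = 0.2, ...) {
  rows <- lapply(ds_cells, function(cl) {
    so <- split_on_off(rs, cl, ...)
    data.frame(cell_id = cl,
               is_oods = isTRUE(so$bilobed) &&
                 is.finite(so$peak_ratio) && so$peak_ratio >= ratio_min,
               peak_ratio = so$peak_ratio,
               boundary_time = so$boundary_time)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster preferred directions into the four cardinal subtypes
#'
#' K-means on the circle, following the cardinal organization of ooDSGC
#' preferred directions: clusters are seeded at the four cardinal directions;
#' each cell is assigned to the cluster whose center has the minimal angular
#' difference to its preferred direction; centers are updated to the
#' circular mean of their members; iterate to convergence. An empty cluster
#' retains its current center.
#'
#' @param pref_dirs preferred directions in degrees.
#' @param seeds initial cluster centers, degrees (default the cardinals).
#' @param max_iter iteration cap.
#' @return List with `cluster` (integer per cell), `centers_deg` and
#'   `iterations`.
#' @export
assign_subtypes <- function(pref_dirs, seeds = c(0, 90, 180, 270),
                            max_iter = 100) {
  pref_dirs <- as.numeric(pref_dirs) %% 360
  stopifnot(length(pref_dirs) >= 1, length(seeds) >= 2)
  centers <- seeds %% 360
  assign_once <- function(centers) {
    d <- outer(pref_dirs, centers, ang_diff)
    max.col(-d, ties.method = "first")
  }
  cl <- assign_once(centers)
  iter <- 0
  repeat {
    iter <- iter + 1
    new_centers <- vapply(seq_along(centers), function(k) {
      if (any(cl == k)) circ_mean_deg(pref_dirs[cl == k]) else centers[k]
    }, numeric(1))
    new_cl <- assign_once(new_centers)
    if (identical(new_cl, cl) &&
        max(ang_diff(new_centers, centers)) < 1e-9) {
      centers <- new_centers
      break
    }
    centers <- new_centers
    cl <- new_cl
    if (iter >= max_iter) break
  }
  list(cluster = cl, centers_deg = centers, iterations = iter)
}

#' Compare two population metric distributions
#'
#' Two-sample Kolmogorov-Smirnov test on per-cell metric vectors (tuning
#' width, strength, ON-OFF preferred-direction difference, ...), as used to
#' compare genotype populations' cumulative distributions.
#'
#' @param metric_a,metric_b numeric vectors; NAs dropped.
#' @return List with `ks_statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_populations <- function(metric_a, metric_b) {
  a <- metric_a[is.finite(metric_a)]
  b <- metric_b[is.finite(metric_b)]
  stopifnot(length(a) > 0, length(b) > 0)
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(ks_statistic = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(a), n_b = length(b))
}
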