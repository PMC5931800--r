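# Shared fixture builders. Everything is generated in code at test time.

# Spike-response set built directly from per-direction spike-time lists:
# `times` is a named list direction -> list of per-trial numeric vectors.
manual_rs <- function(times, n_trials = 8, contrast = 300,
                      trial_duration = 2.5, cell = "cellA") {
  pr <- stimulus_protocol(contrasts = contrast, n_trials = n_trials,
                          trial_duration_s = trial_duration)
  rows <- list()
  for (d in names(times)) {
    for (tr in seq_along(times[[d]])) {
      tt <- times[[d]][[tr]]
      if (length(tt))
        rows[[length(rows) + 1]] <- data.frame(
          cell_id = cell, direction_deg = as.numeric(d),
          contrast_pct = contrast, trial = tr, spike_time_s = tt)
    }
  }
  spikes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), direction_deg = numeric(0),
               contrast_pct = numeric(0), trial = integer(0),
               spike_time_s = numeric(0))
  spike_response_set(spikes, pr, cells = cell)
}

# Population of randomly oriented DS cells sharing gain/null_rate, one
# contrast, for power and recovery experiments.
make_ds_population <- function(n_cells, null_rate, seed, gain = 30,
                               kappa_set = c(1, 2, 4), n_trials = 8,
                               delta_phi_sd = 0) {
  pr <- stimulus_protocol(contrasts = 300, n_trials = n_trials)
  cells <- withr::with_seed(seed, lapply(seq_len(n_cells), function(i) {
    mu <- runif(1, 0, 360)
    cell_params(sprintf("c%03d", i), mu_on = mu,
                mu_off = (mu + rnorm(1, 0, max(delta_phi_sd, 1e-9))) %% 360,
                kappa_on = sample(kappa_set, 1),
                kappa_off = sample(kappa_set, 1),
                gain = gain, null_rate = null_rate)
  }))
  truth <- synthetic_truth(cells, pr, seed = seed + 1)
  generate_population(truth)
}

# Independent brute-force evaluation of the two-term cosine-weighted tuning
# strength, written from the formula (not via circular_stats()).
strength_oracle <- function(counts, dirs = seq(0, 330, by = 30)) {
  vx <- sum(counts * cos(dirs * pi / 180))
  vy <- sum(counts * sin(dirs * pi / 180))
  pd <- (atan2(vy, vx) * 180 / pi) %% 360
  circ_d <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  two_sum <- function(axis) {
    d <- circ_d(dirs, axis)
    k <- order(d)[1:2]
    sum(counts[k] * cos(d[k] * pi / 180))
  }
  p <- two_sum(pd)
  n <- two_sum((pd + 180) %% 360)
  (p - n) / (p + n)
}
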