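dirs12 <- seq(0, 330, by = 30)

test_that("tuning curves count spikes per direction across trials", {
  times <- setNames(vector("list", 12), as.character(dirs12))
  for (d in names(times)) times[[d]] <- replicate(8, numeric(0),
                                                  simplify = FALSE)
  times[["90"]] <- replicate(8, c(0.5, 1.0), simplify = FALSE)
  rs <- manual_rs(times)
  tc <- compute_tuning_curve(rs, "cellA", 300)
  expect_equal(tc$counts[dirs12 == 90], 16)
  expect_equal(sum(tc$counts), 16)
  expect_error(compute_tuning_curve(rs, "nope", 300), "unknown cell")
  expect_error(compute_tuning_curve(rs, "cellA", 42), "unknown contrast")
})

test_that("synthetic counts match the generator's expectation within 3 SE", {
  pr <- stimulus_protocol(contrasts = 300, n_trials = 50)
  p <- cell_params("x", mu_on = 150, kappa_on = 2, gain = 20, gain_off = 0,
                   null_rate = 0.5)
  rs <- generate_population(synthetic_truth(list(p), pr, seed = 21))
  tc <- compute_tuning_curve(rs, "x", 300)
  lam <- expected_counts(p, pr, 300)$lambda_total * pr$n_trials
  expect_true(all(abs(tc$counts - lam) < 3.5 * sqrt(pmax(lam, 1))))
})

test_that("DSI follows the vector-sum definition", {
  one_dir <- tuning_curve(dirs12, c(0, 0, 0, 25, rep(0, 8)))
  expect_equal(compute_dsi(one_dir), 1)
  uniform <- tuning_curve(dirs12, rep(7, 12))
  expect_equal(compute_dsi(uniform), 0, tolerance = 1e-12)
  # hand vector arithmetic: counts (10, 5, 0, ...) at (0, 30, ...) degrees
  tc <- tuning_curve(dirs12, c(10, 5, rep(0, 10)))
  vx <- 10 * cos(0) + 5 * cos(30 * pi / 180)
  vy <- 10 * sin(0) + 5 * sin(30 * pi / 180)
  expect_equal(compute_dsi(tc), sqrt(vx^2 + vy^2) / 15)
  expect_equal(compute_dsi(tc), 0.969771, tolerance = 1e-6)
  expect_warning(val <- compute_dsi(tuning_curve(dirs12, rep(0, 12))),
                 "all-zero")
  expect_true(is.nan(val))
})

test_that("adding direction-independent counts strictly decreases DSI", {
  base <- tuning_curve(dirs12, c(30, 18, 6, 1, 0, 0, 0, 0, 0, 0, 1, 9))
  d0 <- compute_dsi(base)
  for (k in c(1, 5, 20)) {
    dk <- compute_dsi(tuning_curve(dirs12, base$counts + k))
    expect_lt(dk, d0)
  }
})

test_that("circular statistics match closed forms", {
  point <- tuning_curve(dirs12, c(0, 0, 12, rep(0, 9)))
  cs <- circular_stats(point)
  expect_equal(cs$r_bar, 1)
  expect_equal(cs$sigma_circ, 0)
  expect_equal(cs$mean_deg, 60)
  uniform <- circular_stats(tuning_curve(dirs12, rep(3, 12)))
  expect_equal(uniform$r_bar, 0, tolerance = 1e-12)
  expect_true(is.infinite(uniform$sigma_circ))
  # dense von Mises samples: R_bar -> I1(kappa)/I0(kappa)
  th <- seq(0, 359.9, by = 0.1)
  for (kappa in c(1, 2, 4)) {
    dens <- exp(kappa * cos((th - 77) * pi / 180))
    cs <- circular_stats(tuning_curve(th, dens))
    rb_true <- besselI(kappa, 1) / besselI(kappa, 0)
    expect_lt(abs(cs$r_bar - rb_true) / rb_true, 0.01)
    expect_lt(abs(cs$sigma_circ - sqrt(-2 * log(rb_true))), 0.01)
    expect_equal(cs$mean_deg, 77, tolerance = 0.1)
  }
})

test_that("kappa_from_rbar inverts the Bessel ratio", {
  a1 <- function(k) besselI(k, 1) / besselI(k, 0)
  for (k in c(0.3, 1, 2, 5, 12)) {
    expect_equal(kappa_from_rbar(a1(k)), k, tolerance = 1e-6)
  }
  expect_equal(kappa_from_rbar(0), 0)
})

test_that("von Mises fits recover noiseless parameters", {
  kappa <- 3; mu <- 120
  counts <- 500 * exp(kappa * cos((dirs12 - mu) * pi / 180)) /
    (2 * pi * besselI(kappa, 0))
  fit <- fit_von_mises(tuning_curve(dirs12, counts))
  expect_true(fit$converged)
  expect_lt(ang_diff(fit$mu_deg, mu), 1)
  expect_lt(abs(fit$kappa - kappa) / kappa, 0.05)
  expect_equal(fit$amplitude, 500, tolerance = 0.05)
  # uniform counts collapse to kappa ~ 0
  flat <- fit_von_mises(tuning_curve(dirs12, rep(10, 12)))
  expect_lt(flat$kappa, 0.05)
  # a single nonzero direction violates the stability precondition
  expect_error(fit_von_mises(tuning_curve(dirs12, c(9, rep(0, 11)))),
               "nonzero directions")
})

test_that("tuning strength matches the two-term cosine formula", {
  # all spikes at a sampled direction: strength 1
  tc <- tuning_curve(dirs12, c(0, 0, 0, 40, rep(0, 8)))
  expect_equal(tuning_strength(tc)$strength, 1)
  # symmetric curve r(theta) = r(theta + 180): strength 0
  sym <- tuning_curve(dirs12, c(5, 1, 0, 0, 0, 0, 5, 1, 0, 0, 0, 0))
  expect_equal(tuning_strength(sym)$strength, 0, tolerance = 1e-12)
  # printed-grid toy curve against the brute-force oracle
  toy <- c(20, 12, 2, rep(0, 8), 12)
  st <- tuning_strength(tuning_curve(dirs12, toy))
  expect_equal(st$strength, strength_oracle(toy))
  expect_equal(st$strength, 1)  # null-side counts are zero here
  # curves with nonzero null response, against the same oracle
  for (s in 1:10) {
    counts <- withr::with_seed(s, rpois(12, 3) +
                                 round(20 * exp(2 * (cos((dirs12 - 40) *
                                                           pi / 180) - 1))))
    expect_equal(tuning_strength(tuning_curve(dirs12, counts))$strength,
                 strength_oracle(counts))
  }
  expect_warning(st0 <- tuning_strength(tuning_curve(dirs12, rep(0, 12))),
                 "all-zero")
  expect_true(is.nan(st0$strength))
})

test_that("median width falls and strength rises with concentration", {
  meds <- lapply(c(1, 2, 4), function(kappa) {
    rs <- make_ds_population(30, null_rate = 0.5, seed = 100 + kappa,
                             kappa_set = kappa)
    m <- cell_metrics(rs, split = FALSE)
    c(width = median(m$width_deg), strength = median(m$strength))
  })
  widths <- vapply(meds, `[[`, numeric(1), "width")
  strengths <- vapply(meds, `[[`, numeric(1), "strength")
  expect_true(all(diff(widths) < 0))
  expect_true(all(diff(strengths) > 0))
})
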