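test_that("mosaic generators respect their geometric constraints", {
  # unjittered lattice: all nearest-neighbor distances equal the constant
  lat <- generate_mosaic("lattice_jitter", density = 600, jitter_sd = 0,
                         seed = 1)
  a <- sqrt(2 / (sqrt(3) * 600e-6))
  d <- as.matrix(dist(cbind(lat$x, lat$y)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_true(all(abs(nn - a) < 1e-6))
  # hard core: minimum pairwise distance >= d_min
  hc <- generate_mosaic("hardcore", density = 600, d_min = 8, seed = 2)
  dh <- dist(cbind(hc$x, hc$y))
  expect_gte(min(dh), 8)
  # impossible packing raises a stated error
  expect_error(generate_mosaic("hardcore", density = 20000, d_min = 12,
                               bounds = c(0, 0, 200, 200), seed = 3,
                               max_tries_per_point = 20),
               "too dense")
  # reproducibility
  expect_identical(generate_mosaic("poisson", density = 500, seed = 9),
                   generate_mosaic("poisson", density = 500, seed = 9))
})

test_that("Voronoi domains partition the field and exclude edge cells", {
  m <- generate_mosaic("hardcore", density = 800, d_min = 8, seed = 4)
  v <- voronoi_domains(m)
  field <- (m$bounds[3] - m$bounds[1]) * (m$bounds[4] - m$bounds[2])
  # clipped domains tile the rectangle exactly
  expect_equal(sum(v$areas_all_um2), field, tolerance = 1e-9)
  # the excluded set is exactly the domains touching the bounds
  touches <- vapply(v$polygons, function(p) {
    nrow(p) < 3 || any(p[, 1] <= m$bounds[1] + 1e-7 |
                         p[, 1] >= m$bounds[3] - 1e-7 |
                         p[, 2] <= m$bounds[2] + 1e-7 |
                         p[, 2] >= m$bounds[4] - 1e-7)
  }, logical(1))
  expect_identical(v$is_edge, touches)
  expect_equal(v$n_interior + sum(v$is_edge), length(m$x))
})

test_that("Voronoi areas agree with a nearest-neighbor grid oracle", {
  m <- generate_mosaic("hardcore", density = 600, d_min = 8,
                       bounds = c(0, 0, 400, 400), seed = 5)
  v <- voronoi_domains(m)
  # independent route: assign a fine pixel grid to the nearest cell
  h <- 0.5
  gx <- seq(h / 2, 400 - h / 2, by = h)
  pix <- expand.grid(x = gx, y = gx)
  idx <- integer(nrow(pix))
  best <- rep(Inf, nrow(pix))
  for (i in seq_along(m$x)) {
    d2 <- (pix$x - m$x[i])^2 + (pix$y - m$y[i])^2
    better <- d2 < best
    idx[better] <- i
    best[better] <- d2[better]
  }
  grid_area <- tabulate(idx, nbins = length(m$x)) * h^2
  interior <- which(!v$is_edge)
  expect_true(all(abs(grid_area[interior] -
                        v$areas_all_um2[interior]) /
                    v$areas_all_um2[interior] < 0.02))
})

test_that("lattice geometry gives the closed-form domain area and a capped VDRI", {
  # 5x5 square lattice with spacing 20: center cells own 20x20 domains
  xy <- expand.grid(x = seq(10, 90, by = 20), y = seq(10, 90, by = 20))
  m <- mosaic_pattern(xy$x, xy$y, c(0, 0, 100, 100))
  v <- voronoi_domains(m)
  expect_true(all(abs(v$areas_um2 - 400) < 1e-9))
  expect_true(v$degenerate)
  expect_equal(v$vdri, 1e6)
})

test_that("VDRI is invariant to coordinate scaling; areas scale as s^2", {
  m <- generate_mosaic("hardcore", density = 700, d_min = 8, seed = 6)
  v1 <- voronoi_domains(m)
  s <- 3.7
  m2 <- mosaic_pattern(m$x * s, m$y * s, m$bounds * s)
  v2 <- voronoi_domains(m2)
  expect_equal(v2$vdri, v1$vdri, tolerance = 1e-9)
  expect_equal(v2$areas_um2, v1$areas_um2 * s^2, tolerance = 1e-9)
})

test_that("regularity orders lattice > hardcore > poisson across seeds", {
  v <- vapply(1:12, function(s) c(
    lattice = voronoi_domains(generate_mosaic("lattice_jitter",
                                              density = 600, jitter_sd = 2,
                                              seed = 900 + s))$vdri,
    hardcore = voronoi_domains(generate_mosaic("hardcore", density = 600,
                                               d_min = 8,
                                               seed = 900 + s))$vdri,
    poisson = voronoi_domains(generate_mosaic("poisson", density = 600,
                                              seed = 900 + s))$vdri),
    numeric(3))
  # jittered lattice dominates both random processes in every seed
  expect_true(all(v["lattice", ] > v["hardcore", ]))
  expect_true(all(v["lattice", ] > v["poisson", ]))
  # hard core exceeds Poisson in distribution (the per-seed gap is small)
  expect_gt(mean(v["hardcore", ]), mean(v["poisson", ]))
  expect_gte(mean(v["hardcore", ] > v["poisson", ]), 0.5)
})

test_that("the Poisson null VDRI is density-invariant", {
  means <- vapply(c(500, 1000, 2000), function(dens) {
    random_null(dens, bounds = c(0, 0, 500, 500), d_min = 0, n_sims = 20,
                seed = 7)$mean
  }, numeric(1))
  expect_lt(sd(means) / mean(means), 0.05)
  # single simulation with a fixed seed is reproducible
  a <- random_null(600, d_min = 8, n_sims = 1, seed = 8)
  b <- random_null(600, d_min = 8, n_sims = 1, seed = 8)
  expect_identical(a$vdri, b$vdri)
})

test_that("per-animal summaries average fields", {
  m <- generate_mosaic("hardcore", density = 600, seed = 10)
  v <- voronoi_domains(m)
  expect_equal(per_animal_summary(list(v, v, v))$mean_vdri, v$vdri)
  v2 <- voronoi_domains(generate_mosaic("hardcore", density = 600,
                                        seed = 11))
  s <- per_animal_summary(list(v, v2))
  expect_equal(s$mean_vdri, (v$vdri + v2$vdri) / 2)
  expect_equal(s$n_fields, 2)
})

test_that("territory bins report outcome rates with open-ended extremes", {
  m <- generate_mosaic("poisson", density = 900, seed = 12)
  v <- voronoi_domains(m)
  # constant outcome: every nonempty bin at rate 1
  all_true <- territory_bin_analysis(v, rep(TRUE, v$n_interior))
  expect_true(all(all_true$rate == 1))
  expect_equal(sum(all_true$n), v$n_interior)
  expect_equal(all_true$label[1], "<200")
  # step outcome by construction
  step <- territory_bin_analysis(v, v$areas_um2 > 600)
  expect_true(all(step$rate[step$bin_hi <= 600] == 0))
  expect_true(all(step$rate[step$bin_lo >= 600] == 1))
  # area-independent outcome: weighted regression slope CI contains 0
  out <- withr::with_seed(13, runif(v$n_interior) < 0.3)
  tab <- territory_bin_analysis(v, out)
  mid <- ifelse(is.finite(tab$bin_lo) & is.finite(tab$bin_hi),
                (tab$bin_lo + tab$bin_hi) / 2,
                ifelse(is.finite(tab$bin_hi), tab$bin_hi - 50,
                       tab$bin_lo + 50))
  fit <- lm(rate ~ mid, data = data.frame(rate = tab$rate, mid = mid),
            weights = tab$n)
  ci <- confint(fit)["mid", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("mosaic point tables round-trip", {
  m <- generate_mosaic("hardcore", density = 500, seed = 14)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mosaic(m, path)
  back <- read_mosaic(path)
  expect_equal(back$x, m$x)
  expect_equal(back$bounds, m$bounds)
})
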