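test_that("dendrite angles partition into IPL/tangential/ONBL", {
  expect_equal(as.character(classify_dendrite_angle(0)), "IPL")
  expect_equal(as.character(classify_dendrite_angle(90)), "TANGENTIAL")
  expect_equal(as.character(classify_dendrite_angle(180)), "ONBL")
  expect_error(classify_dendrite_angle(-5), "0, 180")
  # no gaps or overlaps at any cut setting
  grid <- seq(0, 180, by = 0.25)
  for (cuts in list(c(45, 135), c(30, 150), c(60, 120))) {
    cls <- classify_dendrite_angle(grid, cuts[1], cuts[2])
    expect_false(any(is.na(cls)))
    expect_equal(sum(table(cls)), length(grid))
  }
})

test_that("orientation summaries give fractions and histograms", {
  s <- orientation_summary(rep(10, 5))
  expect_equal(unname(s$fractions["IPL"]), 1)
  s3 <- orientation_summary(c(10, 90, 170))
  expect_equal(unname(s3$fractions), rep(1 / 3, 3))
  expect_equal(sum(s3$histogram$count), 3)
  # uniform angles: fractions approach the quadrant measure (0.25/0.5/0.25)
  u <- withr::with_seed(81, runif(1000, 0, 180))
  su <- orientation_summary(u)
  se <- sqrt(0.25 * 0.75 / 1000)
  expect_lt(abs(su$fractions[["IPL"]] - 0.25), 4 * se)
  expect_lt(abs(su$fractions[["TANGENTIAL"]] - 0.5), 4 * se)
  expect_lt(abs(su$fractions[["ONBL"]] - 0.25), 4 * se)
})

test_that("IPL profiles are width-averaged, background-subtracted, normalized", {
  img <- matrix(5, nrow = 50, ncol = 20)
  img[31, ] <- 25
  p <- ipl_profile(img)
  expect_equal(max(p$intensity), 1)
  expect_equal(min(p$intensity), 0)
  expect_equal(sum(p$intensity == 1), 1)
  expect_equal(p$depth_pct[p$intensity == 1],
               (31 - 1) / 49 * 100)
  # affine intensity rescaling leaves the profile unchanged
  p2 <- ipl_profile(img * 7.3 + 11)
  expect_equal(p2$intensity, p$intensity)
  expect_error(ipl_profile(matrix(3, 10, 4)), "flat")
})

test_that("peak calls use the plateau-center rule", {
  d <- seq(0, 100, by = 1)
  y <- rep(0.1, 101)
  y[d >= 40 & d <= 50] <- 1
  p <- intensity_profile(d, y)
  expect_equal(find_peaks(p), 45)
  # single maximum
  y2 <- exp(-(d - 62)^2 / 50)
  expect_equal(find_peaks(intensity_profile(d, y2)), 62)
  # two-band synthetic fixture recovered within grid resolution
  fix <- generate_ipl_profile(list(c(31, 3, 1), c(62, 3, 0.8)),
                              n_samples = 201)
  pk <- find_peaks(fix)
  expect_equal(length(pk), 2)
  expect_lt(abs(pk[1] - 31), 0.5)
  expect_lt(abs(pk[2] - 62), 0.5)
})

test_that("band distances subtract dominant peak depths", {
  a <- generate_ipl_profile(list(c(56, 2.5, 1)))
  b <- generate_ipl_profile(list(c(69, 2.5, 1)))
  expect_equal(band_distance(a, b), 13, tolerance = 0.5)
  expect_equal(band_distance(a, a), 0)
  noisy_a <- generate_ipl_profile(list(c(56, 2.5, 1)), noise_sd = 0.03,
                                  seed = 82)
  noisy_b <- generate_ipl_profile(list(c(69, 2.5, 1)), noise_sd = 0.03,
                                  seed = 83)
  expect_equal(band_distance(noisy_a, noisy_b), 13, tolerance = 1.5)
  expect_error(band_distance(a, intensity_profile(0:10, c(10:0))),
               "no peak")
})

test_that("territory areas follow polygon closed forms and invariances", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(arbor_territory_area(sq), 1)
  r <- 12
  hexa <- cbind(r * cos(2 * pi * (0:5) / 6), r * sin(2 * pi * (0:5) / 6))
  expect_equal(arbor_territory_area(hexa), 3 * sqrt(3) / 2 * r^2)
  # star-shaped random tip set against an inline shoelace oracle
  tips <- withr::with_seed(84, {
    ang <- sort(runif(40, 0, 2 * pi))
    rad <- runif(40, 5, 30)
    cbind(100 + rad * cos(ang), -50 + rad * sin(ang))
  })
  # inline shoelace oracle on the same centroid-angular ordering
  ctr <- c(mean(tips[, 1]), mean(tips[, 2]))
  o <- order(atan2(tips[, 2] - ctr[2], tips[, 1] - ctr[1]))
  x <- tips[o, 1]; y <- tips[o, 2]
  oracle <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  expect_equal(arbor_territory_area(tips), oracle, tolerance = 1e-9)
  # translation/rotation invariance, s^2 scaling
  th <- 0.7
  rot <- tips %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  expect_equal(arbor_territory_area(rot + 500), oracle, tolerance = 1e-9)
  expect_equal(arbor_territory_area(tips * 2.5), oracle * 2.5^2,
               tolerance = 1e-9)
  expect_error(arbor_territory_area(rbind(c(0, 0), c(1, 1))), "3 tips")
  expect_error(arbor_territory_area(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "collinear")
})

test_that("plexus coverage thresholds and counts foreground", {
  half <- cbind(matrix(0, 50, 25), matrix(1, 50, 25))
  expect_equal(plexus_coverage(half), 50)
  img <- generate_plexus_image(0.70, seed = 85)
  expect_equal(plexus_coverage(img), 70, tolerance = 2)
  # punching holes of known area reduces coverage by that amount
  full <- matrix(1, 100, 100)
  full[1, 1] <- 0  # non-constant so thresholding is defined
  full[11:20, 11:30] <- 0  # 200 px hole
  expect_equal(plexus_coverage(full, threshold = 0.5),
               100 * (1e4 - 201) / 1e4)
  expect_error(plexus_coverage(matrix(1, 5, 5)), "constant")
})

test_that("contact rates count tip hits with a flipped-channel control", {
  dims <- c(20, 20, 6)
  all_mask <- array(TRUE, dims)
  tips <- cbind(sample(20), sample(20), rep(3, 20))
  cv <- contact_volume(tips, all_mask)
  expect_equal(contact_rate(cv)$rate_pct, 100)
  expect_equal(flipped_control(cv)$rate_pct, 100)
  # fixture with exact placement: 111/125 = 88.8%
  fx <- generate_contact_volume(125, 0.888, seed = 86)
  cr <- contact_rate(fx)
  expect_equal(cr$n_contact, 111)
  expect_equal(cr$rate_pct, 88.8)
  # flip-symmetric mask: control equals observed
  sym <- array(FALSE, dims)
  sym[8:13, 8:13, ] <- TRUE  # centered, invariant to the double flip
  tips2 <- withr::with_seed(87, cbind(sample(20, 30, TRUE),
                                      sample(20, 30, TRUE),
                                      sample(6, 30, TRUE)))
  cv2 <- contact_volume(tips2, sym)
  expect_equal(flipped_control(cv2)$rate_pct, contact_rate(cv2)$rate_pct)
  # 1-voxel dilation can only add hits
  expect_gte(contact_rate(cv2, dilate = 1)$n_contact,
             contact_rate(cv2)$n_contact)
})

test_that("stratification calls combine peak position and band fraction", {
  tight <- generate_ipl_profile(list(c(31, 3, 1)))
  call_ok <- stratification_call(tight, band_center_pct = 31)
  expect_true(call_ok$stratified)
  expect_lt(abs(call_ok$peak_pct - 31), 1)
  # same peak, wrong reference band
  expect_false(stratification_call(tight, band_center_pct = 62)$stratified)
  # diffuse profile: peak in band but most signal outside
  diffuse <- generate_ipl_profile(list(c(31, 2, 1), c(70, 25, 0.9)))
  expect_lt(stratification_call(diffuse, 31)$band_fraction, 0.6)
  expect_false(stratification_call(diffuse, 31)$stratified)
})

test_that("projection tables give per-group fractions with binomial SEs", {
  rec <- data.frame(
    genotype = rep(c("wt", "mut"), c(10, 8)),
    innervates_ipl = c(rep(TRUE, 10), rep(TRUE, 5), rep(FALSE, 3)),
    stratified = c(rep(TRUE, 9), FALSE, rep(TRUE, 3), rep(FALSE, 5)))
  tab <- projection_frequency_table(rec, "genotype")
  wt <- tab[tab$genotype == "wt", ]
  expect_equal(wt$stratified_frac, 0.9)
  expect_equal(wt$stratified_se, sqrt(0.9 * 0.1 / 10))
  expect_equal(tab$n[order(tab$genotype)], c(8, 10))  # mut, wt
  zero <- projection_frequency_table(
    data.frame(g = "a", soma_layer = rep(FALSE, 7)), "g")
  expect_equal(zero$soma_layer_frac, 0)
  # stratified cells must innervate the IPL
  bad <- data.frame(g = "a", innervates_ipl = FALSE, stratified = TRUE)
  expect_error(projection_frequency_table(bad, "g"), "innervate")
})
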