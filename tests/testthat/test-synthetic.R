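test_that("generator hits geometry targets (closed loop with cell_shape)", {
  for (ecc in c(0, 0.4, 0.8)) {
    cell <- synthetic_cell(perimeter = 320, eccentricity = ecc)
    expect_lt(abs(cell$truth$eccentricity - ecc), 0.02)
  }
  for (a in c(2000, 12000)) {
    cell <- synthetic_cell(area = a)
    lat <- first_lattice(cell)
    expect_lt(abs(unname(lat$area[1]) - a) / a, 0.05)
  }
  for (mu in c(0.55, 0.7, 0.85)) {
    cell <- synthetic_cell(perimeter = 320, regularity = mu)
    expect_lt(abs(cell$truth$regularity - mu), 0.02)
  }
})

test_that("generator geometry is deterministic given the seed", {
  c1 <- synthetic_cell(perimeter = 300, regularity = 0.6, seed = 5)
  c2 <- synthetic_cell(perimeter = 300, regularity = 0.6, seed = 5)
  expect_identical(c1$intensity, c2$intensity)
  expect_identical(c1$skeleton, c2$skeleton)
  c3 <- synthetic_cell(perimeter = 300, regularity = 0.6, seed = 6)
  expect_false(identical(c1$intensity, c3$intensity))
})

test_that("two-level painting covers the intended regions", {
  # +-30 deg sector on this hexagon orientation = exactly the vertical edges
  cs <- synthetic_cell(perimeter = 300, placement = "sector", sector_half_deg = 30)
  cv <- synthetic_cell(perimeter = 300, placement = "vertical_junctions")
  expect_equal(cs$truth$peak_fraction, cv$truth$peak_fraction, tolerance = 0.02)
  expect_equal(cv$truth$peak_fraction, 1 / 3, tolerance = 0.01)
  # +-60 deg sector additionally covers half of each oblique edge
  c60 <- synthetic_cell(perimeter = 300, placement = "sector", sector_half_deg = 60)
  expect_equal(c60$truth$peak_fraction, 2 / 3, tolerance = 0.01)
  # coverage endpoints
  c0 <- synthetic_cell(perimeter = 300, placement = "coverage", coverage = 0)
  expect_true(all(c0$intensity[c0$intensity > 0] == 40))
  cfull <- synthetic_cell(perimeter = 300, placement = "coverage", coverage = 300)
  expect_true(all(cfull$intensity[cfull$intensity > 0] == 255))
  expect_error(synthetic_cell(perimeter = 300, placement = "coverage",
                              coverage = 400), "coverage")
  # coverage arc budget is respected
  cu <- synthetic_cell(perimeter = 300, placement = "coverage", coverage = 100)
  expect_equal(cu$truth$peak_fraction, 100 / 300, tolerance = 0.02)
})

test_that("puncta intensities follow the Gaussian bump model", {
  cell <- synthetic_cell(perimeter = 440, model = "puncta",
                         placement = "vertical_junctions")
  img <- cell$intensity[cell$intensity > 0]
  expect_equal(max(img), 255, tolerance = 2)
  expect_equal(min(img), 40)
  # oracle: repaint the profile by brute force from the truth geometry
  P <- planarpolarity:::outline_samples(cell$truth$vertices, step = 0.2)
  cls <- planarpolarity:::edge_axis_class(P)
  centers <- planarpolarity:::deg2rad(7.5 + seq(0, 345, by = 15))
  centers <- atan2(sin(centers), cos(centers))
  sig <- 4.47 * P$per / 360
  ci <- vapply(centers, function(a)
    which.min(abs(atan2(sin(P$theta - a), cos(P$theta - a)))), 1L)
  keep <- (cls[P$edge] == "vertical")[ci]
  dmin <- rep(Inf, length(P$s))
  for (c0 in P$s[ci][keep]) {
    d <- abs(P$s - c0); dmin <- pmin(dmin, pmin(d, P$per - d))
  }
  oracle <- 40 + 215 * exp(-dmin^2 / (2 * sig^2))
  pa <- planarpolarity:::paint_intensity(P, "puncta", "vertical_junctions",
                                         255, 40, NULL, 60, 15, 4.47, "deg", 7.5)
  expect_equal(pa$I, unname(oracle), tolerance = 1e-9)
  # punctum centers at the expected angles: intensity near 255 at +-7.5 deg
  i_on <- which.min(abs(P$theta - planarpolarity:::deg2rad(7.5)))
  expect_gt(pa$I[i_on], 250)
  # far field at 90 deg is base
  i_off <- which.min(abs(P$theta - pi / 2))
  expect_equal(pa$I[i_off], 40, tolerance = 0.5)
})

test_that("add_noise is seeded, scaled, and clipped", {
  cell <- std_cell()
  n1 <- add_noise(cell, snr = 5, seed = 3)
  n2 <- add_noise(cell, snr = 5, seed = 3)
  expect_identical(n1$intensity, n2$intensity)
  n3 <- add_noise(cell, snr = 5, seed = 4)
  expect_false(identical(n1$intensity, n3$intensity))
  expect_identical(add_noise(cell, snr = Inf)$intensity, cell$intensity)
  expect_error(add_noise(cell, snr = -1), "positive")
  expect_true(all(n1$intensity >= 0 & n1$intensity <= 255))
  # empirical sd of the added noise matches the requested sd within 2%
  big <- synthetic_cell(perimeter = 200, margin = 120)
  nb <- add_noise(big, snr = 10, seed = 1)
  sd_target <- mean(big$intensity[big$skeleton == 1]) / 10
  # background pixels carry max(N, 0) after clipping, so E[value^2] = sd^2/2
  noise <- nb$intensity[big$intensity == 0]
  sd_emp <- sqrt(2 * mean(noise^2))
  expect_equal(sd_emp, sd_target, tolerance = 0.02)
})

test_that("ground-truth axis is 0 and read out by all methods on clean fixtures", {
  cell <- std_cell(placement = "vertical_junctions")
  pol <- quantify_polarity(cell$intensity, cell$skeleton)
  expect_true(all(abs(pol$angle_deg) <= 2))
})

test_that("synthetic_sweep produces a manifest bound to the fixtures", {
  sw <- synthetic_sweep("coverage", c(40, 80), perimeter = 200,
                        placement = "coverage")
  expect_length(sw$cells, 2L)
  expect_equal(sw$manifest$value, c(40, 80))
  expect_equal(sw$cells[[2]]$truth$params$coverage, 80)
  swn <- synthetic_sweep("snr", c(20, 5), perimeter = 200,
                         placement = "vertical_junctions")
  expect_length(swn$cells, 2L)
  expect_identical(swn$cells[[1]]$skeleton, swn$cells[[2]]$skeleton)
  expect_false(identical(swn$cells[[1]]$intensity, swn$cells[[2]]$intensity))
})
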