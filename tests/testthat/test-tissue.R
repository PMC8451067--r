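test_that("average magnitude is the arithmetic mean", {
  expect_equal(average_magnitude(mk_readout(0.3, 10)), 0.3)
  expect_equal(average_magnitude(mk_readout(c(0.2, 0.4), c(0, 0))), 0.3)
  set.seed(3)
  p <- runif(40)
  expect_equal(average_magnitude(mk_readout(p, rep(5, 40))), mean(p))
  expect_error(average_magnitude(mk_readout(numeric(0), numeric(0))), "no readouts")
})

test_that("vector average collapses misaligned axes and preserves aligned ones", {
  r <- mk_readout(c(0.5, 0.5), c(20, 20))
  va <- vector_average(r)
  expect_equal(unname(va["p_vec"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(va["theta_vec"]), 20, tolerance = 1e-9)
  # orthogonal axes cancel (axial data)
  r2 <- mk_readout(c(0.5, 0.5), c(0, 90))
  expect_lt(unname(vector_average(r2)["p_vec"]), 1e-12)
})

test_that("p_vec <= p_average with equality iff all angles equal (randomized)", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(2:12, 1)
    p <- runif(n, 0.05, 1)
    ang <- runif(n, -90, 90)
    r <- mk_readout(p, ang)
    pv <- unname(vector_average(r)["p_vec"])
    pa <- average_magnitude(r)
    expect_lte(pv, pa + 1e-12)
  }
  # equality case
  r <- mk_readout(runif(5), rep(-33.3, 5))
  expect_equal(unname(vector_average(r)["p_vec"]), average_magnitude(r),
               tolerance = 1e-12)
})

test_that("angle variance spans [0, 1] with the documented endpoints", {
  expect_equal(angle_variance(mk_readout(rep(1, 4), rep(17, 4))), 0)
  expect_equal(angle_variance(mk_readout(rep(1, 4), c(0, 0, 90, 90))), 1)
  set.seed(5)
  av <- angle_variance(mk_readout(rep(1, 4000), runif(4000, -90, 90)))
  expect_gt(av, 0.95)
  # axial symmetry: shifting all angles by 180 changes nothing
  a <- c(-70, 15, 40)
  expect_equal(angle_variance(a), angle_variance(a + 180), tolerance = 1e-12)
})

test_that("mean angle difference wraps axially and is symmetric", {
  a <- mk_readout(rep(1, 3), c(10, 20, 30))
  expect_equal(mean_angle_difference(a, a), 0)
  b <- mk_readout(rep(1, 3), c(55, 65, 75))
  expect_equal(mean_angle_difference(a, b), 45)
  aa <- mk_readout(1, 85); bb <- mk_readout(1, -85)
  expect_equal(mean_angle_difference(aa, bb), 10)
  expect_equal(mean_angle_difference(bb, aa), 10)
  set.seed(8)
  x <- mk_readout(runif(20), runif(20, -90, 90))
  y <- mk_readout(runif(20), runif(20, -90, 90))
  d <- mean_angle_difference(x, y)
  expect_gte(d, 0); expect_lte(d, 90)
  bad <- mk_readout(runif(3), runif(3)); bad$cell_id <- 11:13
  expect_error(mean_angle_difference(x[1:3, ], bad), "cell id sets differ")
})

test_that("weighted circular histogram duplicates axes and matches the oracle", {
  r <- mk_readout(rep(0.8, 6), rep(27, 6))
  h <- weighted_circular_histogram(r, n_bins = 20)
  nz <- which(h$height > 0)
  expect_length(nz, 2L)
  expect_equal(h$bin_start[nz], c(18, 198))  # 27 and 207 in 18-deg bins
  # uniform angles, equal magnitude: flat histogram
  r2 <- mk_readout(rep(1, 360), seq(-89.75, 89.75, length.out = 360))
  h2 <- weighted_circular_histogram(r2, n_bins = 20)
  expect_equal(diff(range(h2$height)), 0, tolerance = 1e-9)
  # mixed set equals brute-force bin-and-weight
  set.seed(9)
  r3 <- mk_readout(runif(50), runif(50, -90, 90))
  h3 <- weighted_circular_histogram(r3, n_bins = 20)
  a <- c(r3$angle_deg %% 360, (r3$angle_deg + 180) %% 360)
  w <- rep(r3$magnitude_raw, 2)
  for (bi in 1:20) {
    sel <- a >= (bi - 1) * 18 & a < bi * 18
    expect_equal(h3$height[bi], sum(sel) * (if (any(sel)) mean(w[sel]) else 0),
                 tolerance = 1e-12)
  }
})

test_that("dataset normalization maps methods onto [0, 1] correctly", {
  df <- rbind(
    data.frame(cell_id = 1:2, method = "ratio", magnitude_raw = c(1, 3), angle_deg = 0),
    data.frame(cell_id = 1:2, method = "pca", magnitude_raw = c(2, 8), angle_deg = 0))
  out <- normalize_across_dataset(df)
  expect_equal(out$magnitude_norm[out$method == "ratio"], c(0, 1))
  expect_equal(out$magnitude_norm[out$method == "pca"], c(0.25, 1))
  z <- data.frame(cell_id = 1, method = "fourier", magnitude_raw = 0, angle_deg = NA)
  expect_warning(out2 <- normalize_across_dataset(z), "zero")
  expect_equal(out2$magnitude_norm, 0)
})

test_that("coarse graining recovers the limiting cases", {
  set.seed(21)
  n <- 24
  r <- mk_readout(runif(n, 0.2, 1), runif(n, -90, 90))
  cen <- data.frame(cell_id = 1:n, x = runif(n, 0, 100), y = runif(n, 0, 100))
  whole <- coarse_grain(r, cen, group_size = n)
  expect_equal(nrow(whole), 1L)
  va <- vector_average(r)
  expect_equal(whole$p_vec, unname(va["p_vec"]), tolerance = 1e-12)
  single <- coarse_grain(r, cen, group_size = 1)
  expect_equal(nrow(single), n)
  expect_equal(sort(single$p_vec), sort(r$magnitude_raw), tolerance = 1e-12)
  expect_warning(coarse_grain(r, cen, group_size = n + 5), "single group")
  # two spatial halves with orthogonal uniform polarity
  r2 <- mk_readout(rep(0.6, 20), rep(c(0, 90), each = 10))
  cen2 <- data.frame(cell_id = 1:20, x = rep(c(10, 90), each = 10),
                     y = rep(seq(5, 95, by = 10), 2))
  cg <- coarse_grain(r2, cen2, group_size = 10)
  expect_equal(nrow(cg), 2L)
  expect_equal(cg$p_vec, cg$p_average, tolerance = 1e-12)
  expect_lt(unname(vector_average(r2)["p_vec"]), 1e-12)
})

test_that("neighbor vector polarity uses the cell plus its neighbors", {
  lat <- label_cells(grid_skeleton(3, 3, cell = 6))
  ids <- lat$cells
  # uniformly polarized lattice: neighbor mean equals the average magnitude
  r <- mk_readout(rep(0.7, 9), rep(12, 9)); r$cell_id <- ids
  nv <- neighbor_vector(r, lat$adjacency)
  expect_equal(nv$tissue_mean, 0.7, tolerance = 1e-12)
  # checkerboard of orthogonal axes: brute-force 5-cell groups
  chk <- matrix(c(0, 90, 0, 90, 0, 90, 0, 90, 0), 3, 3, byrow = TRUE)
  r2 <- mk_readout(rep(1, 9), as.vector(t(chk))); r2$cell_id <- ids
  nv2 <- neighbor_vector(r2, lat$adjacency)
  for (i in seq_along(ids)) {
    grp <- c(ids[i], lat$adjacency[[as.character(ids[i])]])
    sel <- r2[r2$cell_id %in% grp, ]
    z <- mean(exp(2i * sel$angle_deg * pi / 180))
    expect_equal(nv2$cells$p_vec[i], Mod(z), tolerance = 1e-12)
  }
  # random angles: local alignment far below the average magnitude
  set.seed(31)
  r3 <- mk_readout(rep(1, 9), runif(9, -90, 90)); r3$cell_id <- ids
  expect_lt(neighbor_vector(r3, lat$adjacency)$tissue_mean, 0.9)
})

test_that("tissue_summary packages the statistics", {
  lat <- label_cells(grid_skeleton(3, 3, cell = 6))
  r <- mk_readout(runif(9, 0.1, 1), runif(9, -90, 90)); r$cell_id <- lat$cells
  ts <- tissue_summary(r, lat$adjacency)
  expect_equal(ts$n_cells, 9)
  expect_lte(ts$p_vec, ts$p_average)
  expect_gte(ts$angle_variance, 0); expect_lte(ts$angle_variance, 1)
  expect_false(is.na(ts$neighbor_p_vec))
})
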