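test_that("area and perimeter behave on squares and under scaling", {
  lat <- label_cells(grid_skeleton(3, 3, cell = 10))
  b <- trace_boundary(lat, lat$cells[!lat$border][1L])
  ap <- area_perimeter(b)
  expect_equal(unname(ap["area"]), 100)
  expect_gte(unname(ap["perimeter"]), 36)
  expect_lte(unname(ap["perimeter"]), 40)
  # similarity scaling of a hexagon fixture: area x4, perimeter x2
  c1 <- synthetic_cell(perimeter = 200)
  c2 <- synthetic_cell(perimeter = 400)
  b1 <- trace_boundary(first_lattice(c1), 1L)
  b2 <- trace_boundary(first_lattice(c2), 1L)
  expect_equal(b2$area / b1$area, 4, tolerance = 0.05)
  expect_equal(b2$perimeter / b1$perimeter, 2, tolerance = 0.03)
})

test_that("fit_ellipse recovers exact ellipse parameters", {
  p <- ellipse_points(10, 5, 30, x0 = 3, y0 = -2, n = 120)
  f <- fit_ellipse(p$x, p$y)
  expect_equal(f$a, 10, tolerance = 1e-6)
  expect_equal(f$b, 5, tolerance = 1e-6)
  expect_equal(f$theta, 30, tolerance = 1e-6)
  expect_equal(unname(f$center), c(3, -2), tolerance = 1e-6)
})

test_that("fit_ellipse handles circles, rotations, and degenerate input", {
  p <- ellipse_points(7, 7, 0)
  f <- fit_ellipse(p$x, p$y)
  expect_lt(ellipse_eccentricity(f), 1e-6)
  expect_equal(f$a, 7, tolerance = 1e-6)
  # 90-degree rotation shifts theta by 90 (mod 180), a and b unchanged
  p1 <- ellipse_points(10, 5, 20)
  p2 <- list(x = -p1$y, y = p1$x)
  f1 <- fit_ellipse(p1$x, p1$y)
  f2 <- fit_ellipse(p2$x, p2$y)
  expect_equal(f2$a, f1$a, tolerance = 1e-9)
  expect_equal(f2$b, f1$b, tolerance = 1e-9)
  expect_equal(axial_diff_deg(f2$theta, f1$theta + 90), 0, tolerance = 1e-6)
  expect_error(fit_ellipse(1:10, 2 * (1:10) + 1), "collinear")
  expect_error(fit_ellipse(1:4, c(2, 3, 1, 5)), "at least 6")
})

test_that("eccentricity follows the closed form", {
  f <- structure(list(a = 2, b = 1), class = "ellipse_fit")
  expect_equal(ellipse_eccentricity(f), sqrt(3) / 2)
  f$b <- 2
  expect_equal(ellipse_eccentricity(f), 0)
  f$b <- 1e-9
  expect_gt(ellipse_eccentricity(f), 0.999)
  f$b <- 3
  expect_error(ellipse_eccentricity(f), "semi-minor")
})

test_that("regularity is 1 for regular polygons and decreases with jitter", {
  hexv <- ellipse_points(10, 10, 0, n = 6)
  V <- cbind(hexv$x, hexv$y)
  expect_equal(polygon_regularity(V), 1, tolerance = 1e-12)
  mus <- sapply(c(0, 0.5, 1.2, 2.2), function(eta) {
    set.seed(7)
    polygon_regularity(V + matrix(runif(12, -eta, eta), 6, 2))
  })
  expect_true(all(diff(mus) < 0))
  # degenerate sliver stays clamped in [0, 1]
  sliver <- rbind(c(0, 0), c(10, 0.05), c(20, 0))
  expect_gte(polygon_regularity(sliver), 0)
  expect_lt(polygon_regularity(sliver), 0.3)
  expect_error(polygon_regularity(rbind(c(0, 0), c(1, 1))), "at least 3")
})

test_that("regularity and eccentricity are invariant under similarity transforms", {
  set.seed(11)
  V <- cbind(10 * cos(seq(0, 5) * pi / 3), 10 * sin(seq(0, 5) * pi / 3)) +
    matrix(runif(12, -1.5, 1.5), 6, 2)
  mu0 <- polygon_regularity(V)
  rot <- function(V, a) V %*% matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  expect_equal(polygon_regularity(V + 100), mu0, tolerance = 1e-12)
  expect_equal(polygon_regularity(3 * V), mu0, tolerance = 1e-12)
  expect_equal(polygon_regularity(rot(V, 0.7)), mu0, tolerance = 1e-12)
  dense <- ellipse_points(12, 7, 25, n = 300)
  e0 <- ellipse_eccentricity(fit_ellipse(dense$x, dense$y))
  e1 <- ellipse_eccentricity(fit_ellipse(3 * dense$x + 5, 3 * dense$y - 2))
  expect_equal(e0, e1, tolerance = 1e-9)
})

test_that("refitting points sampled from a fit reproduces the fit", {
  p <- ellipse_points(9, 4, -40)
  f1 <- fit_ellipse(p$x, p$y)
  p2 <- ellipse_points(f1$a, f1$b, f1$theta, f1$center[1], f1$center[2])
  f2 <- fit_ellipse(p2$x, p2$y)
  expect_equal(f2$a, f1$a, tolerance = 1e-9)
  expect_equal(f2$b, f1$b, tolerance = 1e-9)
  expect_equal(f2$theta, f1$theta, tolerance = 1e-7)
})

test_that("fit orientation agrees with the second-moment principal axis", {
  cell <- synthetic_cell(perimeter = 300, eccentricity = 0.6)
  b <- trace_boundary(first_lattice(cell), 1L)
  f <- fit_ellipse(b)
  x <- b$x - mean(b$x); y <- -(b$y - mean(b$y))
  cv <- cov(cbind(x, y))
  ax <- atan2(2 * cv[1, 2], cv[1, 1] - cv[2, 2]) / 2 * 180 / pi
  expect_lt(axial_diff_deg(f$theta, ax), 1)
})

test_that("count_junctions applies the 10% mean-edge rule", {
  hexv <- ellipse_points(10, 10, 0, n = 6)
  V <- cbind(hexv$x, hexv$y)
  b <- structure(list(edges = data.frame(
    chord = sqrt(rowSums((V[c(2:6, 1), ] - V)^2)))), class = "cell_boundary")
  expect_equal(count_junctions(b), 6L)
  # shorten one edge to 5% of the mean: no longer a side
  b$edges$chord[1] <- 0.05 * mean(b$edges$chord)
  expect_equal(count_junctions(b), 5L)
})

test_that("junction count equals neighbor count for interior lattice cells", {
  lat <- label_cells(grid_skeleton(3, 3, cell = 10))
  ctr <- lat$cells[!lat$border][1L]
  b <- trace_boundary(lat, ctr)
  expect_equal(count_junctions(b),
               length(lat$adjacency[[as.character(ctr)]]))
  expect_equal(count_junctions(b), 4L)
})

test_that("shape_metrics summarizes a generated hexagon correctly", {
  cell <- std_cell()
  sm <- shape_metrics(first_lattice(cell))
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$n_junctions, 6L)
  expect_gt(sm$regularity, 0.95)
  expect_lt(sm$eccentricity, 0.25)
  expect_equal(sm$area_px2, sum(first_lattice(cell)$labels == 1L))
})
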