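#' Cell area and perimeter
#'
#' Area is the pixel count of the labeled cell region; perimeter is the
#' length of the traced boundary loop (diagonal steps count sqrt(2)).
#'
#' @param boundary A `cell_boundary` from [trace_boundary()].
#' @return Named numeric vector `c(area =, perimeter =)`.
#' @export
area_perimeter <- function(boundary) {
  stopifnot(inherits(boundary, "cell_boundary"))
  c(area = boundary$area, perimeter = boundary$perimeter)
}

#' Direct least-squares ellipse fit
#'
#' Fits the general conic u1 x^2 + u2 xy + u3 y^2 + u4 x + u5 y + u6 = 0 to a
#' set of points by minimizing the algebraic residual subject to the
#' ellipse-specific constraint 4 u1 u3 - u2^2 = 1 (the numerically stable
#' scatter-partitioned formulation), which guarantees an ellipse even on noisy
#' rasters where the unconstrained fit can return a hyperbola.
#'
#' @param x,y Point coordinates. `y` is interpreted in the mathematical y-up
#'   frame; pass `-row` when fitting raster pixels so that the reported
#'   orientation follows the package angle convention. Alternatively `x` may
#'   be a `cell_boundary`, in which case the conversion is done internally.
#' @return An `ellipse_fit`: list with semi-axes `a >= b`, orientation `theta`
#'   (degrees in (-90, 90], from the image x-axis), `center` (in the input
#'   frame), and conic `coefficients`.
#' @export
fit_ellipse <- function(x, y = NULL) {
  if (inherits(x, "cell_boundary")) {
    # circular moving average along the ordered loop suppresses the
    # half-pixel quantization bias of raster boundaries, which otherwise
    # inflates the eccentricity of near-circular cells
    b <- x
    sm <- smooth_loop(cbind(b$x, -b$y), window = 7L)
    x <- sm[, 1L]; y <- sm[, 2L]
  }
  stopifnot(length(x) == length(y))
  if (length(x) < 6L)
    stop("ellipse fitting needs at least 6 points", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y))
  if (!is.finite(sc) || sc < .Machine$double.eps)
    stop("degenerate point set: no spatial extent", call. = FALSE)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  sv <- svd(cbind(xs, ys))$d
  if (sv[2L] / sv[1L] < 1e-10)
    stop("collinear points: cannot fit an ellipse", call. = FALSE)
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)),
                 error = function(e) stop("degenerate/collinear points: cannot fit an ellipse",
                                          call. = FALSE))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1L, ] * V[3L, ] - V[2L, ]^2
  sel <- which(cond > 0)
  if (length(sel) == 0L)
    stop("no ellipse solution for these points", call. = FALSE)
  a1 <- V[, sel[1L]]
  coef <- c(a1, as.vector(Tm %*% a1))  # conic in scaled, centered coords
  A <- coef[1L]; B <- coef[2L]; C <- coef[3L]
  D <- coef[4L]; E <- coef[5L]; F <- coef[6L]
  den <- B^2 - 4 * A * C
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  num1 <- A * E^2 + C * D^2 - B * D * E + den * F
  tmp <- sqrt((A - C)^2 + B^2)
  a <- -sqrt(2 * num1 * ((A + C) + tmp)) / den
  b <- -sqrt(2 * num1 * ((A + C) - tmp)) / den
  if (!is.finite(a) || !is.finite(b))
    stop("degenerate ellipse fit", call. = FALSE)
  th <- atan2(B, A - C) / 2 + pi / 2  # major-axis direction
  if (a < b) { tt <- a; a <- b; b <- tt; th <- th + pi / 2 }
  structure(list(a = a * sc, b = b * sc,
                 theta = wrap_axial(rad2deg(th)),
                 center = c(x = x0 * sc + mx, y = y0 * sc + my),
                 coefficients = coef),
            class = "ellipse_fit")
}

#' Eccentricity of a fitted ellipse
#'
#' epsilon = sqrt(1 - b^2/a^2): 0 for a circle, approaching 1 for highly
#' elongated cells.
#'
#' @param fit An `ellipse_fit`, or a `cell_boundary` (fitted internally).
#' @return Eccentricity in [0, 1).
#' @export
ellipse_eccentricity <- function(fit) {
  if (inherits(fit, "cell_boundary")) fit <- fit_ellipse(fit)
  stopifnot(inherits(fit, "ellipse_fit"))
  if (fit$b > fit$a)
    stop("internal inconsistency: semi-minor axis exceeds semi-major axis",
         call. = FALSE)
  sqrt(1 - (fit$b / fit$a)^2)
}

#' Shape regularity of a polygon
#'
#' Measures how far a polygon departs from the regular n-gon in both its
#' equilateral and equiangular properties. With edge lengths l_i (median
#' l_med, total l_sum) and interior angles phi_i, the deviation is
#' D = sum(|l_i - l_med|)/l_sum + mean(|phi_i - phi_reg|)/phi_reg with
#' phi_reg = (n-2) pi / n, and the regularity is mu = max(0, 1 - D): 1 for a
#' perfect regular polygon, decreasing with edge-length or angle dispersion.
#' The exact functional form is this package's reconstruction; treat mu as
#' method-internal rather than comparable across tools.
#'
#' @param vertices An n x 2 matrix of polygon vertices in order (n >= 3).
#' @return Regularity mu in [0, 1].
#' @export
polygon_regularity <- function(vertices) {
  V <- as.matrix(vertices)
  n <- nrow(V)
  if (n < 3L) stop("a polygon needs at least 3 vertices", call. = FALSE)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  e <- V[nxt, , drop = FALSE] - V
  l <- sqrt(rowSums(e^2))
  if (any(l < .Machine$double.eps))
    stop("degenerate polygon: zero-length edge", call. = FALSE)
  a <- V[prv, , drop = FALSE] - V
  b <- V[nxt, , drop = FALSE] - V
  cosphi <- rowSums(a * b) / sqrt(rowSums(a^2) * rowSums(b^2))
  phi <- acos(pmin(1, pmax(-1, cosphi)))
  phireg <- (n - 2) * pi / n
  D <- sum(abs(l - stats::median(l))) / sum(l) +
    mean(abs(phi - phireg)) / phireg
  max(0, 1 - D)
}

#' Shape regularity of a cell
#'
#' Applies [polygon_regularity()] to the cell polygonized at its vertices
#' (edge lengths are vertex-to-vertex chords, not raster path lengths).
#'
#' @param boundary A `cell_boundary`.
#' @return Regularity mu in [0, 1].
#' @export
regularity <- function(boundary) {
  stopifnot(inherits(boundary, "cell_boundary"))
  V <- boundary$vertex_pos
  polygon_regularity(cbind(V[, 1L], -V[, 2L]))  # y-up frame
}

#' Number of cell junctions (polygon sides)
#'
#' Edges shorter than 10% of the cell's mean edge length are not considered
#' sides. For interior cells the count equals the number of neighboring cells.
#'
#' @param boundary A `cell_boundary`.
#' @param min_frac Minimum edge length as a fraction of the mean edge length.
#' @return Integer junction count.
#' @export
count_junctions <- function(boundary, min_frac = 0.10) {
  stopifnot(inherits(boundary, "cell_boundary"))
  l <- boundary$edges$chord
  sum(l >= min_frac * mean(l))
}

#' Morphology table for all cells of a lattice
#'
#' @param lattice A `cell_lattice`.
#' @param corner_tol Corner tolerance passed to [trace_boundary()].
#' @return data.frame with columns cell_id, area_px2, perimeter_px,
#'   regularity, eccentricity, orientation_deg, n_junctions.
#' @export
shape_metrics <- function(lattice, corner_tol = 1.5) {
  stopifnot(inherits(lattice, "cell_lattice"))
  rows <- lapply(lattice$cells, function(id) {
    b <- trace_boundary(lattice, id, corner_tol = corner_tol)
    f <- fit_ellipse(b)
    data.frame(cell_id = id, area_px2 = b$area, perimeter_px = b$perimeter,
               regularity = regularity(b),
               eccentricity = ellipse_eccentricity(f),
               orientation_deg = f$theta,
               n_junctions = count_junctions(b))
  })
  do.call(rbind, rows)
}
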