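# Internal helpers shared across modules.
#
# Coordinate conventions used throughout the package:
#  * images are numeric matrices m[row, col]; x = column index, y = row index
#    (y increases downwards on screen, as for any raster image);
#  * angles are reported in a mathematical y-up frame: theta = atan2(-(dy), dx),
#    so 0 deg lies along the image x-axis and +90 deg points up the image;
#  * polarity angles and cell orientations are axial (theta == theta + 180 deg)
#    and reported in (-90, +90] degrees.

# wrap an angle in degrees into the axial interval (-90, 90]
wrap_axial <- function(deg) {
  d <- ((deg + 90) %% 180) - 90
  d[d == -90] <- 90
  d
}

# axial angular distance in degrees, in [0, 90]
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# circular midpoint weights for sorted angles th (radians, ascending);
# returns weights summing to exactly 2*pi
midpoint_weights <- function(th) {
  n <- length(th)
  if (n < 3L) stop("angular weighting needs at least 3 points", call. = FALSE)
  nxt <- c(diff(th), th[1L] + 2 * pi - th[n])
  w <- (nxt + c(nxt[n], nxt[-n])) / 2
  w * (2 * pi / sum(w))
}

# shoelace area of a polygon given vertex matrix V[, c("x","y")] (any frame)
polygon_area <- function(V) {
  x <- V[, 1L]; y <- V[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  abs(sum(x * y2 - x2 * y)) / 2
}

polygon_perimeter <- function(V) {
  sum(sqrt(rowSums((V - V[c(2:nrow(V), 1L), , drop = FALSE])^2)))
}

# area centroid of a polygon
polygon_centroid <- function(V) {
  x <- V[, 1L]; y <- V[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

# integer Bresenham line between two pixels, returned as a 2-column matrix
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  r <- r0; cc <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, cc)
    if (r == r1 && cc == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; cc <- cc + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  out
}

# closed-loop polyline simplification (Douglas-Peucker); pts is an n x 2
# matrix of loop coordinates in traversal order; returns indices of corners
dp_corners <- function(pts, tol = 1.5) {
  n <- nrow(pts)
  if (n < 4L) return(seq_len(n))
  d0 <- sqrt(rowSums((pts - matrix(pts[1L, ], n, 2L, byrow = TRUE))^2))
  i1 <- which.max(d0)
  keep <- logical(n)
  keep[c(1L, i1)] <- TRUE
  rec <- function(a, b) {
    idx <- if (a < b) seq(a, b) else c(seq(a, n), seq_len(b))
    if (length(idx) <= 2L) return(invisible())
    p0 <- pts[a, ]; p1 <- pts[b, ]
    v <- p1 - p0
    L <- sqrt(sum(v^2))
    mid <- idx[-c(1L, length(idx))]
    if (L < .Machine$double.eps) {
      dd <- sqrt(rowSums((pts[mid, , drop = FALSE] -
                            matrix(p0, length(mid), 2L, byrow = TRUE))^2))
    } else {
      w <- pts[mid, , drop = FALSE] - matrix(p0, length(mid), 2L, byrow = TRUE)
      dd <- abs(w[, 1L] * v[2L] - w[, 2L] * v[1L]) / L
    }
    if (max(dd) > tol) {
      im <- mid[which.max(dd)]
      keep[im] <<- TRUE
      rec(a, im); rec(im, b)
    }
    invisible()
  }
  rec(1L, i1); rec(i1, 1L)
  which(keep)
}

# circular moving average of an ordered closed loop (n x 2 matrix)
smooth_loop <- function(pts, window = 7L) {
  n <- nrow(pts)
  if (n <= window) return(pts)
  h <- window %/% 2L
  out <- pts
  for (d in setdiff(-h:h, 0L)) {
    idx <- ((seq_len(n) - 1L + d) %% n) + 1L
    out <- out + pts[idx, , drop = FALSE]
  }
  out / (2L * h + 1L)
}

# drop polygon corners whose perpendicular distance to the chord between
# their neighbors is below tol (spurious raster corners), iteratively
prune_corners <- function(pts, idx, tol) {
  repeat {
    m <- length(idx)
    if (m <= 3L) return(idx)
    P <- pts[idx, , drop = FALSE]
    prv <- P[c(m, 1:(m - 1L)), , drop = FALSE]
    nxt <- P[c(2:m, 1L), , drop = FALSE]
    v <- nxt - prv
    L <- sqrt(rowSums(v^2))
    w <- P - prv
    d <- abs(w[, 1L] * v[, 2L] - w[, 2L] * v[, 1L]) / pmax(L, 1e-12)
    if (min(d) >= tol) return(idx)
    idx <- idx[-which.min(d)]
  }
}

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
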