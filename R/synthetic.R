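# Synthetic epithelial cell generator: rasterized polygonal cells with
# controlled geometry (area/perimeter, shape regularity, eccentricity) and
# junctional intensity models (two-level and punctate), plus ground truth.
# These are the validation fixtures for the polarity methods.

# regular n-gon with one edge centered on the +x axis (flat left/right sides:
# "vertical junctions" flank the x poles)
base_polygon <- function(n) {
  ang <- deg2rad(180 / n + (0:(n - 1L)) * 360 / n)
  cbind(x = cos(ang), y = sin(ang))
}

# jitter vertices to reach a target regularity; deterministic given seed.
# The jitter is mirror-symmetric about the x-axis so that the fixture's
# ground-truth polarity axis stays exactly at 0 degrees: an asymmetric shape
# perturbation would move the true axis itself, confounding angle readouts.
jitter_to_regularity <- function(V, target, seed, tol = 0.005) {
  if (target >= 1) return(V)
  n <- nrow(V)
  # mirror partner of each vertex (vertex angles are +-(180/n + k*360/n))
  ang <- atan2(V[, 2L], V[, 1L])
  partner <- vapply(seq_len(n), function(i) {
    d <- abs(atan2(sin(ang + ang[i]), cos(ang + ang[i])))
    which.min(d)
  }, 1L)
  for (attempt in 1:25) {
    u <- with_seed(seed * 131L + attempt, matrix(stats::runif(2L * n, -1, 1), n, 2L))
    for (i in seq_len(n)) {
      j <- partner[i]
      if (j > i) u[j, ] <- c(u[i, 1L], -u[i, 2L])
      if (j == i) u[i, 2L] <- 0  # vertices on the axis move along it only
    }
    f <- function(eta) polygon_regularity(V + eta * u)
    lo <- 0; hi <- 0.75
    # find hi with mu below target (mu decreases with eta overall)
    ok <- FALSE
    for (hh in seq(0.1, 0.75, by = 0.05)) {
      if (f(hh) <= target) { hi <- hh; ok <- TRUE; break }
    }
    if (!ok) next
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > target) lo <- mid else hi <- mid
      if (abs(f(mid) - target) < tol) return(V + mid * u)
    }
    if (abs(f(hi) - target) < 2 * tol) return(V + hi * u)
  }
  stop("could not reach regularity target ", target, call. = FALSE)
}

# anisotropic area-preserving stretch (x*s, y/s) to reach a target fitted
# eccentricity (major axis along x), refined against the dense-outline
# ellipse fit. Also runs for target 0, where it removes the net anisotropy a
# vertex jitter introduces: each geometric factor is varied in isolation.
stretch_to_eccentricity <- function(V, target) {
  s <- (1 - target^2)^(-1 / 4)
  # near a circle the eccentricity responds as sqrt(scale error), so converge
  # on the squared eccentricity with a dense outline fit
  for (it in 1:10) {
    Vs <- cbind(V[, 1L] * s, V[, 2L] / s)
    P <- outline_samples(Vs, step = polygon_perimeter(Vs) / 6000)
    f <- fit_ellipse(P$x, P$y)
    ea <- ellipse_eccentricity(f)
    vertical <- abs(f$theta) > 45  # major axis along y: stretch x more
    es2 <- if (vertical) -ea^2 else ea^2
    if (abs(es2 - target^2) < 1e-4) break
    fac <- ((1 - min(ea, 0.995)^2) / (1 - target^2))^(if (vertical) -1 / 4 else 1 / 4)
    s <- s * fac
  }
  cbind(V[, 1L] * s, V[, 2L] / s)
}

# dense samples along the polygon outline (math frame): positions, arc
# position s, angle theta about the area centroid, and edge index
outline_samples <- function(V, step = 0.2) {
  n <- nrow(V)
  cen <- polygon_centroid(V)
  segs <- lapply(seq_len(n), function(i) {
    a <- V[i, ]; b <- V[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    m <- max(2L, ceiling(len / step))
    t <- (seq_len(m) - 0.5) / m
    cbind(x = a[1L] + t * (b[1L] - a[1L]),
          y = a[2L] + t * (b[2L] - a[2L]),
          dl = len / m, edge = i)
  })
  P <- do.call(rbind, segs)
  s <- cumsum(P[, "dl"]) - P[, "dl"] / 2
  list(x = P[, "x"], y = P[, "y"], dl = P[, "dl"], edge = P[, "edge"],
       s = s, theta = atan2(P[, "y"] - cen[2L], P[, "x"] - cen[1L]),
       per = sum(P[, "dl"]), cen = cen, V = V)
}

# which edges are "vertical junctions" (outward normal within 45 deg of the
# x-axis) / "horizontal junctions" (within 45 deg of the y-axis)
edge_axis_class <- function(P) {
  V <- P$V; n <- nrow(V)
  vapply(seq_len(n), function(i) {
    a <- V[i, ]; b <- V[if (i == n) 1L else i + 1L, ]
    e <- b - a
    nv <- c(e[2L], -e[1L])
    mid <- (a + b) / 2 - P$cen
    if (sum(nv * mid) < 0) nv <- -nv
    ang <- abs(atan2(nv[2L], nv[1L])) * 180 / pi
    ang <- min(ang, 180 - ang)  # axial angle to x-axis
    if (ang <= 45) "vertical" else "horizontal"
  }, "")
}

# arc distance (circular) from each sample to the outline points nearest the
# two x-poles (theta = 0 and theta = pi)
arc_dist_to_poles <- function(P) {
  i0 <- which.min(abs(P$theta))
  ipi <- which.min(pi - abs(P$theta))
  dmin <- rep(Inf, length(P$s))
  for (p0 in c(P$s[i0], P$s[ipi])) {
    d <- abs(P$s - p0)
    dmin <- pmin(dmin, pmin(d, P$per - d))
  }
  dmin
}

# intensity values along the outline samples for the chosen model
paint_intensity <- function(P, model, placement, peak, base, coverage,
                            sector_half_deg, puncta_spacing_deg, puncta_sigma,
                            sigma_units, puncta_phase_deg) {
  axd <- function(th) {
    d <- abs((rad2deg(th)) %% 180)
    pmin(d, 180 - d)
  }
  peak_mask <- switch(placement,
    vertical_junctions = edge_axis_class(P)[P$edge] == "vertical",
    horizontal_junctions = edge_axis_class(P)[P$edge] == "horizontal",
    sector = axd(P$theta) <= sector_half_deg,
    coverage = {
      if (is.null(coverage)) stop("coverage placement needs `coverage`", call. = FALSE)
      if (coverage < 0 || coverage > P$per + 1e-9)
        stop("coverage must lie in [0, perimeter]", call. = FALSE)
      if (coverage >= P$per) rep(TRUE, length(P$s)) else
        arc_dist_to_poles(P) < coverage / 4
    },
    stop("unknown placement: ", placement, call. = FALSE))
  if (placement == "horizontal_junctions") truth_axis <- 90 else truth_axis <- 0
  if (model == "two_level") {
    I <- ifelse(peak_mask, peak, base)
  } else if (model == "puncta") {
    if (puncta_sigma <= 0) stop("puncta sigma must be positive", call. = FALSE)
    if (360 %% puncta_spacing_deg != 0)
      stop("puncta spacing must divide 360 degrees", call. = FALSE)
    # centers offset by half a spacing so none sits exactly on a polygon
    # vertex or placement border (degenerate alignment)
    centers_th <- deg2rad(puncta_phase_deg +
                            seq(0, 360 - puncta_spacing_deg, by = puncta_spacing_deg))
    centers_th <- atan2(sin(centers_th), cos(centers_th))
    ci <- vapply(centers_th, function(a) {
      dd <- abs(atan2(sin(P$theta - a), cos(P$theta - a)))
      which.min(dd)
    }, 1L)
    keep <- peak_mask[ci]  # puncta on peak junctions only
    cs <- P$s[ci][keep]
    if (length(cs) == 0L) {
      I <- rep(base, length(P$s))
    } else {
      sig <- if (sigma_units == "deg")
        puncta_sigma * P$per / 360 else puncta_sigma
      dmin <- rep(Inf, length(P$s))
      for (c0 in cs) {
        d <- abs(P$s - c0)
        dmin <- pmin(dmin, pmin(d, P$per - d))
      }
      I <- base + (peak - base) * exp(-dmin^2 / (2 * sig^2))
    }
  } else stop("unknown intensity model: ", model, call. = FALSE)
  list(I = I, axis = truth_axis, peak_mask = peak_mask)
}

#' Generate a synthetic epithelial cell with ground truth
#'
#' Constructs a polygonal cell (regular n-gon, optional vertex jitter to hit a
#' shape-regularity target, optional area-preserving anisotropic stretch along
#' the x-axis to hit an eccentricity target), rasterizes its outline as a
#' 1-pixel skeleton loop, and paints a junctional intensity image (a band of
#' width `band` around the outline) according to the chosen model:
#' \describe{
#'   \item{two_level}{peak intensity (default 255 a.u.) on a chosen placement,
#'     base (default 40 a.u.) elsewhere. Placements: `vertical_junctions`
#'     (edges whose outward normal is within 45 deg of the x-axis),
#'     `horizontal_junctions`, `sector` (|theta| <= sector_half_deg, axially),
#'     `coverage` (`coverage` perimeter-px of peak grown symmetrically from
#'     the two x-poles of the outline).}
#'   \item{puncta}{Gaussian intensity bumps (floor `base`, amplitude `peak`)
#'     centered every `puncta_spacing_deg` around the boundary; only puncta
#'     whose centers lie on the peak placement carry the full amplitude, so
#'     the cell is a punctate version of the two-level cell. `puncta_sigma`
#'     is the Gaussian sigma in boundary-arc pixels (or degrees with
#'     `sigma_units = "deg"`).}
#' }
#' The ground-truth polarity axis is 0 deg for all placements except
#' `horizontal_junctions` (90 deg).
#'
#' @param n_sides Number of polygon sides (default 6).
#' @param perimeter Target polygon perimeter (px). Exactly one of `perimeter`
#'   and `area` is used; default is a perimeter of 440 px.
#' @param area Target enclosed raster area (px^2), within ~5%.
#' @param eccentricity Target fitted eccentricity (0 to <1), within ~0.02.
#' @param regularity Target shape regularity (0 to 1], within ~0.01.
#' @param model `"two_level"` or `"puncta"`.
#' @param placement Peak placement (see Details).
#' @param peak,base Peak and base intensities (a.u.).
#' @param coverage Peak coverage in perimeter px (placement `"coverage"`).
#' @param sector_half_deg Sector half-width in degrees (placement `"sector"`).
#' @param puncta_spacing_deg,puncta_sigma,sigma_units,puncta_phase_deg Puncta
#'   parameters. Sigma is interpreted in degrees by default (converted to arc
#'   px via the perimeter), which makes the angular profile independent of
#'   cell size; `sigma_units = "px"` uses boundary-arc pixels directly. The
#'   phase offsets punctum centers (default half a spacing) so none sits on a
#'   polygon vertex or placement border.
#' @param band Width of the painted junctional band (px).
#' @param margin Canvas margin around the cell (px).
#' @param bits Image bit depth (intensities clipped to [0, 2^bits - 1]).
#' @param seed Seed for the (deterministic) regularity jitter.
#' @return A `synthetic_cell`: list with `intensity` (matrix), `skeleton`
#'   (0/1 matrix) and `truth` (axis_deg, perimeter, area_polygon, vertices,
#'   centroid (x,y in pixel coordinates), regularity, eccentricity, peak
#'   arc fraction, and the generation parameters).
#' @export
synthetic_cell <- function(n_sides = 6, perimeter = NULL, area = NULL,
                           eccentricity = 0, regularity = 1,
                           model = c("two_level", "puncta"),
                           placement = c("vertical_junctions",
                                         "horizontal_junctions",
                                         "sector", "coverage"),
                           peak = 255, base = 40,
                           coverage = NULL, sector_half_deg = 60,
                           puncta_spacing_deg = 15, puncta_sigma = 4.47,
                           sigma_units = c("deg", "px"),
                           puncta_phase_deg = puncta_spacing_deg / 2,
                           band = 5, margin = 8, bits = 8, seed = 1) {
  model <- match.arg(model)
  placement <- match.arg(placement)
  sigma_units <- match.arg(sigma_units)
  if (peak < base || base <= 0)
    stop("need peak >= base > 0", call. = FALSE)
  if (is.null(perimeter) && is.null(area)) perimeter <- 440

  V <- base_polygon(n_sides)
  V <- jitter_to_regularity(V, regularity, seed)
  V <- stretch_to_eccentricity(V, eccentricity)
  if (regularity < 1) {
    # the eccentricity-normalizing stretch shifts the achieved regularity;
    # re-target the jitter against the composite until both land
    tgt <- regularity
    for (round in 1:4) {
      mu <- polygon_regularity(V)
      if (abs(mu - regularity) <= 0.008) break
      tgt <- min(max(tgt + (regularity - mu), 0.05), 0.995)
      V <- stretch_to_eccentricity(
        jitter_to_regularity(base_polygon(n_sides), tgt, seed), eccentricity)
    }
  }
  if (!is.null(perimeter)) {
    V <- V * perimeter / polygon_perimeter(V)
  } else {
    # one correction for the ~P/2 boundary pixels excluded from the interior
    V <- V * sqrt(area / polygon_area(V))
    V <- V * sqrt((area + polygon_perimeter(V) / 2) / polygon_area(V))
  }
  cen <- polygon_centroid(V)
  V <- V - matrix(cen, nrow(V), 2L, byrow = TRUE)

  P <- outline_samples(V, step = 0.2)
  pa <- paint_intensity(P, model, placement, peak, base, coverage,
                        sector_half_deg, puncta_spacing_deg, puncta_sigma,
                        sigma_units, puncta_phase_deg)

  # canvas: math (x, y) -> (row = y0 - y, col = x0 + x)
  xr <- range(P$x); yr <- range(P$y)
  W <- ceiling(diff(xr)) + 2L * margin + 1L
  H <- ceiling(diff(yr)) + 2L * margin + 1L
  col_of <- function(x) margin + 1L + (x - floor(xr[1L]))
  row_of <- function(y) (H - margin) - (y - floor(yr[1L]))
  skel <- matrix(0L, H, W)
  Vi <- cbind(round(row_of(V[, 2L])), round(col_of(V[, 1L])))
  n <- nrow(Vi)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    seg <- bresenham(Vi[i, 1L], Vi[i, 2L], Vi[j, 1L], Vi[j, 2L])
    skel[seg] <- 1L
  }
  # paint a band of width `band` around the outline; each pixel takes the
  # intensity of its nearest outline sample, so model borders land on the
  # geometric bisector (no traversal-order bias)
  img <- matrix(0, H, W)
  D2 <- matrix(Inf, H, W)
  re <- row_of(P$y); ce <- col_of(P$x)
  rr <- round(re); cc <- round(ce)
  fr <- re - rr; fc <- ce - cc
  rad <- band / 2
  ran <- ceiling(rad)
  off <- expand.grid(dr = -ran:ran, dc = -ran:ran)
  off <- off[off$dr^2 + off$dc^2 <= (rad + 0.5)^2, , drop = FALSE]
  for (kk in seq_len(nrow(off))) {
    r2 <- rr + off$dr[kk]; c2 <- cc + off$dc[kk]
    d2 <- (off$dr[kk] - fr)^2 + (off$dc[kk] - fc)^2
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W & d2 <= rad^2
    if (!any(ok)) next
    li <- r2[ok] + (c2[ok] - 1L) * H
    o <- order(d2[ok], decreasing = TRUE)
    li <- li[o]; dd <- d2[ok][o]; vals <- pa$I[ok][o]
    better <- dd < D2[li]
    D2[li[better]] <- dd[better]
    img[li[better]] <- vals[better]
  }
  img <- round(pmin(img, 2^bits - 1))

  fit <- fit_ellipse(P$x, P$y)
  truth <- list(axis_deg = pa$axis,
                perimeter = P$per,
                area_polygon = polygon_area(V),
                vertices = V,
                centroid = c(x = col_of(0), y = row_of(0)),
                regularity = polygon_regularity(V),
                eccentricity = ellipse_eccentricity(fit),
                peak_fraction = sum(P$dl[pa$peak_mask]) / P$per,
                params = list(n_sides = n_sides, model = model,
                              placement = placement, peak = peak, base = base,
                              coverage = coverage,
                              sector_half_deg = sector_half_deg,
                              puncta_spacing_deg = puncta_spacing_deg,
                              puncta_sigma = puncta_sigma, band = band,
                              bits = bits, seed = seed))
  structure(list(intensity = img, skeleton = skel, truth = truth),
            class = "synthetic_cell")
}

#' @export
print.synthetic_cell <- function(x, ...) {
  cat("synthetic_cell:", nrow(x$intensity), "x", ncol(x$intensity), "px,",
      x$truth$params$model, "/", x$truth$params$placement,
      "- axis", x$truth$axis_deg, "deg\n")
  invisible(x)
}

#' Add Gaussian noise to a synthetic cell
#'
#' Adds zero-mean normally distributed noise with standard deviation set so
#' that (mean junctional signal)/(noise sd) equals `snr`, clipped to the
#' image bit range. Deterministic given the seed.
#'
#' @param cell A `synthetic_cell`.
#' @param snr Signal-to-noise ratio (> 0; `Inf` returns the input).
#' @param seed RNG seed.
#' @return The cell with noisy intensity; noise parameters recorded in
#'   `truth$noise`.
#' @export
add_noise <- function(cell, snr, seed = 1) {
  stopifnot(inherits(cell, "synthetic_cell"))
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive", call. = FALSE)
  if (!is.finite(snr)) return(cell)
  sig <- mean(cell$intensity[cell$skeleton == 1L])
  sd <- sig / snr
  noise <- with_seed(seed,
                     matrix(stats::rnorm(length(cell$intensity), 0, sd),
                            nrow(cell$intensity)))
  top <- 2^cell$truth$params$bits - 1
  cell$intensity <- pmin(pmax(cell$intensity + noise, 0), top)
  cell$truth$noise <- list(snr = snr, sd = sd, seed = seed)
  cell
}

#' Generate a parameter sweep of synthetic cells
#'
#' Varies one generator field over a grid, holding everything else fixed;
#' returns the fixtures plus a manifest binding parameters to list positions.
#'
#' @param field One of "area", "perimeter", "regularity", "eccentricity",
#'   "coverage", "peak", "snr".
#' @param values Grid of values for the field.
#' @param ... Remaining arguments passed to [synthetic_cell()] (for
#'   `field = "snr"`, the noiseless cell parameters; noise seeds derive from
#'   `seed`).
#' @param seed Base seed.
#' @return List with `cells` (list of `synthetic_cell`) and `manifest`
#'   (data.frame field, value, index).
#' @export
synthetic_sweep <- function(field, values, ..., seed = 1) {
  stopifnot(length(values) >= 1L)
  args <- list(...)
  cells <- vector("list", length(values))
  if (field == "snr") {
    base_cell <- do.call(synthetic_cell, c(args, list(seed = seed)))
    for (i in seq_along(values))
      cells[[i]] <- add_noise(base_cell, values[i], seed = seed + i)
  } else {
    for (i in seq_along(values)) {
      ai <- args
      ai[[field]] <- values[i]
      ai$seed <- seed
      cells[[i]] <- do.call(synthetic_cell, ai)
    }
  }
  list(cells = cells,
       manifest = data.frame(field = field, value = values,
                             index = seq_along(values)))
}

#' Save a synthetic cell to disk
#'
#' Writes the intensity image as TIFF, the skeleton as PNG, and the ground
#' truth as JSON, using a common path prefix.
#'
#' @param cell A `synthetic_cell`.
#' @param prefix Path prefix (files `<prefix>_intensity.tif`,
#'   `<prefix>_skeleton.png`, `<prefix>_truth.json`).
#' @return Invisibly, the written file paths.
#' @export
save_synthetic_cell <- function(cell, prefix) {
  stopifnot(inherits(cell, "synthetic_cell"))
  bits <- cell$truth$params$bits
  depth <- if (bits <= 8) 8L else 16L
  f1 <- paste0(prefix, "_intensity.tif")
  f2 <- paste0(prefix, "_skeleton.png")
  f3 <- paste0(prefix, "_truth.json")
  tiff::writeTIFF(cell$intensity / (2^depth - 1), f1,
                  bits.per.sample = depth)
  png::writePNG(cell$skeleton + 0, f2)
  tr <- cell$truth
  tr$vertices <- apply(tr$vertices, 1L, function(v) c(x = v[[1]], y = v[[2]]),
                       simplify = FALSE)
  jsonlite::write_json(tr, f3, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(f1, f2, f3))
}
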