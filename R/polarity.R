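# The three cell-scale polarity methods. All operate on a boundary_profile
# and report an axial polarity angle in (-90, 90] degrees (0 = image x-axis)
# plus a method-specific raw magnitude:
#   * fourier: magnitude >= 0, 0 = unpolarized
#   * ratio:   asymmetry >= 1, 1 = unpolarized
#   * pca:     lambda1 - lambda2 >= 0, 0 = unpolarized

polarity_row <- function(cell_id, method, p, ang) {
  data.frame(cell_id = cell_id, method = method,
             magnitude_raw = p, angle_deg = ang)
}

#' Fourier Series polarity
#'
#' Second-harmonic tensor of the angular intensity distribution: with
#' boundary samples (I_i, theta_i) and arc weights dl_i,
#' Q1 = sum(I dl cos 2theta)/N, Q2 = sum(I dl sin 2theta)/N, N = sum(I dl).
#' Magnitude p = sqrt(Q1^2 + Q2^2); angle = atan2(Q2, Q1)/2. Per-pixel (arc)
#' weighting follows the pixel-sum construction of the established Fourier
#' implementations, and is what makes this readout sensitive to cell
#' eccentricity (junctions close to the centroid carry more arc per angle).
#'
#' @param profile A `boundary_profile`.
#' @return One-row data.frame: cell_id, method, magnitude_raw, angle_deg.
#' @export
fourier_polarity <- function(profile) {
  stopifnot(inherits(profile, "boundary_profile"))
  w <- profile$I * profile$dl
  N <- sum(w)
  if (N <= 0) stop("degenerate signal: all intensities are zero", call. = FALSE)
  Q1 <- sum(w * cos(2 * profile$theta)) / N
  Q2 <- sum(w * sin(2 * profile$theta)) / N
  p <- sqrt(Q1^2 + Q2^2)
  ang <- if (p < 1e-12) NA_real_ else wrap_axial(rad2deg(atan2(Q2, Q1) / 2))
  polarity_row(profile$cell_id, "fourier", p, ang)
}

#' Ratio (rotating-quadrant) polarity
#'
#' The angular profile is linearly interpolated onto a uniform angular grid;
#' for each trial angle phi a square-wave template of four 90-degree bins is
#' applied, and the asymmetry is the ratio of the summed mean intensities of
#' one opposite bin pair to the other, oriented so it is >= 1. Asymmetries
#' are rounded to a precision of 1e-3; the raw magnitude is the maximum
#' asymmetry and the angle is the circular (axial) mean of all maximizing
#' trial angles.
#'
#' @param profile A `boundary_profile`.
#' @param angle_step Trial-angle step in degrees.
#' @param resample_step Interpolation grid step in degrees.
#' @param return_scan Also return the full asymmetry-vs-angle scan?
#' @return One-row data.frame (plus a `scan` attribute if requested).
#' @export
ratio_polarity <- function(profile, angle_step = 1, resample_step = 1,
                           return_scan = FALSE) {
  stopifnot(inherits(profile, "boundary_profile"))
  if (sum(profile$I) <= 0)
    stop("degenerate signal: all intensities are zero", call. = FALSE)
  thd <- rad2deg(profile$theta)  # sorted ascending in (-180, 180]
  grid <- seq(-180, 180 - resample_step, by = resample_step)
  Ig <- stats::approx(c(thd - 360, thd, thd + 360), rep(profile$I, 3),
                      xout = grid)$y
  phis <- seq(0, 90 - angle_step, by = angle_step)
  asym <- rep(NA_real_, length(phis))
  axis_of_max <- rep(NA_real_, length(phis))
  for (j in seq_along(phis)) {
    d <- (grid - phis[j]) %% 360
    b1 <- d >= 315 | d < 45
    b2 <- d >= 45 & d < 135
    b3 <- d >= 135 & d < 225
    pA <- mean(Ig[b1]) + mean(Ig[b3])
    pB <- mean(Ig[b2]) + mean(Ig[!(b1 | b2 | b3)])
    if (pA == 0 && pB == 0) next
    if (min(pA, pB) == 0) next  # undefined ratio at this trial angle
    asym[j] <- round(max(pA / pB, pB / pA), 3)
    axis_of_max[j] <- if (pA >= pB) phis[j] else phis[j] + 90
  }
  if (all(is.na(asym))) {
    warning("all trial angles undefined; degenerate signal")
    stop("degenerate signal: asymmetry undefined at every trial angle",
         call. = FALSE)
  }
  pmax_ <- max(asym, na.rm = TRUE)
  maxers <- axis_of_max[!is.na(asym) & asym == pmax_]
  z <- mean(exp(2i * deg2rad(maxers)))
  ang <- if (pmax_ <= 1 + 1e-9 || Mod(z) < 1e-12) NA_real_ else
    wrap_axial(rad2deg(Arg(z) / 2))
  out <- polarity_row(profile$cell_id, "ratio", pmax_, ang)
  if (return_scan)
    attr(out, "scan") <- data.frame(phi_deg = phis, asymmetry = asym)
  out
}

#' Compress a cell to a regular shape
#'
#' Applies the shape-normalizing transform of the PCA method: boundary points
#' are rotated so the fitted ellipse's major axis lies along x, scaled along
#' that axis by the compression factor alpha (default b/a, which maps the
#' fitted ellipse to a circle), rotated back, all relative to the centroid.
#' Angles and both weightings are recomputed on the transformed coordinates;
#' intensities are unchanged.
#'
#' @param profile A `boundary_profile`.
#' @param fit An `ellipse_fit` for the same cell (computed from the profile
#'   points if omitted).
#' @param alpha Compression factor in (0, 1]; default `fit$b / fit$a`.
#' @return The transformed `boundary_profile` (coordinates are centroid-
#'   relative; `y` stays in the row/down convention).
#' @export
compress_cell <- function(profile, fit = NULL, alpha = NULL) {
  stopifnot(inherits(profile, "boundary_profile"))
  if (is.null(fit)) fit <- fit_ellipse(profile$x, -profile$y)
  stopifnot(inherits(fit, "ellipse_fit"))
  if (is.null(alpha)) alpha <- fit$b / fit$a
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("compression factor alpha must lie in (0, 1]", call. = FALSE)
  thc <- deg2rad(fit$theta)
  xu <- profile$x - profile$centroid[["x"]]
  yu <- -(profile$y - profile$centroid[["y"]])  # y-up
  ct <- cos(-thc); st <- sin(-thc)
  xr <- xu * ct - yu * st
  yr <- xu * st + yu * ct
  xr <- xr * alpha
  ct2 <- cos(thc); st2 <- sin(thc)
  xt <- xr * ct2 - yr * st2
  yt <- xr * st2 + yr * ct2
  build_profile(xt, -yt, profile$I, c(x = 0, y = 0), profile$cell_id)
}

#' Normalize profile intensities
#'
#' I'_i = k * I_i / S(I) with the scale S either a high quantile of the
#' sampled intensities (default: 95th percentile, a robust maximum) or their
#' dtheta-weighted mean. A quantile scale leaves the normalized two-level
#' contrast independent of how much of the boundary carries peak signal,
#' and makes the readout exactly invariant to image brightness and bit depth.
#'
#' @param profile A `boundary_profile`.
#' @param k Normalization factor (default 1e3).
#' @param scale `"quantile"` or `"mean"`.
#' @param q Quantile used when `scale = "quantile"`.
#' @return The profile with normalized intensities.
#' @export
normalize_intensities <- function(profile, k = 1000, scale = c("quantile", "mean"),
                                  q = 0.95) {
  stopifnot(inherits(profile, "boundary_profile"))
  scale <- match.arg(scale)
  if (all(profile$I == 0))
    stop("degenerate signal: all intensities are zero", call. = FALSE)
  S <- switch(scale,
              quantile = stats::quantile(profile$I, q, names = FALSE, type = 7),
              mean = sum(profile$dtheta * profile$I) / sum(profile$dtheta))
  if (S <= 0) S <- max(profile$I)
  profile$I <- k * profile$I / S
  profile
}

#' Embed intensities as radial coordinates
#'
#' x_hat_i = I_i cos(theta_i), y_hat_i = I_i sin(theta_i): the intensity is
#' used as the distance from the centroid at its angle.
#'
#' @param profile A `boundary_profile` (typically normalized).
#' @return A list with `x`, `y` (the embedded cloud, y-up frame) and `w`
#'   (the dtheta weights).
#' @export
intensity_coords <- function(profile) {
  stopifnot(inherits(profile, "boundary_profile"))
  list(x = profile$I * cos(profile$theta),
       y = profile$I * sin(profile$theta),
       w = profile$dtheta)
}

#' Weighted covariance of a 2D point cloud
#'
#' sigma_ab = sum(w (a - abar)(b - bbar)) / sum(w) with weighted means.
#'
#' @param x,y Point coordinates.
#' @param w Non-negative weights.
#' @return A symmetric 2x2 covariance matrix.
#' @export
weighted_covariance <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(x) == length(w))
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  ws <- sum(w)
  mx <- sum(w * x) / ws
  my <- sum(w * y) / ws
  sxx <- sum(w * (x - mx)^2) / ws
  syy <- sum(w * (y - my)^2) / ws
  sxy <- sum(w * (x - mx) * (y - my)) / ws
  matrix(c(sxx, sxy, sxy, syy), 2L, 2L)
}

#' PCA polarity
#'
#' The shape-insensitive polarity readout: the cell is compressed to a
#' regular shape ([compress_cell()]), intensities are normalized
#' ([normalize_intensities()]) and embedded as radial points
#' ([intensity_coords()]), and the dtheta-weighted covariance eigensystem is
#' read out. With eigenvalues lambda1 >= lambda2, the raw magnitude is
#' p = lambda1 - lambda2 (0 iff the distribution is homogeneous, growing with
#' bipolarity) and the angle is the principal-axis direction
#' atan2(2 sigma_xy, sigma_xx - sigma_yy)/2, axial in (-90, 90].
#'
#' @param profile A `boundary_profile` (raw intensities).
#' @param fit Optional precomputed `ellipse_fit` of the cell.
#' @param k Normalization factor for [normalize_intensities()].
#' @param scale,q Normalization scale options.
#' @param compress Apply the compression transform? (default TRUE)
#' @return One-row data.frame: cell_id, method, magnitude_raw, angle_deg.
#'   For a homogeneous (degenerate) distribution the magnitude is ~0 and the
#'   angle is NA.
#' @export
pca_polarity <- function(profile, fit = NULL, k = 1000,
                         scale = c("quantile", "mean"), q = 0.95,
                         compress = TRUE) {
  stopifnot(inherits(profile, "boundary_profile"))
  scale <- match.arg(scale)
  pr <- if (compress) compress_cell(profile, fit) else profile
  pr <- normalize_intensities(pr, k = k, scale = scale, q = q)
  cl <- intensity_coords(pr)
  sig <- weighted_covariance(cl$x, cl$y, cl$w)
  tr <- sig[1L, 1L] + sig[2L, 2L]
  dt <- sqrt(((sig[1L, 1L] - sig[2L, 2L]) / 2)^2 + sig[1L, 2L]^2)
  l1 <- tr / 2 + dt
  l2 <- tr / 2 - dt
  p <- l1 - l2
  ang <- if (tr < .Machine$double.eps || p / tr < 1e-12) NA_real_ else
    wrap_axial(rad2deg(atan2(2 * sig[1L, 2L], sig[1L, 1L] - sig[2L, 2L]) / 2))
  polarity_row(profile$cell_id, "pca", p, ang)
}

#' Quantify planar polarity for every cell of an image
#'
#' Full per-image pipeline: segment (or reuse a lattice), filter, trace each
#' cell, sample its boundary intensity profile, and run the selected polarity
#' methods. Normalized magnitudes are computed per method across the cells of
#' this image ([normalize_across_dataset()]).
#'
#' @param image Intensity matrix.
#' @param skeleton Binary skeleton matrix (ignored when `lattice` is given).
#' @param lattice Optional prebuilt/filtered `cell_lattice` (e.g. to reuse a
#'   segmentation across noise replicates).
#' @param methods Subset of c("pca", "fourier", "ratio").
#' @param min_area,drop_border Filtering options (see [filter_cells()]).
#' @param thickness Sampling disk diameter (px).
#' @param k,scale,q PCA normalization options.
#' @param angle_step,resample_step Ratio method options.
#' @return data.frame with cell_id, method, magnitude_raw, magnitude_norm,
#'   angle_deg; the (filtered) lattice is attached as attribute "lattice".
#' @export
quantify_polarity <- function(image, skeleton = NULL, lattice = NULL,
                              methods = c("pca", "fourier", "ratio"),
                              min_area = 1, drop_border = TRUE,
                              thickness = 3, k = 1000,
                              scale = "quantile", q = 0.95,
                              angle_step = 1, resample_step = 1) {
  methods <- match.arg(methods, c("pca", "fourier", "ratio"),
                       several.ok = TRUE)
  if (is.null(lattice)) {
    if (is.null(skeleton)) stop("provide a skeleton or a lattice", call. = FALSE)
    if (!all(dim(image) == dim(skeleton)))
      stop("intensity image and skeleton dimensions differ", call. = FALSE)
    lattice <- filter_cells(label_cells(skeleton), min_area = min_area,
                            drop_border = drop_border)
  }
  if (!all(dim(image) == dim(lattice$labels)))
    stop("intensity image and lattice dimensions differ", call. = FALSE)
  res <- lapply(lattice$cells, function(id) {
    b <- trace_boundary(lattice, id)
    pr <- sample_intensity(b, image, thickness = thickness)
    out <- list()
    if ("pca" %in% methods)
      out$pca <- pca_polarity(pr, k = k, scale = scale, q = q)
    if ("fourier" %in% methods) out$fourier <- fourier_polarity(pr)
    if ("ratio" %in% methods)
      out$ratio <- ratio_polarity(pr, angle_step = angle_step,
                                  resample_step = resample_step)
    do.call(rbind, out)
  })
  df <- do.call(rbind, res)
  rownames(df) <- NULL
  df <- normalize_across_dataset(df)
  attr(df, "lattice") <- lattice
  df
}
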