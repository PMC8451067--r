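# Tissue-scale polarity statistics on axial (180-degree symmetric) data.
# Per-cell readouts are data.frames as produced by the polarity methods:
# columns cell_id, method, magnitude_raw (or a `magnitude` argument), and
# angle_deg.

get_mag <- function(readouts, use = c("norm", "raw")) {
  use <- match.arg(use)
  col <- if (use == "norm" && "magnitude_norm" %in% names(readouts))
    "magnitude_norm" else "magnitude_raw"
  readouts[[col]]
}

#' Average polarity magnitude
#'
#' Arithmetic mean of per-cell magnitudes, ignoring angles.
#'
#' @param readouts Per-cell readout data.frame (one method).
#' @param use Use `"norm"`alized (default, if present) or `"raw"` magnitudes.
#' @return Scalar mean magnitude.
#' @export
average_magnitude <- function(readouts, use = "norm") {
  p <- get_mag(readouts, use)
  if (length(p) == 0L) stop("no readouts", call. = FALSE)
  mean(p)
}

#' Vector average polarity
#'
#' Each cell is mapped to its axial polarity vector
#' (p cos 2theta, p sin 2theta); the components are averaged and read back:
#' p_vec is the norm of the mean vector and theta_vec = atan2(ybar, xbar)/2.
#' p_vec <= p_average always, with equality iff all angles are equal; the gap
#' measures polarity misalignment.
#'
#' @param readouts Per-cell readout data.frame (one method).
#' @param use Magnitude column choice, see [average_magnitude()].
#' @return Named vector c(p_vec =, theta_vec =) (theta_vec in (-90, 90] deg,
#'   NA when p_vec ~ 0).
#' @export
vector_average <- function(readouts, use = "norm") {
  p <- get_mag(readouts, use)
  ang <- readouts$angle_deg
  ok <- !is.na(ang)
  if (!any(ok)) stop("no defined polarity angles", call. = FALSE)
  p <- p[ok]; ang <- deg2rad(ang[ok])
  mx <- mean(p * cos(2 * ang))
  my <- mean(p * sin(2 * ang))
  pv <- sqrt(mx^2 + my^2)
  th <- if (pv < 1e-15) NA_real_ else wrap_axial(rad2deg(atan2(my, mx) / 2))
  c(p_vec = pv, theta_vec = th)
}

#' Coarse-grain vector polarity over spatial groups of cells
#'
#' Cells are partitioned into spatially contiguous groups of approximately
#' `group_size` cells (centroid-sorted into balanced columns, each split into
#' balanced runs of neighbors in y), and the vector average is computed per
#' group.
#'
#' @param readouts Per-cell readout data.frame (one method).
#' @param centroids data.frame with cell_id, x, y centroid columns (e.g. from
#'   [cell_centroids()]).
#' @param group_size Target number of cells per group.
#' @param use Magnitude column choice.
#' @return data.frame with group, n_cells, x, y (group centroid), p_vec,
#'   theta_vec, p_average.
#' @export
coarse_grain <- function(readouts, centroids, group_size, use = "norm") {
  if (group_size < 1) stop("group_size must be >= 1", call. = FALSE)
  df <- merge(readouts, centroids, by = "cell_id")
  n <- nrow(df)
  if (group_size > n) {
    warning("group_size exceeds the number of cells; using a single group")
    group_size <- n
  }
  ngroups <- max(1L, round(n / group_size))
  # tile the centroid cloud, more columns along its wider axis
  aspect <- (stats::sd(df$x) + 1e-9) / (stats::sd(df$y) + 1e-9)
  ncol_ <- min(max(1L, round(sqrt(ngroups * aspect))), ngroups)
  col_id <- ceiling(rank(df$x, ties.method = "first") / (n / ncol_))
  col_id <- pmin(col_id, ncol_)
  grp <- integer(n)
  gmax <- 0L
  for (cc in sort(unique(col_id))) {
    idx <- which(col_id == cc)
    k <- max(1L, round(length(idx) / group_size))
    sub <- ceiling(rank(df$y[idx], ties.method = "first") / (length(idx) / k))
    grp[idx] <- gmax + pmin(sub, k)
    gmax <- gmax + k
  }
  out <- lapply(sort(unique(grp)), function(g) {
    sel <- df[grp == g, , drop = FALSE]
    va <- vector_average(sel, use = use)
    data.frame(group = g, n_cells = nrow(sel),
               x = mean(sel$x), y = mean(sel$y),
               p_vec = va[["p_vec"]], theta_vec = va[["theta_vec"]],
               p_average = average_magnitude(sel, use = use))
  })
  do.call(rbind, out)
}

#' Neighbor vector polarity
#'
#' For each cell, the vector average over the cell and its immediate
#' neighbors; the tissue-level value is the mean of these local magnitudes.
#' An isolated cell forms a group by itself.
#'
#' @param readouts Per-cell readout data.frame (one method).
#' @param adjacency Named list mapping cell id to neighbor ids (e.g.
#'   `lattice$adjacency`).
#' @param use Magnitude column choice.
#' @return List with `cells` (data.frame cell_id, p_vec, theta_vec) and
#'   `tissue_mean`.
#' @export
neighbor_vector <- function(readouts, adjacency, use = "norm") {
  ids <- readouts$cell_id
  rows <- lapply(ids, function(id) {
    grp <- c(id, adjacency[[as.character(id)]])
    sel <- readouts[readouts$cell_id %in% grp, , drop = FALSE]
    va <- vector_average(sel, use = use)
    data.frame(cell_id = id, p_vec = va[["p_vec"]],
               theta_vec = va[["theta_vec"]])
  })
  cells <- do.call(rbind, rows)
  list(cells = cells, tissue_mean = mean(cells$p_vec))
}

#' Circular angle variance of polarity alignment
#'
#' Var_circ = 1 - |mean(exp(2 i theta))| on doubled angles (axial data):
#' 0 for perfect alignment, 1 for complete misalignment. Magnitudes are not
#' used.
#'
#' @param readouts Per-cell readout data.frame, or a numeric vector of angles
#'   in degrees.
#' @return Angle variance in [0, 1].
#' @export
angle_variance <- function(readouts) {
  ang <- if (is.data.frame(readouts)) readouts$angle_deg else readouts
  ang <- ang[!is.na(ang)]
  if (length(ang) == 0L) stop("no defined polarity angles", call. = FALSE)
  1 - Mod(mean(exp(2i * deg2rad(ang))))
}

#' Mean angle difference between two readouts
#'
#' Per cell, d = min(|a - b|, 180 - |a - b|) (axial wrap); returns mean(d)
#' over the common cells. 0 means complete agreement; the maximum possible
#' value is 90 degrees.
#'
#' @param readouts_a,readouts_b Per-cell readout data.frames over the same
#'   cell ids (e.g. two methods on the same image).
#' @return Mean axial angle difference in degrees.
#' @export
mean_angle_difference <- function(readouts_a, readouts_b) {
  a <- readouts_a[order(readouts_a$cell_id), ]
  b <- readouts_b[order(readouts_b$cell_id), ]
  if (!identical(as.integer(a$cell_id), as.integer(b$cell_id)))
    stop("cell id sets differ between the two readouts", call. = FALSE)
  ok <- !is.na(a$angle_deg) & !is.na(b$angle_deg)
  mean(axial_diff(a$angle_deg[ok], b$angle_deg[ok]))
}

#' Magnitude-weighted circular histogram
#'
#' Polarity axes are duplicated at theta and theta + 180 over [0, 360) and
#' binned; each bin's height is its frequency times the average magnitude of
#' its members, capturing angle and strength together.
#'
#' @param readouts Per-cell readout data.frame (one method).
#' @param n_bins Number of bins over the full circle (default 20).
#' @param use Magnitude column choice.
#' @return data.frame with bin_start, bin_end (degrees), count,
#'   mean_magnitude, height. Bins are closed-left, open-right, starting at 0.
#' @export
weighted_circular_histogram <- function(readouts, n_bins = 20, use = "norm") {
  p <- get_mag(readouts, use)
  ang <- readouts$angle_deg
  ok <- !is.na(ang)
  p <- p[ok]; ang <- ang[ok]
  if (length(p) == 0L) stop("no readouts", call. = FALSE)
  a <- c(ang %% 360, (ang + 180) %% 360)
  w <- c(p, p)
  width <- 360 / n_bins
  bin <- pmin(floor(a / width), n_bins - 1L)
  out <- data.frame(bin_start = (0:(n_bins - 1L)) * width,
                    bin_end = (1:n_bins) * width,
                    count = 0L, mean_magnitude = 0, height = 0)
  for (bidx in sort(unique(bin))) {
    sel <- bin == bidx
    out$count[bidx + 1L] <- sum(sel)
    out$mean_magnitude[bidx + 1L] <- mean(w[sel])
    out$height[bidx + 1L] <- sum(sel) * mean(w[sel])
  }
  out
}

#' Dataset-level magnitude normalization
#'
#' Maps raw magnitudes onto [0, 1] per method: p/max(p) for the PCA and
#' Fourier methods, (r - 1)/max(r - 1) for the Ratio method (whose raw
#' asymmetry starts at 1).
#'
#' @param readouts Long data.frame with columns method, magnitude_raw.
#' @return The data.frame with a magnitude_norm column added/replaced.
#' @export
normalize_across_dataset <- function(readouts) {
  stopifnot(is.data.frame(readouts), "magnitude_raw" %in% names(readouts))
  norm <- rep(NA_real_, nrow(readouts))
  for (m in unique(readouts$method)) {
    sel <- readouts$method == m
    v <- readouts$magnitude_raw[sel]
    if (m == "ratio") v <- v - 1
    top <- max(v)
    if (top <= 0) {
      warning("all raw magnitudes are zero for method '", m,
              "'; normalized magnitudes set to 0")
      norm[sel] <- 0
    } else {
      norm[sel] <- v / top
    }
  }
  readouts$magnitude_norm <- norm
  # keep column order stable: raw, norm, angle
  cols <- c("cell_id", "method", "magnitude_raw", "magnitude_norm", "angle_deg")
  readouts[, c(cols, setdiff(names(readouts), cols)), drop = FALSE]
}

#' Cell centroids of a lattice
#'
#' @param lattice A `cell_lattice`.
#' @return data.frame with cell_id, x, y (pixel coordinates).
#' @export
cell_centroids <- function(lattice) {
  stopifnot(inherits(lattice, "cell_lattice"))
  rows <- lapply(lattice$cells, function(id) {
    px <- which(lattice$labels == id, arr.ind = TRUE)
    data.frame(cell_id = id, x = mean(px[, 2L]), y = mean(px[, 1L]))
  })
  do.call(rbind, rows)
}

#' Tissue summary for one method's readouts
#'
#' @param readouts Per-cell readout data.frame (one method).
#' @param adjacency Optional adjacency list for the neighbor-vector measure.
#' @param use Magnitude column choice.
#' @return One-row data.frame: n_cells, p_average, p_vec, theta_vec,
#'   neighbor_p_vec (NA without adjacency), angle_variance.
#' @export
tissue_summary <- function(readouts, adjacency = NULL, use = "norm") {
  va <- vector_average(readouts, use = use)
  nv <- if (is.null(adjacency)) NA_real_ else
    neighbor_vector(readouts, adjacency, use = use)$tissue_mean
  data.frame(n_cells = nrow(readouts),
             p_average = average_magnitude(readouts, use = use),
             p_vec = va[["p_vec"]], theta_vec = va[["theta_vec"]],
             neighbor_p_vec = nv,
             angle_variance = angle_variance(readouts))
}
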