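# Fixtures and brute-force oracles shared across tests. All fixtures are
# built in code; nothing is read from disk.

# skeleton of an ncell_x x ncell_y grid of square cells, each `cell` px wide.
# Only interior walls are drawn, so outer cells touch the image frame (as in
# real segmentations, where frame cells are cut off by the field of view).
grid_skeleton <- function(ncx = 3, ncy = 3, cell = 8) {
  W <- ncx * (cell + 1) - 1
  H <- ncy * (cell + 1) - 1
  sk <- matrix(0L, H, W)
  if (ncy > 1) sk[seq(cell + 1, H - 1, by = cell + 1), ] <- 1L
  if (ncx > 1) sk[, seq(cell + 1, W - 1, by = cell + 1)] <- 1L
  sk
}

# brute-force 4-connected flood fill labeling of the complement of a skeleton
flood_labels <- function(sk) {
  H <- nrow(sk); W <- ncol(sk)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (sk[r0, c0] == 0L && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      queue <- matrix(c(r0, c0), 1L, 2L)
      lab[r0, c0] <- cur
      while (nrow(queue) > 0L) {
        p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          r <- p[1L] + d[1L]; cc <- p[2L] + d[2L]
          if (r >= 1L && r <= H && cc >= 1L && cc <= W &&
              sk[r, cc] == 0L && lab[r, cc] == 0L) {
            lab[r, cc] <- cur
            queue <- rbind(queue, c(r, cc))
          }
        }
      }
    }
  }
  lab
}

# brute-force edge-sharing adjacency: cells A,B are neighbors iff >= 2
# skeleton pixels have A and B among their 4-neighbors
bruteforce_adjacency <- function(labels, sk) {
  H <- nrow(sk); W <- ncol(sk)
  counts <- list()
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (sk[r, cc] != 1L) next
    labs <- integer(0)
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      r2 <- r + d[1L]; c2 <- cc + d[2L]
      if (r2 >= 1L && r2 <= H && c2 >= 1L && c2 <= W && labels[r2, c2] > 0L)
        labs <- c(labs, labels[r2, c2])
    }
    labs <- sort(unique(labs))
    if (length(labs) >= 2L) {
      prs <- utils::combn(labs, 2L)
      for (i in seq_len(ncol(prs))) {
        key <- paste(prs[1L, i], prs[2L, i], sep = "-")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- names(counts)[unlist(counts) >= 2L]
  do.call(rbind, lapply(keys, function(k)
    as.integer(strsplit(k, "-")[[1L]])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# boundary_profile built directly from points on a circle (unit testing the
# polarity math in isolation from segmentation)
circle_profile <- function(I_fun, n = 720, r = 50, cell_id = 1L) {
  th <- seq(-pi, pi, length.out = n + 1L)[-1L]
  x <- 100 + r * cos(th)
  y <- 100 - r * sin(th)  # row convention (y down)
  pr <- planarpolarity:::build_profile(x, y, I_fun(th), c(x = 100, y = 100),
                                       cell_id)
  pr
}

# exact ellipse sample points (y-up frame)
ellipse_points <- function(a, b, theta_deg, x0 = 0, y0 = 0, n = 100) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  th <- theta_deg * pi / 180
  x <- x0 + a * cos(t) * cos(th) - b * sin(t) * sin(th)
  y <- y0 + a * cos(t) * sin(th) + b * sin(t) * cos(th)
  list(x = x, y = y)
}

# standard single-cell fixture used in several places (small for speed)
std_cell <- function(...) synthetic_cell(perimeter = 300, ...)

first_lattice <- function(cell, drop_border = FALSE) {
  filter_cells(label_cells(cell$skeleton), drop_border = drop_border)
}

cell_profile <- function(cell, thickness = 3) {
  lat <- first_lattice(cell)
  b <- trace_boundary(lat, lat$cells[1L])
  sample_intensity(b, cell$intensity, thickness = thickness)
}

axial_diff_deg <- function(a, b) planarpolarity:::axial_diff(a, b)

# readout data.frame builder for tissue statistics tests
mk_readout <- function(p, ang, method = "pca") {
  data.frame(cell_id = seq_along(p), method = rep(method, length(p)),
             magnitude_raw = p, magnitude_norm = p, angle_deg = ang)
}
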