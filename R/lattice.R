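#' Validate and normalize a skeletonized segmentation mask
#'
#' A skeleton is a binary image in which 1-pixel-wide boundary lines delineate
#' cells, as produced by watershed segmentation tools. Any nonzero pixel is
#' treated as boundary.
#'
#' @param mask A numeric or logical matrix. Nonzero/TRUE pixels are boundary.
#' @return An integer 0/1 matrix of class `skeleton`.
#' @export
as_skeleton <- function(mask) {
  if (inherits(mask, "skeleton")) return(mask)
  if (!is.matrix(mask)) stop("skeleton mask must be a matrix", call. = FALSE)
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.numeric(mask) || any(!is.finite(mask)))
    stop("skeleton mask must be a finite numeric matrix", call. = FALSE)
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1))) {
    # tolerate 0/255-style binary images, reject genuinely non-binary input
    nz <- vals[vals != 0]
    if (length(nz) > 1L)
      stop("skeleton mask is not binary (found ", length(nz) + 1L,
           " distinct values)", call. = FALSE)
    mask <- (mask != 0) * 1L
  }
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  class(m) <- c("skeleton", class(m))
  m
}

#' Label cells in a skeletonized segmentation
#'
#' Non-boundary pixels are grouped into 4-connected regions; each region
#' becomes one cell. The complement region touching all four image sides is
#' treated as outer background, not as a cell. Cells touching at least one
#' image side are flagged as image-border cells (their geometry is incomplete
#' and they are usually removed by [filter_cells()]).
#'
#' @param skeleton A binary skeleton matrix (see [as_skeleton()]).
#' @return A `cell_lattice` object: list with `labels` (integer matrix, 0 =
#'   boundary/background), `cells` (ids), `area` (named pixel counts),
#'   `border` (named logical), `vertices` (data.frame of merged vertex
#'   positions), `adjacency` (named list), `skeleton`.
#' @export
label_cells <- function(skeleton) {
  sk <- as_skeleton(skeleton)
  comp <- (unclass(sk) == 0L) * 1
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(comp)))
  if (max(lab) == 0L)
    stop("empty lattice: the skeleton encloses no region", call. = FALSE)
  nr <- nrow(lab); nc <- ncol(lab)
  side <- list(top = lab[1L, ], bottom = lab[nr, ],
               left = lab[, 1L], right = lab[, nc])
  touches <- vapply(seq_len(max(lab)), function(id)
    sum(vapply(side, function(s) any(s == id), TRUE)), 0)
  bg <- which(touches == 4L)
  lab[lab %in% bg] <- 0L
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(ids) == 0L)
    stop("empty lattice: the skeleton encloses no region", call. = FALSE)
  # compress ids to 1..K, preserving raster order
  relab <- integer(max(ids)); relab[ids] <- seq_along(ids)
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab <- matrix(as.integer(lab), nr, nc)
  ids <- seq_along(ids)
  border <- vapply(ids, function(id) touches[which(relab == id)[1L]] > 0, TRUE)
  # recompute border flags against the compressed labels (cheap and exact)
  onframe <- unique(c(lab[1L, ], lab[nr, ], lab[, 1L], lab[, nc]))
  border <- ids %in% setdiff(onframe, 0L)
  area <- tabulate(lab[pos], nbins = length(ids))
  names(border) <- names(area) <- ids
  lat <- structure(list(labels = lab, cells = ids, area = area,
                        border = border, skeleton = unclass(sk),
                        vertices = NULL, adjacency = NULL),
                   class = "cell_lattice")
  lat$vertices <- detect_vertices(sk)
  lat$adjacency <- find_neighbors(lat)
  lat
}

#' Detect vertices of the boundary network
#'
#' The vertex degree k of a foreground pixel is the number of foreground
#' pixels in its 3x3 neighborhood excluding the pixel itself; pixels with
#' k >= 3 are vertex pixels (three or more boundary edges meet there).
#' Adjacent vertex pixels (including diagonal contact), which arise from
#' rasterization of a single biological vertex, are merged into one vertex at
#' their mean position.
#'
#' @param skeleton A binary skeleton matrix.
#' @return A data.frame with columns `x` (column), `y` (row): merged vertex
#'   positions (possibly sub-pixel).
#' @export
detect_vertices <- function(skeleton) {
  sk <- unclass(as_skeleton(skeleton))
  nb <- matrix(0L, nrow(sk), ncol(sk))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- nb + shift_mat(sk, dr, dc, 0L)
  }
  vpix <- which(sk == 1L & nb >= 3L, arr.ind = TRUE)
  if (nrow(vpix) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0)))
  # merge 8-connected clusters of vertex pixels (union by label propagation)
  n <- nrow(vpix)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      near <- which(abs(vpix[, 1L] - vpix[i, 1L]) <= 1L &
                    abs(vpix[, 2L] - vpix[i, 2L]) <= 1L)
      g <- min(grp[near])
      if (any(grp[near] != g)) { grp[near] <- g; changed <- TRUE }
    }
    if (!changed) break
  }
  xs <- tapply(vpix[, 2L], grp, mean)
  ys <- tapply(vpix[, 1L], grp, mean)
  data.frame(x = as.numeric(xs), y = as.numeric(ys))
}

#' Identify edge-sharing neighbor cells
#'
#' Two cells are neighbors iff they are seen on opposite/adjacent sides of at
#' least `min_shared` boundary pixels (default 2), which excludes cells in
#' vertex-only (diagonal) contact.
#'
#' @param lattice A `cell_lattice`.
#' @param min_shared Minimum number of boundary pixels that must witness the
#'   pair.
#' @return A named list mapping each cell id to an integer vector of
#'   neighbor ids; the relation is symmetric.
#' @export
find_neighbors <- function(lattice, min_shared = 2L) {
  stopifnot(inherits(lattice, "cell_lattice"))
  lab <- lattice$labels
  sk <- lattice$skeleton
  up <- shift_mat(lab, -1L, 0L); dn <- shift_mat(lab, 1L, 0L)
  lf <- shift_mat(lab, 0L, -1L); rt <- shift_mat(lab, 0L, 1L)
  bidx <- which(sk == 1L)
  nbhd <- cbind(up[bidx], dn[bidx], lf[bidx], rt[bidx])
  keys <- character(0)
  for (i in seq_along(bidx)) {
    labs <- unique(nbhd[i, ])
    labs <- labs[labs > 0L]
    if (length(labs) >= 2L) {
      labs <- sort(labs)
      pr <- utils::combn(labs, 2L)
      keys <- c(keys, paste(pr[1L, ], pr[2L, ], sep = "-"))
    }
  }
  adj <- stats::setNames(lapply(lattice$cells, function(i) integer(0)),
                         lattice$cells)
  if (length(keys)) {
    tab <- table(keys)
    good <- names(tab)[tab >= min_shared]
    for (kk in good) {
      ab <- as.integer(strsplit(kk, "-", fixed = TRUE)[[1L]])
      a <- as.character(ab[1L]); b <- as.character(ab[2L])
      adj[[a]] <- sort(c(adj[[a]], ab[2L]))
      adj[[b]] <- sort(c(adj[[b]], ab[1L]))
    }
  }
  adj
}

#' Remove image-border cells and small cells
#'
#' @param lattice A `cell_lattice`.
#' @param min_area Minimum cell area in pixels^2; cells below it are dropped.
#' @param drop_border Drop cells touching the image frame?
#' @return A filtered `cell_lattice`; surviving cells keep their ids.
#'   Adjacency is rebuilt, so neighbor links into removed cells disappear.
#' @export
filter_cells <- function(lattice, min_area = 1, drop_border = TRUE) {
  stopifnot(inherits(lattice, "cell_lattice"))
  if (!is.numeric(min_area) || min_area <= 0)
    stop("min_area must be a positive number of pixels", call. = FALSE)
  keep <- lattice$area >= min_area
  if (drop_border) keep <- keep & !lattice$border
  ids <- lattice$cells[keep]
  if (length(ids) == 0L) {
    warning("no cells survive filtering; returning an empty lattice")
  }
  lab <- lattice$labels
  lab[!(lab %in% ids)] <- 0L
  out <- lattice
  out$labels <- lab
  out$cells <- ids
  out$area <- lattice$area[keep]
  out$border <- lattice$border[keep]
  out$adjacency <- if (length(ids)) find_neighbors(out) else list()
  out
}

#' @export
print.cell_lattice <- function(x, ...) {
  cat("cell_lattice:", length(x$cells), "cells,",
      nrow(x$vertices), "vertices,",
      nrow(x$labels), "x", ncol(x$labels), "px\n")
  invisible(x)
}

#' Trace the ordered boundary of one cell
#'
#' The cell's boundary consists of the skeleton pixels 8-adjacent to its
#' 4-connected interior region. Pixels are ordered counter-clockwise (in the
#' mathematical y-up frame) by angle around the area centroid; epithelial
#' apical cells are star-shaped about their centroid, for which this ordering
#' equals the traversal order. The boundary is polygonized into edges at
#' lattice vertices when at least 3 lie on the loop, otherwise at geometric
#' corners found by closed-loop simplification.
#'
#' @param lattice A `cell_lattice`.
#' @param cell_id Cell id present in `lattice$cells`.
#' @param corner_tol Corner tolerance (px) for geometric corner detection.
#' @return A `cell_boundary`: list with ordered `x`, `y` (pixel coordinates),
#'   `theta` (centroid-relative angle, radians, y-up frame), `centroid`
#'   (x, y), `area` (px^2), `perimeter` (px, raster path with diagonal steps
#'   sqrt(2)), `vertex_idx` (loop positions of polygon corners), `vertex_pos`
#'   (corner coordinates, possibly sub-pixel), and `edges` (data.frame with
#'   chord and raster-arc length per vertex-to-vertex edge).
#' @export
trace_boundary <- function(lattice, cell_id, corner_tol = 1.5) {
  stopifnot(inherits(lattice, "cell_lattice"))
  cell_id <- as.integer(cell_id)
  if (!(cell_id %in% lattice$cells))
    stop("unknown cell id: ", cell_id, call. = FALSE)
  lab <- lattice$labels
  reg <- lab == cell_id
  px <- which(reg, arr.ind = TRUE)
  cy <- mean(px[, 1L]); cx <- mean(px[, 2L])
  dil <- reg
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    dil <- dil | shift_mat(reg * 1L, dr, dc, 0L) > 0L
  }
  bnd <- which(dil & lattice$skeleton == 1L, arr.ind = TRUE)
  if (nrow(bnd) < 4L) stop("degenerate cell boundary", call. = FALSE)
  y <- bnd[, 1L]; x <- bnd[, 2L]
  th <- atan2(-(y - cy), x - cx)
  th[th <= -pi] <- pi
  o <- order(th)
  x <- x[o]; y <- y[o]; th <- th[o]
  n <- length(x)
  steps <- sqrt(diff(c(x, x[1L]))^2 + diff(c(y, y[1L]))^2)
  # perimeter follows the cell region's own contour (diagonal steps sqrt(2)),
  # not the surrounding skeleton ring, which runs ~1 px outside
  oc <- EBImage::ocontour(reg * 1)[[1L]]
  perimeter <- sum(sqrt(rowSums((oc - oc[c(2:nrow(oc), 1L), ])^2)))

  # polygon corners: lattice vertices lying on this loop, else geometric
  vidx <- integer(0); vpos <- NULL
  if (!is.null(lattice$vertices) && nrow(lattice$vertices) >= 3L) {
    vx <- lattice$vertices$x; vy <- lattice$vertices$y
    near <- vapply(seq_along(vx), function(i) {
      d2 <- (x - vx[i])^2 + (y - vy[i])^2
      j <- which.min(d2)
      if (d2[j] <= 2.25) j else NA_integer_
    }, 1L)
    ok <- !is.na(near)
    if (sum(ok) >= 3L) {
      ord <- order(near[ok])
      vidx <- near[ok][ord]
      vpos <- cbind(x = vx[ok][ord], y = vy[ok][ord])
      dup <- duplicated(vidx)
      vidx <- vidx[!dup]; vpos <- vpos[!dup, , drop = FALSE]
    }
  }
  if (length(vidx) < 3L) {
    vidx <- sort(dp_corners(cbind(x, y), tol = corner_tol))
    vidx <- prune_corners(cbind(x, y), vidx, tol = corner_tol)
    vpos <- cbind(x = x[vidx], y = y[vidx])
  }
  m <- length(vidx)
  nxt <- c(2:m, 1L)
  chord <- sqrt((vpos[nxt, 1L] - vpos[, 1L])^2 + (vpos[nxt, 2L] - vpos[, 2L])^2)
  ring_len <- sum(steps)
  s <- c(0, cumsum(steps))[seq_len(n)]  # arc position of each loop pixel
  arc <- vapply(seq_len(m), function(i) {
    a <- s[vidx[i]]; b <- s[vidx[nxt[i]]]
    if (b >= a) b - a else ring_len - (a - b)
  }, 0)
  structure(list(cell_id = cell_id, x = x, y = y, theta = th,
                 centroid = c(x = cx, y = cy),
                 area = nrow(px), perimeter = perimeter,
                 vertex_idx = vidx, vertex_pos = vpos,
                 edges = data.frame(chord = chord, arc = arc)),
            class = "cell_boundary")
}

#' @export
print.cell_boundary <- function(x, ...) {
  cat("cell_boundary: cell", x$cell_id, "-", length(x$x), "px loop,",
      nrow(x$edges), "edges, area", x$area, "px^2\n")
  invisible(x)
}
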