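# Image and table I/O, per-image and batch drivers, overlays.

CSV_SCHEMA <- "# planarpolarity csv schema v1"

write_csv_versioned <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(CSV_SCHEMA, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_versioned <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Read a grayscale intensity image
#'
#' TIFFs are read at native integer values (8/12/16-bit); PNGs are scaled to
#' 0..255. Multi-channel images are reduced to their first channel.
#'
#' @param path Image path (.tif/.tiff/.png).
#' @return Numeric matrix of intensities (a.u.).
#' @export
read_intensity_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    png::readPNG(path) * 255
  } else stop("unsupported image format: .", ext, call. = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  storage.mode(img) <- "double"
  img
}

#' Read a skeletonized segmentation image
#'
#' Any nonzero pixel is boundary.
#'
#' @param path Image path (.tif/.tiff/.png).
#' @return A binary `skeleton` matrix.
#' @export
read_skeleton <- function(path) {
  as_skeleton((read_intensity_image(path) != 0) * 1L)
}

#' Write the labeled lattice as a 16-bit TIFF
#'
#' @param lattice A `cell_lattice`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_label_tiff <- function(lattice, path) {
  stopifnot(inherits(lattice, "cell_lattice"))
  tiff::writeTIFF(lattice$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write cell adjacency as CSV
#'
#' @param lattice A `cell_lattice`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_adjacency_csv <- function(lattice, path) {
  stopifnot(inherits(lattice, "cell_lattice"))
  rows <- lapply(names(lattice$adjacency), function(id) {
    nb <- lattice$adjacency[[id]]
    if (length(nb) == 0L) return(NULL)
    data.frame(cell_id = as.integer(id), neighbor_id = nb)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(cell_id = integer(0), neighbor_id = integer(0))
  write_csv_versioned(df, path)
}

# polarity-bar overlay: one axial bar per cell, length ~ magnitude_norm
overlay_png <- function(image, readouts, centroids, path, bar_scale = 0.8,
                        col = "#00d0ff") {
  H <- nrow(image); W <- ncol(image)
  df <- merge(readouts, centroids, by = "cell_id")
  diam <- sqrt(stats::median(attr(readouts, "cell_area") %||% 900))
  grDevices::png(path, width = W, height = H)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot(NA, xlim = c(0.5, W + 0.5), ylim = c(H + 0.5, 0.5),
                 xaxs = "i", yaxs = "i", axes = FALSE, xlab = "", ylab = "")
  graphics::rasterImage(grDevices::as.raster(image / max(image, 1)),
                        0.5, H + 0.5, W + 0.5, 0.5)
  ok <- !is.na(df$angle_deg)
  len <- bar_scale * df$magnitude_norm[ok] * diam / 2
  a <- deg2rad(df$angle_deg[ok])
  graphics::segments(df$x[ok] - len * cos(a), df$y[ok] + len * sin(a),
                     df$x[ok] + len * cos(a), df$y[ok] - len * sin(a),
                     col = col, lwd = 2)
  invisible(path)
}

# weighted circular histogram rendered as a rose plot
histogram_png <- function(hist_df, path, col = "#3060c0") {
  grDevices::png(path, width = 480, height = 480)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  r <- max(hist_df$height, 1e-9)
  graphics::plot(NA, xlim = c(-r, r), ylim = c(-r, r), asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = "magnitude-weighted polarity axes")
  for (i in seq_len(nrow(hist_df))) {
    if (hist_df$height[i] <= 0) next
    a <- deg2rad(seq(hist_df$bin_start[i], hist_df$bin_end[i], length.out = 12))
    graphics::polygon(c(0, hist_df$height[i] * cos(a)),
                      c(0, hist_df$height[i] * sin(a)),
                      col = col, border = "white")
  }
  invisible(path)
}

#' Compare polarity methods on the same cells
#'
#' For each method pair: squared Pearson correlation (r^2) of the normalized
#' magnitudes and the mean axial angle difference.
#'
#' @param readouts Long readout data.frame covering >= 2 methods.
#' @return data.frame with method_a, method_b, r_squared, mean_angle_diff_deg.
#' @export
compare_methods <- function(readouts) {
  ms <- unique(readouts$method)
  if (length(ms) < 2L) stop("need at least two methods", call. = FALSE)
  prs <- utils::combn(ms, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    a <- readouts[readouts$method == prs[1L, i], ]
    b <- readouts[readouts$method == prs[2L, i], ]
    a <- a[order(a$cell_id), ]; b <- b[order(b$cell_id), ]
    data.frame(method_a = prs[1L, i], method_b = prs[2L, i],
               r_squared = stats::cor(a$magnitude_norm, b$magnitude_norm)^2,
               mean_angle_diff_deg = mean_angle_difference(a, b))
  })
  do.call(rbind, rows)
}

#' Analyze one intensity/skeleton image pair
#'
#' Runs the full workflow and writes, under `out_dir`: the per-cell shape
#' table, one polarity table per method, a tissue summary (per ROI region if
#' masks are given), magnitude-weighted circular histogram tables and plots,
#' polarity-bar overlay images, the labeled-lattice TIFF, the adjacency
#' table, and a log of the configuration. All outputs are pure functions of
#' the inputs and configuration.
#'
#' @param intensity_path,skeleton_path Input image paths.
#' @param out_dir Output directory (created if needed).
#' @param methods Polarity methods to run.
#' @param min_area,drop_border,thickness,k,angle_step,resample_step Pipeline
#'   configuration (see [quantify_polarity()]).
#' @param roi_masks Optional named character vector of mask image paths;
#'   summaries are additionally computed over the cells whose centroids fall
#'   in each mask.
#' @param group_size Optional coarse-grain group size; writes a per-group
#'   table when given.
#' @return Invisibly, a list with `polarity`, `shape`, `summary` data.frames
#'   and the output paths.
#' @export
run_image <- function(intensity_path, skeleton_path, out_dir,
                      methods = c("pca", "fourier", "ratio"),
                      min_area = 1, drop_border = TRUE, thickness = 3,
                      k = 1000, angle_step = 1, resample_step = 1,
                      roi_masks = NULL, group_size = NULL) {
  img <- read_intensity_image(intensity_path)
  sk <- read_skeleton(skeleton_path)
  if (!all(dim(img) == dim(sk)))
    stop("intensity image and skeleton dimensions differ", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pol <- quantify_polarity(img, sk, methods = methods, min_area = min_area,
                           drop_border = drop_border, thickness = thickness,
                           k = k, angle_step = angle_step,
                           resample_step = resample_step)
  lat <- attr(pol, "lattice")
  shp <- shape_metrics(lat)
  cen <- cell_centroids(lat)
  paths <- c(shape = file.path(out_dir, "cells_shape.csv"))
  write_csv_versioned(shp, paths[["shape"]])
  sums <- list()
  for (m in unique(pol$method)) {
    sel <- pol[pol$method == m, ]
    pm <- file.path(out_dir, paste0("polarity_", m, ".csv"))
    write_csv_versioned(sel, pm)
    paths[paste0("polarity_", m)] <- pm
    hh <- weighted_circular_histogram(sel)
    hc <- file.path(out_dir, paste0("histogram_", m, ".csv"))
    write_csv_versioned(hh, hc)
    histogram_png(hh, file.path(out_dir, paste0("histogram_", m, ".png")))
    attr(sel, "cell_area") <- shp$area_px2
    overlay_png(img, sel, cen, file.path(out_dir, paste0("overlay_", m, ".png")))
    sm <- cbind(method = m, region = "all",
                tissue_summary(sel, lat$adjacency))
    sums[[length(sums) + 1L]] <- sm
    if (!is.null(group_size)) {
      cg <- coarse_grain(sel, cen, group_size)
      write_csv_versioned(cg, file.path(out_dir, paste0("coarse_grain_", m, ".csv")))
    }
  }
  if (!is.null(roi_masks)) {
    rn <- names(roi_masks) %||% paste0("roi", seq_along(roi_masks))
    for (ri in seq_along(roi_masks)) {
      mk <- read_intensity_image(roi_masks[[ri]]) != 0
      inroi <- cen$cell_id[mk[cbind(round(cen$y), round(cen$x))]]
      for (m in unique(pol$method)) {
        sel <- pol[pol$method == m & pol$cell_id %in% inroi, ]
        if (nrow(sel) == 0L) next
        sums[[length(sums) + 1L]] <-
          cbind(method = m, region = rn[ri], tissue_summary(sel, lat$adjacency))
      }
    }
  }
  summary_df <- do.call(rbind, sums)
  paths["summary"] <- file.path(out_dir, "tissue_summary.csv")
  write_csv_versioned(summary_df, paths[["summary"]])
  write_label_tiff(lat, file.path(out_dir, "labels.tif"))
  write_adjacency_csv(lat, file.path(out_dir, "adjacency.csv"))
  writeLines(c(paste("planarpolarity", as.character(utils::packageVersion("planarpolarity"))),
               paste("intensity:", intensity_path),
               paste("skeleton:", skeleton_path),
               paste("methods:", paste(methods, collapse = ",")),
               paste("min_area:", min_area), paste("drop_border:", drop_border),
               paste("thickness:", thickness), paste("k:", k),
               paste("angle_step:", angle_step),
               paste("resample_step:", resample_step)),
             file.path(out_dir, "log.txt"))
  invisible(list(polarity = pol, shape = shp, summary = summary_df,
                 paths = paths))
}

#' Batch-process a folder of image pairs
#'
#' Processes every `<stem>_intensity.(tif|tiff|png)` /
#' `<stem>_skeleton.(tif|tiff|png)` pair found in `folder`. Failures are
#' isolated per image and logged; the batch continues.
#'
#' @param folder Input folder.
#' @param out_dir Output root (one subdirectory per image plus a combined
#'   long-format polarity table across images).
#' @param ... Passed to [run_image()].
#' @return Invisibly, a list with `combined` (data.frame with image_id
#'   column), `failed` (named character vector of error messages) and
#'   `n_ok`/`n_failed`.
#' @export
run_batch <- function(folder, out_dir, ...) {
  ints <- list.files(folder, pattern = "_intensity\\.(tif|tiff|png)$",
                     full.names = TRUE)
  if (length(ints) == 0L)
    stop("no *_intensity.(tif|tiff|png) images found in ", folder, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  combined <- list(); failed <- character(0)
  for (ip in ints) {
    stem <- sub("_intensity\\.(tif|tiff|png)$", "", basename(ip))
    sks <- list.files(folder, pattern = paste0("^", stem, "_skeleton\\.(tif|tiff|png)$"),
                      full.names = TRUE)
    if (length(sks) == 0L) {
      failed[stem] <- "no matching skeleton image"
      next
    }
    res <- tryCatch(
      run_image(ip, sks[1L], file.path(out_dir, stem), ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[stem] <- conditionMessage(res)
    } else {
      combined[[stem]] <- cbind(image_id = stem, res$polarity)
    }
  }
  combined <- do.call(rbind, combined)
  rownames(combined) <- NULL
  if (!is.null(combined))
    write_csv_versioned(combined, file.path(out_dir, "combined_polarity.csv"))
  if (length(failed))
    writeLines(paste(names(failed), failed, sep = ": "),
               file.path(out_dir, "failures.log"))
  invisible(list(combined = combined, failed = failed,
                 n_ok = length(ints) - length(failed), n_failed = length(failed)))
}
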