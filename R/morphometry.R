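#' Blebbing classifier thresholds and outlier filters
#'
#' The standardized three-feature blebbing rule and the two per-cell
#' outlier filters. A cell is called "blebbing" when all three hold
#' (strict inequalities): mean boundary curvature above `curvature_min`,
#' nuclear/cytoplasmic adhesion-marker intensity ratio below
#' `intensity_ratio_max`, and cell/nucleus area ratio below
#' `area_ratio_max`. Independently, cells with a DNA-stain-positive area
#' below `nucleus_area_min` or a cell area above `cell_area_max` are
#' excluded from analysis as segmentation outliers.
#'
#' @param curvature_min curvature cutoff, 1/px (default 0.029).
#' @param intensity_ratio_max nuclear/cytoplasmic intensity ratio cutoff
#'   (default 1.15).
#' @param area_ratio_max cell/nucleus area ratio cutoff (default 4.5).
#' @param nucleus_area_min minimum nucleus area in px (default 1000).
#' @param cell_area_max maximum cell area in px (default 150000).
#' @return object of class `blebbing_thresholds`.
#' @export
blebbing_thresholds <- function(curvature_min = 0.029,
                                intensity_ratio_max = 1.15,
                                area_ratio_max = 4.5,
                                nucleus_area_min = 1000,
                                cell_area_max = 150000) {
  stopifnot(curvature_min > 0, intensity_ratio_max > 0, area_ratio_max > 0,
            nucleus_area_min > 0, cell_area_max > 0)
  structure(list(curvature_min = curvature_min,
                 intensity_ratio_max = intensity_ratio_max,
                 area_ratio_max = area_ratio_max,
                 nucleus_area_min = nucleus_area_min,
                 cell_area_max = cell_area_max),
            class = "blebbing_thresholds")
}

new_boundary_trace <- function(points, curvature = NULL) {
  structure(list(points = points, curvature = curvature),
            class = "boundary_trace")
}

#' @export
print.boundary_trace <- function(x, ...) {
  cat(sprintf("Boundary trace: %d points%s\n", nrow(x$points),
              if (is.null(x$curvature)) "" else
                sprintf(", mean curvature %.4f 1/px", mean(x$curvature))))
  invisible(x)
}

#' Trace the outer boundary of a cell mask
#'
#' Extracts an ordered, closed, counter-clockwise sub-pixel contour of a
#' single 8-connected mask at the 0.5 iso-level. The mask is lightly
#' smoothed (Gaussian, `smooth_sigma`) before contouring so the trace
#' interpolates between pixels instead of following the raw pixel
#' staircase; this keeps perimeters of smooth shapes accurate to about 1%.
#'
#' @param cell_mask logical matrix: one 8-connected component, area >= 20 px,
#'   without holes.
#' @param smooth_sigma Gaussian sigma (px) of the pre-contour smoothing.
#' @return a `boundary_trace` (curvature unset) with (row, col) points;
#'   the closing edge from last to first point is implicit.
#' @export
trace_boundary <- function(cell_mask, smooth_sigma = 1) {
  cell_mask <- as_mask(cell_mask)
  area <- sum(cell_mask)
  if (area < 20) stop("mask area below 20 px (degenerate)")
  lab <- label_components(cell_mask, connectivity = 8)
  if (max(lab) != 1L) stop("mask must be a single connected component")
  nr <- nrow(cell_mask); nc <- ncol(cell_mask)
  pad <- matrix(0, nr + 4L, nc + 4L)
  pad[3:(nr + 2L), 3:(nc + 2L)] <- cell_mask
  z <- if (smooth_sigma > 0) as.matrix(EBImage::gblur(pad, sigma = smooth_sigma)) else pad
  cl <- grDevices::contourLines(seq_len(nr + 4L), seq_len(nc + 4L), z, levels = 0.5)
  if (length(cl) == 0L) stop("mask too thin to contour (degenerate)")
  if (length(cl) > 1L) stop("mask has holes or multiple boundary loops")
  pts <- cbind(row = cl[[1]]$x, col = cl[[1]]$y) - 2
  n <- nrow(pts)
  if (all(pts[1, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
  dup <- c(FALSE, rowSums(abs(diff(pts))) < 1e-12)
  pts <- pts[!dup, , drop = FALSE]
  if (nrow(pts) < 8) stop("mask too small to trace (fewer than 8 boundary points)")
  # enforce counter-clockwise orientation (positive signed area with
  # x = col, y = row)
  x <- pts[, 2]; y <- pts[, 1]
  sa <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  if (sa < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  new_boundary_trace(pts)
}

#' Resample a closed boundary to uniform arc-length spacing
#'
#' Linear interpolation along the closed polyline at a fixed spacing.
#' Curvature estimation from circumscribed circles is sensitive to the
#' spacing of the supporting points relative to the sub-pixel jitter of
#' the trace; resampling to a uniform ~2 px spacing makes the downstream
#' smoothing window and triplet step geometrically meaningful.
#'
#' @param trace a `boundary_trace`.
#' @param spacing target arc-length spacing in px.
#' @return a resampled `boundary_trace` (curvature unset).
#' @export
resample_boundary <- function(trace, spacing = 2) {
  stopifnot(inherits(trace, "boundary_trace"), spacing > 0)
  pts <- trace$points
  n <- nrow(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  L <- s[n + 1]
  t_out <- seq(0, L, by = spacing)
  t_out <- t_out[t_out < L - 1e-9]
  if (length(t_out) < 8) stop("boundary too short to resample at this spacing")
  out <- cbind(row = stats::approx(s, closed[, 1], xout = t_out)$y,
               col = stats::approx(s, closed[, 2], xout = t_out)$y)
  new_boundary_trace(out)
}

#' Smooth a closed boundary with a circular Savitzky-Golay filter
#'
#' The row and column coordinate sequences are filtered independently
#' with a Savitzky-Golay filter under circular (wrap-around) padding, so
#' closure is preserved and there are no endpoint transients. Points
#' lying exactly on a polynomial of degree <= `polyorder` are reproduced
#' exactly.
#'
#' @param trace a `boundary_trace`.
#' @param window odd filter window length, `polyorder < window < n points`.
#' @param polyorder polynomial order.
#' @return smoothed `boundary_trace` (curvature unset).
#' @export
smooth_boundary <- function(trace, window = 9, polyorder = 3) {
  stopifnot(inherits(trace, "boundary_trace"))
  n <- nrow(trace$points)
  if (window %% 2 != 1) stop("`window` must be odd")
  if (window <= polyorder) stop("`window` must exceed `polyorder`")
  if (window >= n) stop("`window` must be smaller than the number of boundary points")
  sm <- apply(trace$points, 2, function(y) {
    yp <- c(y[(n - window + 1):n], y, y[1:window])
    signal::sgolayfilt(yp, p = polyorder, n = window)[(window + 1):(window + n)]
  })
  colnames(sm) <- c("row", "col")
  new_boundary_trace(sm)
}

#' Instantaneous curvature from three boundary points
#'
#' Curvature at a point defined as `1 / r`, with `r` the circumradius of
#' the triangle through the point and two neighbours: `kappa = 4A / (abc)`
#' with side lengths `a, b, c` and triangle area `A`. Collinear points
#' give 0; the value is unsigned.
#'
#' @param p_a,p_b,p_c numeric length-2 points (row, col); `p_b` is the
#'   point at which curvature is evaluated.
#' @return curvature in 1/px.
#' @export
point_curvature <- function(p_a, p_b, p_c) {
  ab <- p_a - p_b; cb <- p_c - p_b; ac <- p_a - p_c
  la <- sqrt(sum(cb^2)); lb <- sqrt(sum(ac^2)); lc <- sqrt(sum(ab^2))
  if (la < 1e-12 || lb < 1e-12 || lc < 1e-12) stop("coincident points")
  A <- abs(ab[1] * cb[2] - ab[2] * cb[1]) / 2
  4 * A / (la * lb * lc)
}

# Vectorized per-point curvature over a closed trace with circular
# indexing and triplet spacing `step`.
trace_curvatures <- function(pts, step = 2L) {
  n <- nrow(pts)
  i <- seq_len(n)
  a <- pts[((i - 1L - step) %% n) + 1L, , drop = FALSE]
  b <- pts
  c_ <- pts[((i - 1L + step) %% n) + 1L, , drop = FALSE]
  A <- abs((a[, 1] - b[, 1]) * (c_[, 2] - b[, 2]) -
           (a[, 2] - b[, 2]) * (c_[, 1] - b[, 1])) / 2
  la <- sqrt(rowSums((b - c_)^2))
  lb <- sqrt(rowSums((a - c_)^2))
  lc <- sqrt(rowSums((a - b)^2))
  k <- 4 * A / (la * lb * lc)
  k[!is.finite(k)] <- 0
  k
}

#' Per-point boundary curvature
#'
#' Fills the `curvature` field of a trace with the circumradius curvature
#' of every point, using neighbours `step` samples away (circular
#' indexing).
#'
#' @param trace a (smoothed) `boundary_trace`.
#' @param step triplet half-spacing in samples, `1 <= step < n/3`.
#' @return the trace with `curvature` set (all values >= 0).
#' @export
boundary_curvature <- function(trace, step = 2L) {
  stopifnot(inherits(trace, "boundary_trace"))
  n <- nrow(trace$points)
  if (step < 1 || step >= n / 3) stop("`step` must satisfy 1 <= step < n/3")
  trace$curvature <- trace_curvatures(trace$points, as.integer(step))
  trace
}

#' Mean boundary curvature of a cell
#'
#' Mean over all boundary points of the circumradius curvature through
#' each point and its neighbours `step` samples away.
#'
#' @inheritParams boundary_curvature
#' @return mean curvature in 1/px.
#' @export
mean_cell_curvature <- function(trace, step = 2L) {
  mean(boundary_curvature(trace, step)$curvature)
}

#' Nuclear to cytoplasmic intensity ratio
#'
#' Mean adhesion-marker intensity over the nucleus divided by the mean
#' over the cytoplasm (cell minus nucleus). The nucleus mask is
#' intersected with the cell mask.
#'
#' @param adhesion_channel numeric matrix.
#' @param nucleus_mask,cell_mask logical matrices.
#' @return dimensionless ratio.
#' @export
intensity_ratio <- function(adhesion_channel, nucleus_mask, cell_mask) {
  stop_if_not_image(adhesion_channel)
  nucleus_mask <- as_mask(nucleus_mask) & as_mask(cell_mask)
  cyto <- as_mask(cell_mask) & !nucleus_mask
  if (!any(nucleus_mask)) stop("empty nucleus mask")
  if (!any(cyto)) stop("empty cytoplasm (cell minus nucleus)")
  mean(adhesion_channel[nucleus_mask]) / mean(adhesion_channel[cyto])
}

#' Classify a cell as blebbing or not
#'
#' A cell is blebbing when all three standardized criteria hold (strict
#' inequalities): `mean_curvature > curvature_min`,
#' `intensity_ratio < intensity_ratio_max`, and
#' `area_ratio < area_ratio_max`.
#'
#' @param features a list or one-row data frame with `mean_curvature`,
#'   `intensity_ratio`, `area_ratio` (vectors are accepted and classified
#'   elementwise).
#' @param thresholds a [blebbing_thresholds()] object.
#' @return logical flag (vectorized over rows).
#' @export
classify_blebbing <- function(features, thresholds = blebbing_thresholds()) {
  stopifnot(inherits(thresholds, "blebbing_thresholds"))
  features$mean_curvature > thresholds$curvature_min &
    features$intensity_ratio < thresholds$intensity_ratio_max &
    features$area_ratio < thresholds$area_ratio_max
}

#' Apply the per-cell outlier filters
#'
#' Removes cells whose nucleus (DNA-stain-positive) area is below
#' `nucleus_area_min` or whose cell area exceeds `cell_area_max`. Excluded
#' records are annotated with the triggering rule and returned in the
#' `excluded` attribute; the `excluded_by` column of the returned records
#' is empty for all retained cells.
#'
#' @param records data frame of per-cell features with `nucleus_area` and
#'   `cell_area` columns.
#' @param thresholds a [blebbing_thresholds()] object.
#' @return the retained records (with an empty `excluded_by` column);
#'   attribute `excluded` holds the removed records with their rule names
#'   (`"nucleus_area_min"`, `"cell_area_max"`, comma-separated when both).
#' @export
apply_cell_filters <- function(records, thresholds = blebbing_thresholds()) {
  stopifnot(is.data.frame(records))
  rule <- character(nrow(records))
  small <- records$nucleus_area < thresholds$nucleus_area_min
  big <- records$cell_area > thresholds$cell_area_max
  rule[small] <- "nucleus_area_min"
  rule[big] <- ifelse(nchar(rule[big]) > 0,
                      paste0(rule[big], ",cell_area_max"), "cell_area_max")
  records$excluded_by <- rule
  retained <- records[rule == "", , drop = FALSE]
  excluded <- records[rule != "", , drop = FALSE]
  rownames(retained) <- NULL
  rownames(excluded) <- NULL
  attr(retained, "excluded") <- excluded
  retained
}
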