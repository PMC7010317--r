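# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite pixels", arg), call. = FALSE)
  invisible(x)
}

as_mask <- function(x) {
  if (is.logical(x)) return(x)
  matrix(as.vector(x) > 0, nrow(x), ncol(x))
}

#' Label connected components
#'
#' Connected-component labelling of a binary mask. 8-connectivity (the
#' convention used throughout the pipeline) is obtained by merging
#' 4-connected components that touch diagonally.
#'
#' @param bw logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(bw, connectivity = 8) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- matrix(as.numeric(as_mask(bw)), nrow(bw), ncol(bw))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(round(lab)), nrow(m), ncol(m))
  n <- max(lab)
  if (n == 0L || connectivity == 4L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(n)
    find_root <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (r in seq_len(nrow(pairs))) {
      a <- find_root(pairs[r, 1]); b <- find_root(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(n), find_root, integer(1))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  lab
}

# Sizes of labelled components (index = label).
component_sizes <- function(lab) {
  mx <- max(lab)
  if (mx == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = mx)
}

# Remove components below a minimum area and relabel 1..K preserving order.
drop_small_components <- function(lab, min_area) {
  sz <- component_sizes(lab)
  if (!length(sz)) return(lab)
  keep <- which(sz >= min_area)
  relab <- integer(length(sz))
  relab[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Apply an ordered list of morphology ops, each list(op=, size=).
apply_morphology <- function(bw, ops) {
  img <- matrix(as.numeric(as_mask(bw)), nrow(bw), ncol(bw))
  for (o in ops) {
    op <- o$op
    if (op == "fill_holes" || op == "fill") {
      img <- as.matrix(EBImage::fillHull(img))
      next
    }
    brush <- EBImage::makeBrush(o$size, shape = "disc")
    img <- switch(op,
      open  = as.matrix(EBImage::opening(img, brush)),
      close = as.matrix(EBImage::closing(img, brush)),
      erode = as.matrix(EBImage::erode(img, brush)),
      dilate = as.matrix(EBImage::dilate(img, brush)),
      stop(sprintf("unknown morphology op '%s'", op)))
  }
  matrix(as.vector(img) > 0.5, nrow(bw), ncol(bw))
}

#' Intersection over union of two masks
#'
#' @param a,b logical matrices of the same dimension.
#' @return IoU in \[0, 1\]; 0 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

# Bounding box of a mask with padding, clipped to the image.
mask_bbox <- function(mask, pad = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  list(
    r1 = max(1L, min(idx[, 1]) - pad), r2 = min(nrow(mask), max(idx[, 1]) + pad),
    c1 = max(1L, min(idx[, 2]) - pad), c2 = min(ncol(mask), max(idx[, 2]) + pad))
}
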