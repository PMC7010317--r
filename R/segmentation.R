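#' Segmentation configuration
#'
#' Settings for cell-body segmentation from the cytoplasm channel and for
#' nucleus segmentation via the PST.
#'
#' @param smooth_sigma Gaussian pre-smoothing sigma (px) applied to the
#'   cytoplasm channel before thresholding.
#' @param dim_fraction fraction of dimmest pixels treated as background
#'   (default 0.20, the dimmest 20%).
#' @param threshold_factor multiplier on the mean intensity of the dimmest
#'   pixels giving the foreground threshold.
#' @param reseg_factor multiplier (> 1) on the original threshold used to
#'   re-segment regions that contain multiple nuclei.
#' @param max_grow_iters cap on region-growing iterations.
#' @param border_policy `"drop"` removes cells touching the image border,
#'   `"keep"` retains them.
#' @param nuclei_preset [pst_params()] used for nucleus segmentation.
#' @return object of class `seg_config`.
#' @export
seg_config <- function(smooth_sigma = 2, dim_fraction = 0.20,
                       threshold_factor = 2.0, reseg_factor = 1.5,
                       max_grow_iters = 1000L,
                       border_policy = c("drop", "keep"),
                       nuclei_preset = pst_preset("nuclei")) {
  border_policy <- match.arg(border_policy)
  stopifnot(smooth_sigma >= 0, dim_fraction > 0, dim_fraction < 1,
            threshold_factor > 0, reseg_factor > 1, max_grow_iters >= 1,
            inherits(nuclei_preset, "pst_params"))
  structure(list(smooth_sigma = smooth_sigma, dim_fraction = dim_fraction,
                 threshold_factor = threshold_factor, reseg_factor = reseg_factor,
                 max_grow_iters = as.integer(max_grow_iters),
                 border_policy = border_policy, nuclei_preset = nuclei_preset),
            class = "seg_config")
}

#' Background-referenced intensity threshold
#'
#' Threshold based on the average intensity of the dimmest fraction of
#' pixels (by default the dimmest 20%, taken to represent background):
#' `threshold_factor * mean` of the `floor(dim_fraction * N)` dimmest
#' pixel values. Sorting is stable, so value ties are broken by pixel
#' order and the result is deterministic.
#'
#' @param image numeric matrix.
#' @param dim_fraction fraction in (0, 1).
#' @param threshold_factor positive multiplier.
#' @return threshold intensity (scalar).
#' @export
background_threshold <- function(image, dim_fraction = 0.20, threshold_factor = 2.0) {
  stop_if_not_image(image)
  stopifnot(dim_fraction > 0, dim_fraction < 1, threshold_factor > 0)
  k <- floor(dim_fraction * length(image))
  if (k < 1) stop("dim_fraction selects zero pixels")
  v <- sort(as.vector(image), method = "radix")[seq_len(k)]
  threshold_factor * mean(v)
}

#' Segment nuclei from the DNA counterstain channel
#'
#' Delegates to [pst_segment()] with the nuclei preset (hole filling and a
#' size filter are part of the preset's cleanup), yielding one label per
#' nucleus.
#'
#' @param nuclei_channel numeric matrix.
#' @param config a [seg_config()].
#' @return integer label map.
#' @export
segment_nuclei <- function(nuclei_channel, config = seg_config()) {
  pst_segment(nuclei_channel, config$nuclei_preset)
}

# Assign each nucleus to the component holding the majority (>50%) of its
# area; returns integer vector component-id per nucleus label (0 = none).
majority_component <- function(nuclei_labels, comp_labels) {
  n_nuc <- max(nuclei_labels)
  out <- integer(n_nuc)
  for (k in seq_len(n_nuc)) {
    px <- comp_labels[nuclei_labels == k]
    if (!length(px)) next
    tab <- table(px)
    top <- as.integer(names(tab)[which.max(tab)])
    if (tab[which.max(tab)] > length(px) / 2) out[k] <- top
  }
  out
}

#' Segment cell bodies from the cytoplasm channel
#'
#' Gaussian pre-smoothing, thresholding at [background_threshold()],
#' 8-connected component labelling, then the nucleus-count rule: regions
#' containing two or more nuclei (majority of the nucleus area inside the
#' region) are split with [resolve_undersegmentation()]; regions with zero
#' or, after splitting, multiple nuclei are removed. Border cells are
#' dropped under the default policy.
#'
#' @param cytoplasm_channel numeric matrix.
#' @param nuclei_labels nucleus label map co-registered with the channel.
#' @param config a [seg_config()].
#' @return integer cell label map with attributes `nucleus_of` (integer
#'   vector mapping cell label to its nucleus label) and `threshold` (the
#'   realized background threshold).
#' @export
segment_cell_bodies <- function(cytoplasm_channel, nuclei_labels,
                                config = seg_config()) {
  stop_if_not_image(cytoplasm_channel)
  stopifnot(all(dim(cytoplasm_channel) == dim(nuclei_labels)))
  sm <- if (config$smooth_sigma > 0)
    as.matrix(EBImage::gblur(cytoplasm_channel, sigma = config$smooth_sigma))
  else cytoplasm_channel
  thr <- background_threshold(sm, config$dim_fraction, config$threshold_factor)
  comp <- label_components(sm > thr, connectivity = 8)

  nuc_comp <- majority_component(nuclei_labels, comp)
  out <- matrix(0L, nrow(comp), ncol(comp))
  nucleus_of <- integer(0)
  next_label <- 0L
  for (cid in seq_len(max(comp))) {
    nucs <- which(nuc_comp == cid)
    if (length(nucs) == 0L) next
    if (length(nucs) == 1L) {
      next_label <- next_label + 1L
      out[comp == cid] <- next_label
      nucleus_of[next_label] <- nucs
    } else {
      region <- comp == cid
      sub <- resolve_undersegmentation(region, nuclei_labels, sm, thr, config,
                                       nuclei = nucs)
      sub_nuc <- attr(sub, "nucleus_of")
      for (s in seq_len(max(sub))) {
        next_label <- next_label + 1L
        out[sub == s] <- next_label
        nucleus_of[next_label] <- sub_nuc[s]
      }
    }
  }

  if (config$border_policy == "drop" && next_label > 0L) {
    nr <- nrow(out); nc <- ncol(out)
    border <- unique(c(out[1, ], out[nr, ], out[, 1], out[, nc]))
    border <- border[border > 0L]
    if (length(border)) {
      keep <- setdiff(seq_len(next_label), border)
      relab <- integer(next_label)
      relab[keep] <- seq_along(keep)
      out[out > 0L] <- relab[out[out > 0L]]
      nucleus_of <- nucleus_of[keep]
    }
  }
  attr(out, "nucleus_of") <- nucleus_of
  attr(out, "threshold") <- thr
  out
}

#' Split an under-segmented region using its nuclei as seeds
#'
#' Re-thresholds the region at `reseg_factor` times the original
#' threshold; each high-threshold component is assigned to the nucleus
#' holding the majority of the overlap, and the resulting seeds are grown
#' by synchronous (breadth-first) geodesic dilation restricted to the
#' region until it is partitioned. Pixels reached by one frontier first
#' keep that label; pixels contested within the same iteration go to the
#' seed with the nearer nucleus centroid (Euclidean), remaining ties to
#' the lower label index. If the higher threshold yields seeds for fewer
#' nuclei than the region contains, the nucleus masks themselves are used
#' as seeds (with a message).
#'
#' @param region_mask logical matrix, one connected region with >= 2 nuclei.
#' @param nuclei_labels nucleus label map.
#' @param intensity_image the (smoothed) cytoplasm channel.
#' @param base_threshold the original foreground threshold.
#' @param config a [seg_config()].
#' @param nuclei integer vector of nucleus labels inside the region
#'   (computed from the majority rule when omitted).
#' @return integer label map over the region (labels 1..n in nucleus
#'   order) with attribute `nucleus_of`; labels partition `region_mask`.
#' @export
resolve_undersegmentation <- function(region_mask, nuclei_labels,
                                      intensity_image, base_threshold,
                                      config = seg_config(), nuclei = NULL) {
  region_mask <- as_mask(region_mask)
  if (is.null(nuclei)) {
    comp <- matrix(as.integer(region_mask), nrow(region_mask), ncol(region_mask))
    nuclei <- which(majority_component(nuclei_labels, comp) == 1L)
  }
  if (length(nuclei) < 2L) stop("region must contain at least 2 nuclei")

  # crop to the region bounding box for speed
  bb <- mask_bbox(region_mask, pad = 1L)
  reg <- region_mask[bb$r1:bb$r2, bb$c1:bb$c2]
  nl <- nuclei_labels[bb$r1:bb$r2, bb$c1:bb$c2]
  img <- intensity_image[bb$r1:bb$r2, bb$c1:bb$c2]
  K <- length(nuclei)

  centroids <- t(vapply(nuclei, function(k) {
    idx <- which(nl == k, arr.ind = TRUE)
    colMeans(idx)
  }, numeric(2)))

  hi <- img > base_threshold * config$reseg_factor & reg
  seeds_lab <- label_components(hi, connectivity = 8)
  seed_of_nuc <- rep(0L, K)
  L <- matrix(0L, nrow(reg), ncol(reg))
  if (max(seeds_lab) > 0L) {
    # majority-overlap assignment of high-threshold components to nuclei
    for (s in seq_len(max(seeds_lab))) {
      px <- nl[seeds_lab == s]
      px <- px[px %in% nuclei]
      if (!length(px)) next
      tab <- table(px)
      nk <- match(as.integer(names(tab)[which.max(tab)]), nuclei)
      L[seeds_lab == s] <- nk
      seed_of_nuc[nk] <- 1L
    }
  }
  if (any(seed_of_nuc == 0L)) {
    message("higher threshold yielded fewer seeds than nuclei; using nucleus masks as seeds")
    L <- matrix(0L, nrow(reg), ncol(reg))
    for (k in seq_len(K)) L[nl == nuclei[k] & reg] <- k
  }
  L[!reg] <- 0L

  kern <- matrix(1, 3, 3)
  iter <- 0L
  while (any(reg & L == 0L) && iter < config$max_grow_iters) {
    iter <- iter + 1L
    unl <- reg & L == 0L
    claims <- vector("list", K)
    total <- matrix(0L, nrow(reg), ncol(reg))
    for (k in seq_len(K)) {
      g <- as.matrix(EBImage::dilate(matrix(as.numeric(L == k), nrow(reg), ncol(reg)),
                                     kern)) > 0.5
      g <- g & unl
      claims[[k]] <- g
      total <- total + g
    }
    if (!any(total > 0L)) break  # unreachable pixels remain
    for (k in seq_len(K)) {
      solo <- claims[[k]] & total == 1L
      L[solo] <- k
    }
    contested <- which(total > 1L)
    if (length(contested)) {
      idx <- arrayInd(contested, dim(reg))
      best <- rep(0L, length(contested))
      bestd <- rep(Inf, length(contested))
      for (k in seq_len(K)) {
        ck <- claims[[k]][contested]
        d <- (idx[, 1] - centroids[k, 1])^2 + (idx[, 2] - centroids[k, 2])^2
        upd <- ck & (d < bestd - 1e-9)
        best[upd] <- k
        bestd[upd] <- d[upd]
      }
      L[contested] <- best
    }
  }

  out <- matrix(0L, nrow(region_mask), ncol(region_mask))
  out[bb$r1:bb$r2, bb$c1:bb$c2] <- L
  out[!region_mask] <- 0L
  attr(out, "nucleus_of") <- nuclei
  out
}
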