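#' Extract per-cell morphometric features
#'
#' For every labelled cell: areas, mean smoothed-boundary curvature,
#' nuclear/cytoplasmic adhesion-marker intensity ratio, cell/nucleus area
#' ratio, and the blebbing call. The boundary chain is: trace at the 0.5
#' iso-level, resample to uniform arc spacing, circular Savitzky-Golay
#' smoothing, circumradius curvature.
#'
#' @param channels list with `cytoplasm`, `nuclei`, `adhesion` matrices
#'   (a `synthetic_scene$channels` works directly).
#' @param cell_labels cell label map from [segment_cell_bodies()] (its
#'   `nucleus_of` attribute links cells to nuclei).
#' @param nucleus_labels nucleus label map.
#' @param thresholds a [blebbing_thresholds()].
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param spacing boundary resampling spacing (px).
#' @param step curvature triplet half-spacing (samples).
#' @return data frame, one row per cell: `cell_id`, `nucleus_id`,
#'   `cell_area`, `nucleus_area`, `mean_curvature`, `intensity_ratio`,
#'   `area_ratio`, `blebbing`. Cells whose boundary cannot be traced get
#'   NA features and `blebbing = NA`.
#' @export
extract_cell_features <- function(channels, cell_labels, nucleus_labels,
                                  thresholds = blebbing_thresholds(),
                                  sg_window = 9, sg_polyorder = 3,
                                  spacing = 2, step = 2L) {
  n_cells <- max(cell_labels, 0L)
  nucleus_of <- attr(cell_labels, "nucleus_of") %||% seq_len(n_cells)
  rows <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    cmask <- cell_labels == k
    cmask_f <- apply_morphology(cmask, list(list(op = "fill_holes")))
    nmask <- nucleus_labels == nucleus_of[k]
    cell_area <- sum(cmask_f)
    nucleus_area <- sum(nmask)
    kappa <- NA_real_; iratio <- NA_real_
    feat_ok <- nucleus_area > 0
    if (feat_ok) {
      kappa <- tryCatch({
        bb <- mask_bbox(cmask_f, pad = 4L)
        tr <- trace_boundary(cmask_f[bb$r1:bb$r2, bb$c1:bb$c2])
        tr <- resample_boundary(tr, spacing)
        tr <- smooth_boundary(tr, sg_window, sg_polyorder)
        mean_cell_curvature(tr, step)
      }, error = function(e) NA_real_)
      iratio <- tryCatch(
        intensity_ratio(channels$adhesion, nmask, cmask_f),
        error = function(e) NA_real_)
    }
    aratio <- if (nucleus_area > 0) cell_area / nucleus_area else NA_real_
    rows[[k]] <- data.frame(
      cell_id = k, nucleus_id = nucleus_of[k],
      cell_area = cell_area, nucleus_area = nucleus_area,
      mean_curvature = kappa, intensity_ratio = iratio,
      area_ratio = aratio, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(0), nucleus_id = integer(0),
                      cell_area = integer(0), nucleus_area = integer(0),
                      mean_curvature = numeric(0), intensity_ratio = numeric(0),
                      area_ratio = numeric(0))
  }
  out$blebbing <- classify_blebbing(out, thresholds)
  out
}

#' Quantify one field of view end to end
#'
#' Runs the full per-scene pipeline: nucleus segmentation (PST), cell-body
#' segmentation with nuclei-seeded splitting, per-cell morphometry and
#' blebbing classification, focal-adhesion segmentation/filtering/counting.
#' Dataset-wide steps (outlier filters, FA count cutoffs, statistics) are
#' applied afterwards on the pooled per-cell records.
#'
#' @param channels list with `cytoplasm`, `nuclei`, `adhesion` matrices,
#'   or a `synthetic_scene`.
#' @param config a [seg_config()].
#' @param fa_cfg a [fa_config()].
#' @param thresholds a [blebbing_thresholds()].
#' @return list of class `scene_quantification`: `features` (per-cell data
#'   frame incl. `fa_count`), `cell_labels`, `nucleus_labels`, `fa_labels`.
#' @export
quantify_scene <- function(channels, config = seg_config(),
                           fa_cfg = fa_config(),
                           thresholds = blebbing_thresholds()) {
  if (inherits(channels, "synthetic_scene")) channels <- channels$channels
  stopifnot(all(c("cytoplasm", "nuclei", "adhesion") %in% names(channels)))
  nuclei <- segment_nuclei(channels$nuclei, config)
  cells <- segment_cell_bodies(channels$cytoplasm, nuclei, config)
  feats <- extract_cell_features(channels, cells, nuclei, thresholds)
  fa_raw <- segment_fas(channels$adhesion, fa_cfg)
  fa <- filter_fas(fa_raw, cells, nuclei, channels$adhesion, fa_cfg)
  feats$fa_count <- count_fas(fa, cells)[feats$cell_id]
  structure(list(features = feats, cell_labels = cells,
                 nucleus_labels = nuclei, fa_labels = fa),
            class = "scene_quantification")
}

#' @export
print.scene_quantification <- function(x, ...) {
  cat(sprintf("Scene quantification: %d cells, %d blebbing calls, %d focal adhesions\n",
              nrow(x$features), sum(x$features$blebbing, na.rm = TRUE),
              max(x$fa_labels, 0L)))
  invisible(x)
}

#' Simulate and quantify a grouped experiment
#'
#' Generates seeded synthetic scenes for each experimental group, runs
#' [quantify_scene()] on each, and pools the per-cell records with group
#' labels and ground-truth annotations (matched by nucleus overlap with
#' the generating truth). A convenience wrapper used throughout the
#' package's validation.
#'
#' @param group_params named list of [scene_params()] *templates* (their
#'   `seed` is combined with `seed` and the scene index).
#' @param scenes_per_group number of scenes per group.
#' @param seed master seed.
#' @param ... passed to [quantify_scene()].
#' @return data frame of pooled per-cell records with columns of
#'   [extract_cell_features()] plus `group`, `scene`, `true_blebbing`,
#'   `true_fa_count`, `true_cell_id`.
#' @export
simulate_experiment <- function(group_params, scenes_per_group = 1, seed = 1,
                                ...) {
  stopifnot(is.list(group_params), length(names(group_params)) == length(group_params))
  all_rows <- list()
  scene_id <- 0L
  for (g in names(group_params)) {
    for (s in seq_len(scenes_per_group)) {
      scene_id <- scene_id + 1L
      p <- group_params[[g]]
      p$seed <- as.integer((seed * 10007L + scene_id * 131L) %% .Machine$integer.max)
      scene <- generate_scene(p)
      q <- quantify_scene(scene, ...)
      f <- q$features
      if (!nrow(f)) next
      f$group <- g
      f$scene <- scene_id
      m <- match_cells_to_truth(q, scene$truth)
      f$true_cell_id <- m
      f$true_blebbing <- ifelse(is.na(m), NA, scene$truth$blebbing[m])
      f$true_fa_count <- ifelse(is.na(m), NA, scene$truth$fa_counts[m])
      all_rows[[length(all_rows) + 1L]] <- f
    }
  }
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  out
}

#' Match segmented cells to ground-truth cells
#'
#' Each segmented cell is matched to the ground-truth cell with the
#' largest mask overlap (NA when there is no overlap).
#'
#' @param quant a `scene_quantification`.
#' @param truth a `scene_truth`.
#' @return integer vector over segmented cell labels.
#' @export
match_cells_to_truth <- function(quant, truth) {
  n <- max(quant$cell_labels, 0L)
  out <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    tl <- truth$cell_labels[quant$cell_labels == k]
    tl <- tl[tl > 0L]
    if (!length(tl)) next
    tab <- table(tl)
    out[k] <- as.integer(names(tab)[which.max(tab)])
  }
  out
}
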