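#' Focal-adhesion quantification configuration
#'
#' @param fa_preset [pst_params()] for punctate segmentation.
#' @param min_fa_area minimum focal-adhesion component area in px
#'   (default 30; smaller areas are removed).
#' @param upper_percentile dataset-wide upper cutoff on per-cell counts,
#'   as a percentile (default 99, linear-interpolation definition).
#' @param lower_count_max cells with this many focal adhesions or fewer
#'   are removed (default 4).
#' @return object of class `fa_config`.
#' @export
fa_config <- function(fa_preset = pst_preset("fa"), min_fa_area = 30,
                      upper_percentile = 99, lower_count_max = 4) {
  stopifnot(inherits(fa_preset, "pst_params"), min_fa_area >= 1,
            upper_percentile > 0, upper_percentile <= 100,
            lower_count_max >= 0)
  structure(list(fa_preset = fa_preset, min_fa_area = min_fa_area,
                 upper_percentile = upper_percentile,
                 lower_count_max = lower_count_max),
            class = "fa_config")
}

#' Segment focal-adhesion puncta from the adhesion channel
#'
#' [pst_segment()] with the focal-adhesion preset (no hole filling)
#' proposes candidate puncta; each candidate is then refined against the
#' intensity image so the component extent matches the punctum's
#' intensity support rather than the width of the phase response. The
#' refinement thresholds the candidate's neighbourhood halfway between
#' the local background level and the punctum's upper intensity and keeps
#' the connected part overlapping the candidate; this keeps measured
#' areas faithful, which matters because the downstream area filter is a
#' hard 30 px rule. Location, size, and intensity filtering happen in
#' [filter_fas()].
#'
#' @param adhesion_channel numeric matrix.
#' @param config a [fa_config()].
#' @return integer label map of candidate puncta.
#' @export
segment_fas <- function(adhesion_channel, config = fa_config()) {
  lab <- pst_segment(adhesion_channel, config$fa_preset)
  refine_fa_components(lab, adhesion_channel, config$fa_preset$min_region_area)
}

# Refine each candidate component to the intensity support of its
# punctum. A candidate whose phase response spans several puncta yields
# one label per intensity component; a punctum claimed by an earlier
# candidate is not emitted twice.
refine_fa_components <- function(lab, image, min_area) {
  n <- max(lab)
  if (n == 0L) return(lab)
  out <- matrix(0L, nrow(lab), ncol(lab))
  any_cand <- lab > 0L
  next_id <- 0L
  emit <- function(mask) {
    if (sum(mask) < min_area) return(invisible(NULL))
    claimed <- out[mask] > 0L
    if (mean(claimed) > 0.5) return(invisible(NULL))
    next_id <<- next_id + 1L
    out[mask & out == 0L] <<- next_id
    invisible(NULL)
  }
  for (f in seq_len(n)) {
    sel <- lab == f
    if (!any(sel)) next
    pad <- 6L
    repeat {
      bb <- mask_bbox(sel, pad = pad)
      sub <- image[bb$r1:bb$r2, bb$c1:bb$c2]
      ssel <- sel[bb$r1:bb$r2, bb$c1:bb$c2]
      sbg <- sub[!any_cand[bb$r1:bb$r2, bb$c1:bb$c2]]
      if (!length(sbg)) { comps <- NULL; break }
      bg <- stats::median(sbg)
      fg <- stats::quantile(sub[ssel], 0.95, names = FALSE)
      # refine only clearly punctate candidates; low-contrast candidates
      # (e.g. phase ridges along nucleus outlines) keep their raw extent
      # and fall to the downstream filters
      if (fg <= 1.5 * bg) { comps <- NULL; break }
      thr <- (bg + fg) / 2
      cand <- label_components(sub > thr, connectivity = 8)
      hit <- setdiff(unique(cand[ssel & cand > 0L]), 0L)
      if (!length(hit)) { comps <- NULL; break }
      # grow the window until no hit component is clipped by its border
      edge <- unique(c(cand[1, ], cand[nrow(cand), ], cand[, 1], cand[, ncol(cand)]))
      clipped <- any(hit %in% edge) &&
        !(bb$r1 == 1L && bb$c1 == 1L && bb$r2 == nrow(image) && bb$c2 == ncol(image))
      if (clipped && pad < 64L) { pad <- pad + 8L; next }
      # a refined component much larger than its candidate is not a
      # punctum (e.g. a whole cell interior caught from an edge ridge)
      hit <- hit[vapply(hit, function(h) sum(cand == h), numeric(1)) <=
                   pmax(2 * sum(sel), 150)]
      if (!length(hit)) { comps <- NULL; break }
      comps <- lapply(hit, function(h) {
        m <- matrix(FALSE, nrow(image), ncol(image))
        m[bb$r1:bb$r2, bb$c1:bb$c2] <- cand == h
        m
      })
      break
    }
    if (is.null(comps)) emit(sel) else for (m in comps) emit(m)
  }
  out
}

#' Filter focal-adhesion candidates
#'
#' Applies the noise-removal rules: candidates whose majority area lies
#' outside any cell or inside a nucleus are dropped; survivors are
#' assigned to the cell holding the majority of their area (ties to the
#' lower cell label); components smaller than `min_fa_area` are dropped;
#' components whose mean adhesion-channel intensity does not exceed the
#' mean intensity over their assigned cell's mask are dropped.
#'
#' @param fa_labels candidate label map from [segment_fas()].
#' @param cell_labels,nucleus_labels co-registered label maps.
#' @param adhesion_channel numeric matrix.
#' @param config a [fa_config()].
#' @return relabelled (1..K) focal-adhesion label map with attribute
#'   `fa_cell`, the cell label owning each surviving component.
#' @export
filter_fas <- function(fa_labels, cell_labels, nucleus_labels,
                       adhesion_channel, config = fa_config()) {
  stopifnot(all(dim(fa_labels) == dim(cell_labels)),
            all(dim(fa_labels) == dim(nucleus_labels)))
  n_fa <- max(fa_labels)
  out <- matrix(0L, nrow(fa_labels), ncol(fa_labels))
  fa_cell <- integer(0)
  if (n_fa == 0L) {
    attr(out, "fa_cell") <- fa_cell
    return(out)
  }
  cell_means <- vapply(seq_len(max(cell_labels, 1L)), function(cl) {
    px <- adhesion_channel[cell_labels == cl]
    if (length(px)) mean(px) else NA_real_
  }, numeric(1))
  next_id <- 0L
  for (f in seq_len(n_fa)) {
    sel <- fa_labels == f
    a <- sum(sel)
    if (a == 0L) next
    cells <- cell_labels[sel]
    if (mean(cells > 0L) <= 0.5) next          # majority outside any cell
    if (mean(nucleus_labels[sel] > 0L) > 0.5) next  # majority inside a nucleus
    tab <- table(cells[cells > 0L])
    owner <- as.integer(names(tab)[which.max(tab)])  # ties: lowest label (table order)
    if (a < config$min_fa_area) next
    if (mean(adhesion_channel[sel]) <= cell_means[owner]) next
    next_id <- next_id + 1L
    out[sel] <- next_id
    fa_cell[next_id] <- owner
  }
  attr(out, "fa_cell") <- fa_cell
  out
}

#' Count focal adhesions per cell
#'
#' @param fa_labels filtered label map from [filter_fas()] (its `fa_cell`
#'   attribute is used when present; otherwise ownership is recomputed by
#'   majority overlap).
#' @param cell_labels cell label map.
#' @return integer vector of counts indexed by cell label (cells without
#'   adhesions get 0).
#' @export
count_fas <- function(fa_labels, cell_labels) {
  n_cells <- max(cell_labels, 0L)
  fa_cell <- attr(fa_labels, "fa_cell")
  if (is.null(fa_cell)) {
    fa_cell <- integer(0)
    for (f in seq_len(max(fa_labels, 0L))) {
      cells <- cell_labels[fa_labels == f]
      cells <- cells[cells > 0L]
      if (!length(cells)) next
      tab <- table(cells)
      fa_cell <- c(fa_cell, as.integer(names(tab)[which.max(tab)]))
    }
  }
  tabulate(fa_cell, nbins = n_cells)
}

#' Apply the dataset-wide focal-adhesion count cutoffs
#'
#' Computes the upper cutoff as the `upper_percentile`-th percentile
#' (linear interpolation) of `fa_count` pooled over the whole dataset and
#' removes cells strictly above it; removes cells with
#' `fa_count <= lower_count_max` (four or fewer by default, a regime
#' that tracks failed or borderline segmentations). Exclusions are
#' annotated in `excluded_by`; the realized upper cutoff is attached as
#' an attribute so reports can record it.
#'
#' @param records data frame with an `fa_count` column.
#' @param config a [fa_config()].
#' @return retained records; attributes `excluded` (removed records with
#'   rule names `fa_upper_percentile` / `fa_lower_count`) and
#'   `fa_upper_cutoff` (the realized percentile value).
#' @export
apply_fa_cutoffs <- function(records, config = fa_config()) {
  stopifnot(is.data.frame(records), "fa_count" %in% names(records))
  cutoff <- stats::quantile(records$fa_count, config$upper_percentile / 100,
                            type = 7, names = FALSE)
  rule <- character(nrow(records))
  rule[records$fa_count > cutoff] <- "fa_upper_percentile"
  low <- records$fa_count <= config$lower_count_max
  rule[low] <- ifelse(nchar(rule[low]) > 0,
                      paste0(rule[low], ",fa_lower_count"), "fa_lower_count")
  records$excluded_by <- rule
  retained <- records[rule == "", , drop = FALSE]
  excluded <- records[rule != "", , drop = FALSE]
  rownames(retained) <- NULL
  rownames(excluded) <- NULL
  attr(retained, "excluded") <- excluded
  attr(retained, "fa_upper_cutoff") <- cutoff
  retained
}
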