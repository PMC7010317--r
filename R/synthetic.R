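#' Parameters of a synthetic three-channel scene
#'
#' Describes one simulated field of view: ellipse-like spread fibroblasts
#' versus "blebbing" cells whose outlines carry bead-like bulging membrane
#' protrusions; one nucleus per cell; punctate focal adhesions in the
#' cytoplasm over a diffuse background; Gaussian and optional Poisson
#' noise. A scene is a pure function of its parameters, including `seed`.
#'
#' `channel_intensities` holds the rendered intensity levels (arbitrary
#' 16-bit units): `cytoplasm = c(bg, fg)`, `nuclei = c(bg, fg)`,
#' `adhesion = c(bg, cyto, fa)` plus the nucleus/cytoplasm contrast factors
#' of the adhesion channel, `nuc_factor_blebbing` (default 0.8, nucleus
#' dimmer — blebbing cells show relatively high cytoplasmic marker signal)
#' and `nuc_factor_smooth` (default 1.6, nucleus brighter).
#'
#' @param image_height,image_width image size in pixels.
#' @param n_cells number of cells to place.
#' @param blebbing_fraction fraction of cells rendered blebbing; the count
#'   is exactly `round(blebbing_fraction * n_cells)`.
#' @param cell_radius_mean,cell_radius_sd cell radius distribution (px);
#'   draws are truncated to `[0.72, 1.4] * cell_radius_mean`.
#' @param axis_ratio_max cell outlines are ellipses with axis ratio drawn
#'   uniformly from `[1, axis_ratio_max]` (area preserved).
#' @param nucleus_radius_fraction nucleus radius as a fraction of the cell
#'   radius, in (0, 1).
#' @param n_blebs_range integer range of bead protrusions per blebbing cell.
#' @param bleb_amplitude_fraction bead radius as a fraction of cell radius.
#' @param n_fas_range integer range of focal-adhesion spots per cell.
#' @param fa_area_range focal-adhesion spot area range (px).
#' @param touching_pair_fraction fraction of cells placed as touching pairs
#'   (each pair renders as one connected cell-body region with two nuclei).
#' @param channel_intensities see Details.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param poisson_noise apply Poisson (shot) noise before Gaussian noise.
#' @param seed integer seed; the generator never touches the caller's RNG
#'   state.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(image_height = 768, image_width = 768,
                         n_cells = 10, blebbing_fraction = 0.5,
                         cell_radius_mean = 50, cell_radius_sd = 6,
                         axis_ratio_max = 1.15,
                         nucleus_radius_fraction = 0.55,
                         n_blebs_range = c(6L, 12L),
                         bleb_amplitude_fraction = 0.15,
                         n_fas_range = c(5L, 10L),
                         fa_area_range = c(30, 70),
                         touching_pair_fraction = 0,
                         channel_intensities = list(
                           cytoplasm = c(bg = 200, fg = 1200),
                           nuclei = c(bg = 200, fg = 1800),
                           adhesion = c(bg = 200, cyto = 600, fa = 2400),
                           nuc_factor_blebbing = 0.8,
                           nuc_factor_smooth = 1.6),
                         noise_sd = 30, poisson_noise = FALSE,
                         seed = 1L) {
  stopifnot(image_height >= 64, image_width >= 64, n_cells >= 0,
            blebbing_fraction >= 0, blebbing_fraction <= 1,
            cell_radius_mean > 0, cell_radius_sd >= 0,
            axis_ratio_max >= 1,
            nucleus_radius_fraction > 0, nucleus_radius_fraction < 1,
            length(n_blebs_range) == 2, n_blebs_range[1] >= 3,
            diff(n_blebs_range) >= 0,
            bleb_amplitude_fraction > 0, bleb_amplitude_fraction < 1,
            length(n_fas_range) == 2, n_fas_range[1] >= 0,
            diff(n_fas_range) >= 0,
            length(fa_area_range) == 2, fa_area_range[1] > 0,
            diff(fa_area_range) >= 0,
            touching_pair_fraction >= 0, touching_pair_fraction <= 1,
            noise_sd >= 0, is.finite(seed))
  structure(as.list(environment()), class = "scene_params")
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf("Synthetic scene parameters: %dx%d px, %d cells (%.0f%% blebbing), seed %d\n",
              x$image_height, x$image_width, x$n_cells,
              100 * x$blebbing_fraction, as.integer(x$seed)))
  invisible(x)
}

#' Generate a single cell outline polygon
#'
#' Builds a closed polygon around the origin. Non-blebbing outlines are
#' ellipses with a mild low-frequency radial perturbation. Blebbing
#' outlines carry `n_blebs` semicircular bead protrusions of radius
#' `amplitude_fraction * radius` superposed on the base ellipse, emulating
#' bead-like bulging membrane protrusions. The construction is radial
#' (star-shaped around the origin), so the polygon is simple whenever the
#' radial function stays positive; if a perturbation drives it
#' non-positive the outline is regenerated with reduced amplitude, and an
#' error is raised after bounded retries.
#'
#' Draws from the current RNG; seed the session (or rely on
#' [generate_scene()], which threads one seeded generator through all
#' draws) for reproducibility.
#'
#' @param radius nominal cell radius (px), >= 10.
#' @param blebbing logical flag.
#' @param n_blebs number of bead protrusions (>= 3) when `blebbing`.
#' @param amplitude_fraction bead radius as a fraction of `radius`, in (0,1).
#' @param axis_ratio ellipse axis ratio (area preserved).
#' @param perturb_amplitude amplitude of the low-frequency radial
#'   perturbation of non-blebbing outlines (fraction of radius per
#'   harmonic; 0 gives the exact ellipse/circle).
#' @param n_vertices number of polygon vertices.
#' @return an `n_vertices` x 2 matrix of (row, col) offsets from the
#'   center, closed implicitly (last vertex connects to the first).
#' @export
make_cell_outline <- function(radius, blebbing = FALSE, n_blebs = 8L,
                              amplitude_fraction = 0.15, axis_ratio = 1,
                              perturb_amplitude = 0.02, n_vertices = 720L) {
  stopifnot(radius >= 10, axis_ratio >= 1, n_vertices >= 36)
  if (blebbing) stopifnot(n_blebs >= 3, amplitude_fraction > 0, amplitude_fraction < 1)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  a <- radius * sqrt(axis_ratio); b <- radius / sqrt(axis_ratio)
  psi <- stats::runif(1, 0, pi)
  base <- a * b / sqrt((b * cos(th - psi))^2 + (a * sin(th - psi))^2)
  amp <- amplitude_fraction
  for (try in 1:5) {
    r <- base
    if (blebbing) {
      rho <- amp * radius
      centers <- (seq_len(n_blebs) - 1) * 2 * pi / n_blebs +
        stats::runif(1, 0, 2 * pi) +
        stats::runif(n_blebs, -0.25, 0.25) * 2 * pi / n_blebs
      for (ck in centers) {
        dth <- abs(((th - ck + pi) %% (2 * pi)) - pi)
        arc <- base * dth  # arc-length distance along the base outline
        r <- r + sqrt(pmax(0, rho^2 - arc^2))
      }
    } else if (perturb_amplitude > 0) {
      for (k in 2:4)
        r <- r * (1 + stats::runif(1, 0, perturb_amplitude) *
                    cos(k * th + stats::runif(1, 0, 2 * pi)))
    }
    if (all(r > 0)) return(cbind(row = r * cos(th), col = r * sin(th)))
    amp <- amp / 2
  }
  stop("could not generate a simple outline after 5 retries")
}

#' Rasterize a closed polygon onto a pixel grid
#'
#' Even-odd scanline fill; a pixel belongs to the polygon when its center
#' (integer coordinates) lies inside under the even-odd rule. This one
#' convention is used for every mask the generator renders.
#'
#' @param poly n x 2 matrix of (row, col) vertex coordinates in pixel units.
#' @param nrow,ncol output mask size.
#' @return logical matrix.
#' @export
rasterize_polygon <- function(poly, nrow, ncol) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  x <- poly[, 1]; y <- poly[, 2]
  nv <- length(x)
  x2 <- x[c(2:nv, 1)]; y2 <- y[c(2:nv, 1)]
  mask <- matrix(FALSE, nrow, ncol)
  r_lo <- max(1L, floor(min(x))); r_hi <- min(nrow, ceiling(max(x)))
  if (r_hi < r_lo) return(mask)
  for (rr in r_lo:r_hi) {
    crosses <- (x > rr) != (x2 > rr)
    if (!any(crosses)) next
    yc <- y[crosses] + (rr - x[crosses]) * (y2[crosses] - y[crosses]) / (x2[crosses] - x[crosses])
    yc <- sort(yc)
    for (j in seq(1, length(yc) - 1, by = 2)) {
      lo <- max(1L, ceiling(yc[j])); hi <- min(ncol, floor(yc[j + 1]))
      if (hi >= lo) mask[rr, lo:hi] <- TRUE
    }
  }
  mask
}

#' Add detector noise to an image
#'
#' Optional Poisson (shot) noise followed by additive Gaussian noise, with
#' the result clipped to the valid 16-bit intensity range. With
#' `gaussian_sd = 0` and `poisson = FALSE` the input is returned unchanged.
#' Draws from the current RNG.
#'
#' @param image numeric matrix.
#' @param gaussian_sd Gaussian noise SD (intensity units), >= 0.
#' @param poisson apply Poisson noise (pixel values used as rates).
#' @return noisy image, clipped to `[0, 65535]`.
#' @export
add_noise <- function(image, gaussian_sd = 0, poisson = FALSE) {
  stop_if_not_image(image)
  stopifnot(gaussian_sd >= 0)
  if (gaussian_sd == 0 && !poisson) return(image)
  out <- image
  if (poisson)
    out <- matrix(stats::rpois(length(out), pmax(out, 0)), nrow(out), ncol(out))
  if (gaussian_sd > 0)
    out <- out + stats::rnorm(length(out), 0, gaussian_sd)
  out[out < 0] <- 0
  out[out > 65535] <- 65535
  out
}

# Radial function lookup for a polygon produced by make_cell_outline():
# linear interpolation of vertex radius over angle.
outline_radius_fun <- function(poly) {
  th <- atan2(poly[, 2], poly[, 1])
  r <- sqrt(rowSums(poly^2))
  o <- order(th)
  th <- th[o]; r <- r[o]
  function(angle) {
    angle <- ((angle + pi) %% (2 * pi)) - pi
    stats::approx(c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi),
                  c(r[length(r)], r, r[1]), xout = angle)$y
  }
}

#' Generate a synthetic three-channel scene with ground truth
#'
#' Renders one field of view from [scene_params()]: the cytoplasm channel
#' is foreground over the cell masks, the nuclei channel is bright over
#' nucleus masks, and the adhesion channel combines punctate
#' focal-adhesion spots, a weaker diffuse cytoplasmic signal, and a
#' per-class nuclear contrast (dimmer nucleus for blebbing cells, brighter
#' for non-blebbing ones, so the nuclear/cytoplasmic intensity-ratio
#' criterion is exercised). Noise is applied last. The ground truth is
#' consistent with the noise-free render: each truth mask equals the set
#' of pixels rendered as that object's foreground.
#'
#' @param params a [scene_params()] object.
#' @return a list of class `synthetic_scene` with elements
#'   `channels` (list of `cytoplasm`, `nuclei`, `adhesion` matrices) and
#'   `truth` (class `scene_truth`: `cell_labels`, `nucleus_labels`,
#'   `fa_labels` integer label maps; `blebbing` logical vector;
#'   `fa_cell` integer vector mapping FA label to cell; `fa_counts`;
#'   `touching_pairs` two-column matrix of cell index pairs).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  withr::with_seed(as.integer(params$seed), generate_scene_impl(params))
}

generate_scene_impl <- function(p) {
  H <- p$image_height; W <- p$image_width
  ci <- p$channel_intensities
  cell_labels <- matrix(0L, H, W)
  nucleus_labels <- matrix(0L, H, W)
  fa_labels <- matrix(0L, H, W)
  n <- p$n_cells

  empty_truth <- function(pairs = matrix(integer(0), 0, 2)) {
    structure(list(cell_labels = cell_labels, nucleus_labels = nucleus_labels,
                   fa_labels = fa_labels, blebbing = logical(n),
                   fa_cell = integer(0), fa_counts = integer(n),
                   touching_pairs = pairs, n_cells = n),
              class = "scene_truth")
  }

  render <- function(truth) {
    cyto <- matrix(ci$cytoplasm[["bg"]], H, W)
    cyto[truth$cell_labels > 0L] <- ci$cytoplasm[["fg"]]
    nuc <- matrix(ci$nuclei[["bg"]], H, W)
    nuc[truth$nucleus_labels > 0L] <- ci$nuclei[["fg"]]
    adh <- matrix(ci$adhesion[["bg"]], H, W)
    adh[truth$cell_labels > 0L] <- ci$adhesion[["cyto"]]
    if (truth$n_cells > 0) {
      for (k in seq_len(truth$n_cells)) {
        f <- if (truth$blebbing[k]) ci$nuc_factor_blebbing else ci$nuc_factor_smooth
        adh[truth$nucleus_labels == k] <- ci$adhesion[["cyto"]] * f
      }
    }
    adh[truth$fa_labels > 0L] <- ci$adhesion[["fa"]]
    lapply(list(cytoplasm = cyto, nuclei = nuc, adhesion = adh),
           add_noise, gaussian_sd = p$noise_sd, poisson = p$poisson_noise)
  }

  if (n == 0L) {
    truth <- empty_truth()
    return(structure(list(channels = render(truth), truth = truth,
                          params = p), class = "synthetic_scene"))
  }

  # --- per-cell geometry draws ---------------------------------------
  radius <- pmin(pmax(stats::rnorm(n, p$cell_radius_mean, p$cell_radius_sd),
                      0.72 * p$cell_radius_mean), 1.4 * p$cell_radius_mean)
  axis_ratio <- stats::runif(n, 1, p$axis_ratio_max)
  n_bleb_cells <- round(p$blebbing_fraction * n)
  n_pair_cells <- 2L * (round(p$touching_pair_fraction * n) %/% 2L)
  pair_members <- if (n_pair_cells > 0) seq_len(n_pair_cells) else integer(0)
  # touching-pair members are rendered as near-circles so the intended
  # contact distance cannot open into a gap through ellipse orientation
  if (length(pair_members)) axis_ratio[pair_members] <- 1
  pairs <- if (n_pair_cells > 0)
    matrix(pair_members, ncol = 2, byrow = TRUE) else matrix(integer(0), 0, 2)
  # blebbing assigned preferentially outside touching pairs (pairs exist to
  # exercise the under-segmentation splitter, not the classifier)
  free <- setdiff(seq_len(n), pair_members)
  blebbing <- logical(n)
  picked <- if (n_bleb_cells <= length(free)) {
    if (length(free) == 1L) free else sample(free, n_bleb_cells)
  } else {
    extra <- n_bleb_cells - length(free)
    pm <- if (length(pair_members) == 1L) pair_members else sample(pair_members, extra)
    c(free, pm)
  }
  blebbing[picked] <- TRUE
  # touching-pair members are rendered non-blebbing when possible; if
  # blebbing spilled into pairs (fraction too high), beads stay outward so
  # pairs still merge into one region.

  # --- placement ------------------------------------------------------
  eff_r <- radius * (1 + ifelse(blebbing, p$bleb_amplitude_fraction, 0.03)) + 2
  centers <- matrix(NA_real_, n, 2)
  place_margin <- 5
  max_attempts <- 400L * n
  attempts <- 0L
  placed <- logical(n)
  order_place <- c(pair_members, free)
  k_idx <- 1L
  while (k_idx <= n) {
    k <- order_place[k_idx]
    is_second_of_pair <- k %in% pairs[, 2]
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(paste0("could not place %d cells of effective radius ~%.0f px ",
                          "in a %dx%d image; reduce n_cells or cell_radius_mean"),
                   n, mean(eff_r), H, W))
    if (is_second_of_pair) {
      mate <- pairs[pairs[, 2] == k, 1]
      d <- 0.88 * (radius[mate] + radius[k])
      ang <- stats::runif(1, 0, 2 * pi)
      cand <- centers[mate, ] + d * c(cos(ang), sin(ang))
    } else {
      cand <- c(stats::runif(1, eff_r[k] + place_margin, H - eff_r[k] - place_margin),
                stats::runif(1, eff_r[k] + place_margin, W - eff_r[k] - place_margin))
    }
    if (cand[1] < eff_r[k] + place_margin || cand[1] > H - eff_r[k] - place_margin ||
        cand[2] < eff_r[k] + place_margin || cand[2] > W - eff_r[k] - place_margin) next
    ok <- TRUE
    for (j in which(placed)) {
      if (is_second_of_pair && j == pairs[pairs[, 2] == k, 1]) next
      lim <- if (j %in% pairs[, 1] && k %in% pairs[pairs[, 1] == j, 2])
        0 else eff_r[k] + eff_r[j] + 6
      if (sqrt(sum((centers[j, ] - cand)^2)) < lim) { ok <- FALSE; break }
    }
    if (!ok) next
    centers[k, ] <- cand
    placed[k] <- TRUE
    k_idx <- k_idx + 1L
  }

  # --- outlines and masks ----------------------------------------------
  outlines <- vector("list", n)
  for (k in seq_len(n)) {
    nb <- if (diff(p$n_blebs_range) > 0)
      sample(p$n_blebs_range[1]:p$n_blebs_range[2], 1) else p$n_blebs_range[1]
    outlines[[k]] <- make_cell_outline(
      radius[k], blebbing = blebbing[k], n_blebs = nb,
      amplitude_fraction = p$bleb_amplitude_fraction,
      axis_ratio = axis_ratio[k])
  }
  for (k in seq_len(n)) {
    poly <- sweep(outlines[[k]], 2, centers[k, ], `+`)
    m <- rasterize_polygon(poly, H, W)
    ov <- m & cell_labels > 0L
    if (any(ov)) {
      # touching pairs may overlap slightly; assign contested pixels to the
      # cell whose center is nearer in units of its own radius
      idx <- which(ov, arr.ind = TRUE)
      other <- cell_labels[ov]
      d_new <- sqrt((idx[, 1] - centers[k, 1])^2 + (idx[, 2] - centers[k, 2])^2) / radius[k]
      d_old <- sqrt((idx[, 1] - centers[other, 1])^2 +
                    (idx[, 2] - centers[other, 2])^2) / radius[other]
      m[ov] <- d_new < d_old
    }
    cell_labels[m] <- k
  }

  # --- nuclei -----------------------------------------------------------
  nuc_r <- p$nucleus_radius_fraction * radius
  for (k in seq_len(n)) {
    th <- seq(0, 2 * pi, length.out = 361)[-361]
    poly <- cbind(centers[k, 1] + nuc_r[k] * cos(th),
                  centers[k, 2] + nuc_r[k] * sin(th))
    m <- rasterize_polygon(poly, H, W) & cell_labels == k
    nucleus_labels[m] <- k
  }

  # --- focal adhesions --------------------------------------------------
  fa_cell <- integer(0)
  fa_id <- 0L
  for (k in seq_len(n)) {
    n_fa <- if (diff(p$n_fas_range) > 0)
      sample(p$n_fas_range[1]:p$n_fas_range[2], 1) else p$n_fas_range[1]
    if (n_fa == 0L) next
    rfun <- outline_radius_fun(outlines[[k]])
    placed_fa <- matrix(numeric(0), 0, 3)
    tries <- 0L
    while (nrow(placed_fa) < n_fa && tries < 400L) {
      tries <- tries + 1L
      area <- stats::runif(1, p$fa_area_range[1], p$fa_area_range[2])
      sr <- sqrt(area / pi)
      ang <- stats::runif(1, 0, 2 * pi)
      lo <- nuc_r[k] + 6 + sr
      hi <- rfun(ang) - 4 - sr
      if (!is.finite(hi) || lo >= hi) next
      rr <- stats::runif(1, lo, hi)
      sx <- centers[k, 1] + rr * cos(ang); sy <- centers[k, 2] + rr * sin(ang)
      if (nrow(placed_fa) > 0) {
        gap <- sqrt((placed_fa[, 1] - sx)^2 + (placed_fa[, 2] - sy)^2) -
          placed_fa[, 3] - sr
        if (min(gap) < 10) next
      }
      placed_fa <- rbind(placed_fa, c(sx, sy, sr))
    }
    for (j in seq_len(nrow(placed_fa))) {
      th <- seq(0, 2 * pi, length.out = 181)[-181]
      sr <- placed_fa[j, 3]
      # grow the radius marginally if rasterization lands the mask below
      # the nominal minimum area (pixel-count jitter of small discs)
      for (adj in c(0, 0.1, 0.2, 0.3)) {
        poly <- cbind(placed_fa[j, 1] + (sr + adj) * cos(th),
                      placed_fa[j, 2] + (sr + adj) * sin(th))
        m <- rasterize_polygon(poly, H, W) & cell_labels == k & nucleus_labels == 0L
        if (sum(m) >= p$fa_area_range[1]) break
      }
      if (sum(m) < p$fa_area_range[1]) next
      fa_id <- fa_id + 1L
      fa_labels[m] <- fa_id
      fa_cell <- c(fa_cell, k)
    }
  }

  truth <- structure(list(
    cell_labels = cell_labels, nucleus_labels = nucleus_labels,
    fa_labels = fa_labels, blebbing = blebbing, fa_cell = fa_cell,
    fa_counts = tabulate(fa_cell, nbins = n), touching_pairs = pairs,
    n_cells = n), class = "scene_truth")
  structure(list(channels = render(truth), truth = truth, params = p),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %dx%d px, %d cells (%d blebbing), %d focal adhesions\n",
              nrow(x$channels$cytoplasm), ncol(x$channels$cytoplasm),
              x$truth$n_cells, sum(x$truth$blebbing), length(x$truth$fa_cell)))
  invisible(x)
}

#' Extract one ground-truth mask from a scene
#'
#' @param truth a `scene_truth` object.
#' @param what `"cell"`, `"nucleus"`, or `"fa"`.
#' @param index object index.
#' @return logical mask.
#' @export
truth_mask <- function(truth, what = c("cell", "nucleus", "fa"), index) {
  what <- match.arg(what)
  lab <- switch(what, cell = truth$cell_labels,
                nucleus = truth$nucleus_labels, fa = truth$fa_labels)
  lab == as.integer(index)
}
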