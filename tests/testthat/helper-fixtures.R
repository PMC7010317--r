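# Shared fixture builders and independent oracles.

disk_mask <- function(n, cx, cy, r) {
  xy <- expand.grid(seq_len(n), seq_len(n))
  matrix((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2 <= r^2, n, n)
}

# Analytic circle polygon (no rasterization).
circle_polygon <- function(r, n = 720, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(row = cx + r * cos(th), col = cy + r * sin(th))
}

# Independent two-sided Fisher oracle: direct hypergeometric enumeration
# written against the table entries (not the package's margin algebra).
fisher_oracle <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  N <- a + b + c + d
  p_of <- function(x) {
    # probability of table [x, a+b-x; a+c-x, d-a+x] under fixed margins
    choose(a + b, x) * choose(c + d, a + c - x) / choose(N, a + c)
  }
  xs <- max(0, a - d):min(a + b, a + c)
  probs <- vapply(xs, p_of, numeric(1))
  p_obs <- p_of(a)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# Benjamini-Hochberg step-up applied literally to the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Boundary trace from raw points (bypasses tracing, for analytic fixtures).
new_trace_for_test <- function(pts) {
  colnames(pts) <- c("row", "col")
  structure(list(points = pts, curvature = NULL), class = "boundary_trace")
}

# Small default scene used by several tests.
small_scene <- function(seed, n_cells = 6, ...) {
  generate_scene(scene_params(n_cells = n_cells, seed = seed, ...))
}

# Lazily computed batch of default-condition scenes shared by the
# classifier-recovery and segmentation-recovery checks (same study
# conditions; computed once).
.accept_cache <- new.env(parent = emptyenv())

default_recovery_runs <- function() {
  if (!is.null(.accept_cache$runs)) return(.accept_cache$runs)
  runs <- lapply(1:20, function(i) {
    s <- generate_scene(scene_params(n_cells = 10, blebbing_fraction = 0.5,
                                     touching_pair_fraction = 0,
                                     seed = 1000 + i))
    nuclei <- segment_nuclei(s$channels$nuclei)
    cells <- suppressMessages(
      segment_cell_bodies(s$channels$cytoplasm, nuclei))
    feats <- extract_cell_features(s$channels, cells, nuclei)
    list(scene = s, nuclei = nuclei, cells = cells, feats = feats)
  })
  .accept_cache$runs <- runs
  runs
}

# Main-effect F statistic of factor A in a balanced two-way layout,
# computed from sums of squares directly (oracle for permutation tests).
balanced_f_a <- function(y, A, B) {
  gm <- mean(y)
  ssa <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, interaction(A, B), mean)
  celln <- tapply(y, interaction(A, B), length)
  sscells <- sum(celln * (cellm - gm)^2)
  ssab <- sscells - ssa - ssb
  sse <- sum((y - ave(y, interaction(A, B)))^2)
  dfa <- nlevels(factor(A)) - 1
  dfe <- length(y) - nlevels(factor(A)) * nlevels(factor(B))
  (ssa / dfa) / (sse / dfe)
}
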