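test_that("boundary tracing recovers the square and disk fixtures", {
  m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
  tr <- trace_boundary(m)
  n <- nrow(tr$points)
  expect_gte(n, 32); expect_lte(n, 40)
  x <- tr$points[, 2]; y <- tr$points[, 1]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  expect_lt(abs(area - 100) / 100, 0.05)

  d <- disk_mask(81, 41, 41, 30)
  trd <- trace_boundary(d)
  pts <- trd$points
  per <- sum(sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2)))
  expect_lt(abs(per - 2 * pi * 30) / (2 * pi * 30), 0.03)
})

test_that("degenerate masks are rejected by the tracer", {
  line <- matrix(FALSE, 30, 30); line[5:25, 10] <- TRUE
  expect_error(trace_boundary(line), "degenerate|8 boundary|thin")
  two <- disk_mask(64, 20, 20, 8) | disk_mask(64, 45, 45, 8)
  expect_error(trace_boundary(two), "single connected")
  tiny <- matrix(FALSE, 10, 10); tiny[4:5, 4:5] <- TRUE
  expect_error(trace_boundary(tiny), "area below")
})

test_that("traces are closed, counter-clockwise and duplicate-free", {
  d <- disk_mask(81, 41, 41, 25)
  tr <- trace_boundary(d)
  pts <- tr$points
  expect_gt(nrow(pts), 8)
  expect_false(any(rowSums(abs(diff(pts))) < 1e-12))
  x <- pts[, 2]; y <- pts[, 1]
  expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2, 0)
  # closure: last point adjacent to first (within one sample spacing)
  gap <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
  step <- median(sqrt(rowSums(diff(pts)^2)))
  expect_lt(gap, 3 * step)
})

test_that("Savitzky-Golay smoothing preserves exact-interpolation and straight runs", {
  # window = polyorder + 1 (odd window, exact interpolation) is the identity
  tr <- new_trace_for_test(circle_polygon(30, 60))
  sm <- smooth_boundary(tr, window = 5, polyorder = 4)
  expect_lt(max(abs(sm$points - tr$points)), 1e-9)
  # points on a straight segment are reproduced away from the corners
  race <- rbind(cbind(seq(0, 40, by = 1), 0),
                cbind(40, seq(1, 20, by = 1)),
                cbind(seq(39, 1, by = -1), 20),
                cbind(0, seq(19, 1, by = -1)))
  trr <- new_trace_for_test(race)
  smr <- smooth_boundary(trr, 9, 3)
  mid <- 15:25  # indices well inside the first straight run
  expect_lt(max(abs(smr$points[mid, ] - trr$points[mid, ])), 1e-9)
})

test_that("smoothing reduces radial noise on a circle", {
  set.seed(10)
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  r <- 50 + rnorm(360, 0, 1)
  tr <- new_trace_for_test(cbind(r * cos(th), r * sin(th)))
  sm <- smooth_boundary(tr, 9, 3)
  rms <- function(p) sqrt(mean((sqrt(rowSums(p^2)) - 50)^2))
  expect_lt(rms(sm$points), rms(tr$points))
})

test_that("smoothing preconditions raise named errors", {
  tr <- new_trace_for_test(circle_polygon(20, 50))
  expect_error(smooth_boundary(tr, 8, 3), "odd")
  expect_error(smooth_boundary(tr, 5, 5), "polyorder")
  expect_error(smooth_boundary(tr, 51, 3), "number of boundary points")
})

test_that("point curvature matches the circumradius definition", {
  expect_equal(point_curvature(c(0, 0), c(1, 0), c(2, 0)), 0)
  expect_equal(point_curvature(c(10, 0), c(0, 10), c(-10, 0)), 0.1)
  expect_error(point_curvature(c(1, 1), c(1, 1), c(0, 0)), "coincident")
  # independent oracle: solve the circumcenter 2x2 linear system
  set.seed(12)
  for (i in 1:50) {
    p <- matrix(rnorm(6, sd = 10), 3, 2)
    a <- p[1, ]; b <- p[2, ]; c <- p[3, ]
    M <- rbind(2 * (b - a), 2 * (c - a))
    if (abs(det(M)) < 1e-8) next
    rhs <- c(sum(b^2) - sum(a^2), sum(c^2) - sum(a^2))
    center <- solve(M, rhs)
    kappa_oracle <- 1 / sqrt(sum((a - center)^2))
    expect_equal(point_curvature(a, b, c), kappa_oracle, tolerance = 1e-9)
  }
})

test_that("mean curvature matches closed forms on circle and ellipse", {
  tr <- new_trace_for_test(circle_polygon(50, 720))
  k <- mean_cell_curvature(tr, step = 2)
  expect_lt(abs(k - 0.02) / 0.02, 0.05)
  # ellipse a=60, b=30: kappa(t) = a b / (a^2 sin^2 t + b^2 cos^2 t)^(3/2)
  a <- 60; b <- 30
  t <- seq(0, 2 * pi, length.out = 721)[-721]
  tre <- new_trace_for_test(cbind(a * cos(t), b * sin(t)))
  k_oracle <- mean(a * b / (a^2 * sin(t)^2 + b^2 * cos(t)^2)^1.5)
  expect_lt(abs(mean_cell_curvature(tre, 2) - k_oracle) / k_oracle, 0.10)
})

test_that("curvature is unsigned and scales inversely with size", {
  set.seed(14)
  poly <- make_cell_outline(45, TRUE, n_blebs = 9)
  tr <- boundary_curvature(new_trace_for_test(poly), 2)
  expect_true(all(tr$curvature >= 0))
  s <- 3
  tr_s <- boundary_curvature(new_trace_for_test(poly * s), 2)
  expect_lt(max(abs(tr_s$curvature - tr$curvature / s)), 1e-6)
})

test_that("intensity ratio divides nuclear by cytoplasmic means", {
  cell <- disk_mask(64, 32, 32, 20)
  nuc <- disk_mask(64, 32, 32, 9)
  ch <- matrix(3, 64, 64)
  expect_equal(intensity_ratio(ch, nuc, cell), 1.0)
  ch[nuc] <- 50; ch[cell & !nuc] <- 100
  expect_equal(intensity_ratio(ch, nuc, cell), 0.5)
  expect_error(intensity_ratio(ch, cell, cell), "cytoplasm")
  # shipped default cutoff
  expect_equal(blebbing_thresholds()$intensity_ratio_max, 1.15)
})

test_that("the three-criterion blebbing rule uses strict inequalities", {
  th <- blebbing_thresholds()
  f <- function(k, r, a) list(mean_curvature = k, intensity_ratio = r, area_ratio = a)
  expect_true(classify_blebbing(f(0.030, 1.10, 4.0), th))
  expect_false(classify_blebbing(f(0.030, 1.20, 4.0), th))  # intensity fails
  expect_false(classify_blebbing(f(0.005, 1.00, 10), th))   # smooth spread cell
  # boundary values are not blebbing (strict)
  expect_false(classify_blebbing(f(0.029, 1.10, 4.0), th))
  expect_false(classify_blebbing(f(0.030, 1.15, 4.0), th))
  expect_false(classify_blebbing(f(0.030, 1.10, 4.5), th))
})

test_that("raising the curvature cutoff never increases blebbing calls", {
  set.seed(16)
  feats <- data.frame(mean_curvature = runif(200, 0, 0.08),
                      intensity_ratio = runif(200, 0.5, 1.6),
                      area_ratio = runif(200, 2, 6))
  calls <- vapply(c(0.01, 0.02, 0.029, 0.04, 0.06), function(cm)
    sum(classify_blebbing(feats, blebbing_thresholds(curvature_min = cm))),
    numeric(1))
  expect_true(all(diff(calls) <= 0))
})

test_that("outlier filters exclude by the printed rules and are idempotent", {
  rec <- data.frame(cell_id = 1:4,
                    nucleus_area = c(900, 5000, 8638, 2000),
                    cell_area = c(30000, 160000, 35665, 140000))
  out <- apply_cell_filters(rec)
  excl <- attr(out, "excluded")
  expect_equal(out$cell_id, c(3L, 4L))
  expect_equal(excl$excluded_by[excl$cell_id == 1], "nucleus_area_min")
  expect_equal(excl$excluded_by[excl$cell_id == 2], "cell_area_max")
  # a typical cell (median-scale areas) is retained
  expect_true(3L %in% out$cell_id)
  # subset + idempotent
  again <- apply_cell_filters(out)
  expect_equal(again$cell_id, out$cell_id)
  expect_equal(nrow(attr(again, "excluded")), 0L)
  both <- apply_cell_filters(data.frame(cell_id = 9, nucleus_area = 500,
                                        cell_area = 2e5))
  expect_equal(attr(both, "excluded")$excluded_by, "nucleus_area_min,cell_area_max")
})
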