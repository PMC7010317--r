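test_that("background threshold follows the dimmest-fraction rule", {
  expect_equal(background_threshold(matrix(7, 10, 10), 0.2, 1), 7)
  img <- matrix(1:100, 10, 10)
  # brute-force oracle: sort the 100 values, average the dimmest 20
  expect_equal(background_threshold(img, 0.2, 1), mean(sort(1:100)[1:20]))
  expect_equal(background_threshold(img, 0.2, 1), 10.5)
  expect_equal(background_threshold(img, 0.2, 2.5), 2.5 * 10.5)
  expect_error(background_threshold(matrix(1, 2, 2), 0.1, 1), "zero pixels")
  # shipped default is the dimmest 20%
  expect_equal(seg_config()$dim_fraction, 0.20)
})

test_that("raising the threshold factor never increases foreground area", {
  s <- small_scene(17)
  sm <- as.matrix(EBImage::gblur(s$channels$cytoplasm, 2))
  areas <- vapply(c(1, 1.5, 2, 3, 4), function(f)
    sum(sm > background_threshold(sm, 0.2, f)), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("nuclei of a default scene are recovered one label each", {
  s <- generate_scene(scene_params(n_cells = 8, noise_sd = 0, seed = 19))
  lab <- segment_nuclei(s$channels$nuclei)
  expect_equal(max(lab), 8L)
  s2 <- generate_scene(scene_params(n_cells = 0, seed = 2))
  expect_equal(max(segment_nuclei(s2$channels$nuclei)), 0L)
})

test_that("nuclei at SNR 10 with default noise reach IoU >= 0.8", {
  ci <- scene_params()$channel_intensities
  ci$nuclei <- c(bg = 200, fg = 200 + 10 * 30)  # step = 10 x default noise SD
  s <- generate_scene(scene_params(n_cells = 6, channel_intensities = ci, seed = 23))
  lab <- segment_nuclei(s$channels$nuclei)
  expect_equal(max(lab), 6L)
  for (k in seq_len(6)) {
    best <- max(vapply(seq_len(max(lab)), function(L)
      mask_iou(lab == L, truth_mask(s$truth, "nucleus", k)), numeric(1)))
    expect_gte(best, 0.8)
  }
})

test_that("cell bodies segment one label per nucleus; debris is dropped", {
  s <- small_scene(29, n_cells = 6)
  nuclei <- segment_nuclei(s$channels$nuclei)
  cyto <- s$channels$cytoplasm
  cyto[30:60, 30:60] <- 1200  # bright debris blob with no nucleus
  cells <- segment_cell_bodies(cyto, nuclei)
  expect_equal(max(cells), 6L)
  nuc_of <- attr(cells, "nucleus_of")
  expect_equal(sort(unique(nuc_of)), sort(nuc_of))  # one nucleus per cell
  # the debris area carries no label
  expect_equal(max(cells[30:60, 30:60]), 0L)
  # one-nucleus rule holds on the output
  for (k in seq_len(max(cells))) {
    inside <- table(nuclei[cells == k & nuclei > 0])
    majority <- vapply(seq_len(max(nuclei)), function(nn) {
      px <- sum(nuclei == nn)
      sum(nuclei == nn & cells == k) > px / 2
    }, logical(1))
    expect_equal(sum(majority), 1L)
  }
})

test_that("a touching pair is split into two one-nucleus cells", {
  s <- generate_scene(scene_params(n_cells = 2, touching_pair_fraction = 1,
                                   seed = 31))
  nuclei <- segment_nuclei(s$channels$nuclei)
  cells <- suppressMessages(segment_cell_bodies(s$channels$cytoplasm, nuclei))
  expect_equal(max(cells), 2L)
  expect_equal(length(unique(attr(cells, "nucleus_of"))), 2L)
})

test_that("under-segmentation resolution partitions a dumbbell at its neck", {
  n <- 160
  region <- disk_mask(n, 50, 80, 26) | disk_mask(n, 110, 80, 26)
  region[48:112, 74:86] <- TRUE  # neck of width 13 along rows 48..112
  region <- region | FALSE
  nuclei <- matrix(0L, n, n)
  nuclei[disk_mask(n, 50, 80, 9)] <- 1L
  nuclei[disk_mask(n, 110, 80, 9)] <- 2L
  intensity <- matrix(0, n, n); intensity[region] <- 1000
  out <- suppressMessages(
    resolve_undersegmentation(region, nuclei, intensity, 500))
  # exactly one label per nucleus, and the labels partition the region
  expect_equal(max(out), 2L)
  expect_true(all(out[region] > 0L))
  expect_true(all(out[!region] == 0L))
  a1 <- sum(out == 1L); a2 <- sum(out == 2L)
  # symmetric fixture: areas within 5%
  expect_lt(abs(a1 - a2) / max(a1, a2), 0.05)
  # interface lies within 3 px of the minimum-width cut (row 80 by symmetry)
  rows1 <- which(out == 1L, arr.ind = TRUE)[, 1]
  rows2 <- which(out == 2L, arr.ind = TRUE)[, 1]
  expect_lte(max(rows1), 80 + 3)
  expect_gte(min(rows2), 80 - 3)
})

test_that("a region with n nuclei yields exactly n labels", {
  n <- 220
  region <- disk_mask(n, 55, 110, 28) | disk_mask(n, 110, 110, 28) |
    disk_mask(n, 165, 110, 28)
  region[55:165, 104:116] <- TRUE
  nuclei <- matrix(0L, n, n)
  nuclei[disk_mask(n, 55, 110, 9)] <- 1L
  nuclei[disk_mask(n, 110, 110, 9)] <- 2L
  nuclei[disk_mask(n, 165, 110, 9)] <- 3L
  intensity <- matrix(0, n, n); intensity[region] <- 1000
  out <- suppressMessages(resolve_undersegmentation(region, nuclei, intensity, 500))
  expect_equal(max(out), 3L)
  expect_true(all(out[region] > 0L))
  expect_error(
    resolve_undersegmentation(disk_mask(64, 32, 32, 10),
                              matrix(0L, 64, 64), matrix(1, 64, 64), 0.5),
    "at least 2 nuclei")
})

test_that("high-threshold seeds are used when they exist for every nucleus", {
  n <- 160
  region <- disk_mask(n, 50, 80, 26) | disk_mask(n, 110, 80, 26)
  region[48:112, 76:84] <- TRUE
  nuclei <- matrix(0L, n, n)
  nuclei[disk_mask(n, 50, 80, 8)] <- 1L
  nuclei[disk_mask(n, 110, 80, 8)] <- 2L
  intensity <- matrix(0, n, n); intensity[region] <- 600
  intensity[disk_mask(n, 50, 80, 14)] <- 2000  # bright cores above 1.5x threshold
  intensity[disk_mask(n, 110, 80, 14)] <- 2000
  expect_no_message(
    out <- resolve_undersegmentation(region, nuclei, intensity, 500))
  expect_equal(max(out), 2L)
  expect_true(all(out[region] > 0L))
})
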