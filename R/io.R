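#' Read a three-channel stack from a multi-page TIFF
#'
#' Pages are read in order cytoplasm, nuclei, adhesion and rescaled from
#' the [0, 1] convention of the tiff package back to 16-bit intensity
#' units.
#'
#' @param path TIFF file with at least three pages.
#' @return list with `cytoplasm`, `nuclei`, `adhesion` matrices.
#' @export
read_channel_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF stacks")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 3) stop("expected a 3-page TIFF (cytoplasm, nuclei, adhesion)")
  ch <- lapply(pages[1:3], function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    matrix(p * 65535, nrow(p), ncol(p))
  })
  names(ch) <- c("cytoplasm", "nuclei", "adhesion")
  ch
}

#' Write a three-channel stack as a 16-bit multi-page TIFF
#'
#' Page order: cytoplasm, nuclei, adhesion.
#'
#' @param channels list with `cytoplasm`, `nuclei`, `adhesion` matrices in
#'   16-bit intensity units.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_channel_stack <- function(channels, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF stacks")
  if (inherits(channels, "synthetic_scene")) channels <- channels$channels
  pages <- lapply(channels[c("cytoplasm", "nuclei", "adhesion")],
                  function(m) pmin(pmax(m / 65535, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read or write an integer label map as 16-bit TIFF
#'
#' @param lab integer label matrix (values up to 65535).
#' @param path file path.
#' @return `read_label_map` returns an integer matrix; `write_label_map`
#'   returns `path` invisibly.
#' @export
write_label_map <- function(lab, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF label maps")
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF label maps")
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3) p <- p[, , 1]
  matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
}
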