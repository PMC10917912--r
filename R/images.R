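# Image reading, resizing, normalization, dataset statistics.

#' Read a PNG or JPEG image as an H x W x 3 array in [0, 1]
#'
#' Grayscale images are replicated to 3 channels; an alpha channel is
#' dropped.
#'
#' @param path file path ending in .png, .jpg or .jpeg.
#' @return `H x W x 3` numeric array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, " (expected PNG or JPEG)")
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  img
}

#' Bilinear resize of an H x W x C image array
#'
#' @param img `H x W x C` array.
#' @param oh,ow output height and width.
#' @return Resized array.
#' @export
resize_bilinear <- function(img, oh, ow) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  if (H == oh && W == ow) return(img)
  coord <- function(n_in, n_out) {
    # align-centers convention
    p <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    p <- pmin(pmax(p, 1), n_in)
    lo <- pmin(floor(p), n_in - 1L)
    if (n_in == 1L) lo <- rep(1, n_out)
    list(lo = lo, hi = pmin(lo + 1L, n_in), w = p - lo)
  }
  cy <- coord(H, oh); cx <- coord(W, ow)
  out <- array(0, c(oh, ow, d[3]))
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    top <- m[cy$lo, , drop = FALSE] * (1 - cy$w) + m[cy$hi, , drop = FALSE] * cy$w
    out[, , ch] <- top[, cx$lo, drop = FALSE] * (1 - cx$w) +
      top[, cx$hi, drop = FALSE] * cx$w
  }
  out
}

#' Channel-wise normalization of an image batch
#'
#' @param x `H x W x 3 x N` array of images in `[0, 1]`.
#' @param mean,std RGB triples; defaults are the dataset-level statistics
#'   used by the reference experiments.
#' @return Normalized array `(x - mean) / std`.
#' @export
normalize_images <- function(x, mean = pi_norm_stats()$mean,
                             std = pi_norm_stats()$std) {
  d <- dim(x)
  stopifnot(length(d) == 4L, d[3] == 3L)
  for (ch in 1:3) x[, , ch, ] <- (x[, , ch, ] - mean[ch]) / std[ch]
  x
}

#' Per-channel mean and standard deviation of an image set
#'
#' Accepts either an in-memory batch or a class-per-folder directory of
#' images (the `stats` CLI subcommand calls this).
#'
#' @param x `H x W x 3 x N` array, or a directory path.
#' @param image_size when reading from disk, side length images are resized
#'   to first (`NULL` keeps native sizes; statistics are then weighted by
#'   pixel count).
#' @return A tibble with columns `channel`, `mean`, `sd`.
#' @export
dataset_stats <- function(x, image_size = NULL) {
  if (is.character(x)) {
    ds <- load_image_folder(x, image_size = image_size %||% 64L)
    x <- ds$x
  }
  d <- dim(x)
  stopifnot(length(d) == 4L, d[3] == 3L)
  tibble::tibble(
    channel = c("R", "G", "B"),
    mean = vapply(1:3, function(ch) mean(x[, , ch, ]), numeric(1)),
    sd = vapply(1:3, function(ch) stats::sd(x[, , ch, ]), numeric(1))
  )
}

#' Load a class-per-folder image dataset
#'
#' Expects `root/stage1 ... root/stageK` (any folder names; sorted order
#' defines class indices) containing PNG/JPEG images.
#'
#' @param root dataset root directory.
#' @param image_size side length to resize every image to (default 224).
#' @return A list with `x` (`S x S x 3 x N` array), `y` (integer class
#'   labels, 1-based), and `manifest` (tibble: path, class, label).
#' @export
load_image_folder <- function(root, image_size = 224L) {
  stopifnot(dir.exists(root))
  classes <- sort(list.dirs(root, recursive = FALSE))
  if (length(classes) == 0L) stop("no class folders under ", root)
  files <- lapply(classes, function(d) {
    sort(list.files(d, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                    full.names = TRUE))
  })
  n <- sum(lengths(files))
  if (n == 0L) stop("no images found under ", root)
  x <- array(0, c(image_size, image_size, 3L, n))
  y <- integer(n)
  paths <- character(n)
  i <- 0L
  for (cls in seq_along(classes)) {
    for (f in files[[cls]]) {
      i <- i + 1L
      x[, , , i] <- resize_bilinear(read_image(f), image_size, image_size)
      y[i] <- cls
      paths[i] <- f
    }
  }
  list(x = x, y = y,
       manifest = tibble::tibble(path = paths, class = basename(classes)[y],
                                 label = y))
}
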