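#' Specification for the synthetic skin-lesion image generator
#'
#' The generator emulates the premise of pressure-injury staging: four
#' visually similar classes sharing one background (skin) distribution and
#' differing only in fine lesion cues — colour, edge sharpness, interior
#' structure and texture.  Class archetypes (at full separability):
#' stage 1, a diffuse reddish patch with intact texture; stage 2, a small
#' sharp-edged pale break; stage 3, a crater with a dark core and a
#' granular ring; stage 4, a large dark region with a high-contrast rim.
#'
#' The `separability` scalar in `[0, 1]` linearly interpolates every
#' class-specific lesion parameter between the across-class mean (0: all
#' classes draw from one shared distribution, so classifiers can only reach
#' chance) and the distinct archetypes (1: maximally distinct classes).
#' Backgrounds never depend on the class, forcing classifiers to use lesion
#' features.  All randomness comes from one stream seeded by `seed`, so a
#' spec determines its dataset byte-for-byte.
#'
#' This is a test fixture built for determinism and speed — parametric
#' ellipses/annuli with octave value-noise texture — not a clinical
#' simulator.
#'
#' @param per_class images per class; scalar or length-4 vector.
#' @param image_size square image side in pixels.
#' @param separability class-separability scalar in `[0, 1]`.
#' @param noise pixel-noise standard deviation (image units).
#' @param seed integer RNG seed.
#' @param base_tone background skin tone (RGB in `[0, 1]`).
#' @param tone_jitter half-range of the per-image uniform tone jitter.
#' @return A list of class `wfpn_synth_spec`.
#' @export
synthetic_spec <- function(per_class = 50L, image_size = 64L,
                           separability = 1, noise = 0.05, seed = 1L,
                           base_tone = c(0.72, 0.55, 0.47),
                           tone_jitter = 0.06) {
  if (length(per_class) == 1L) per_class <- rep(per_class, 4L)
  stopifnot(length(per_class) == 4L, all(per_class >= 0L),
            image_size >= 16L,
            separability >= 0, separability <= 1, noise >= 0)
  structure(list(per_class = as.integer(per_class),
                 image_size = as.integer(image_size),
                 separability = separability, noise = noise,
                 seed = as.integer(seed),
                 base_tone = base_tone, tone_jitter = tone_jitter),
            class = "wfpn_synth_spec")
}

# class archetype parameters (rows: parameter, cols: stage 1..4)
synth_class_params <- function(separability) {
  p <- rbind(
    lesion_r    = c(0.60, 0.35, 0.45, 0.30),  # lesion colour R
    lesion_g    = c(0.25, 0.52, 0.28, 0.12),  # lesion colour G
    lesion_b    = c(0.25, 0.48, 0.18, 0.10),  # lesion colour B
    alpha       = c(0.45, 0.85, 0.90, 0.95),  # blend opacity
    sharpness   = c(2.50, 14.0, 8.00, 10.0),  # edge steepness
    size        = c(0.30, 0.14, 0.24, 0.38),  # mean radius, fraction of side
    core_dark   = c(0.00, 0.05, 0.55, 0.40),  # darkening of the inner core
    ring_tex    = c(0.02, 0.03, 0.22, 0.06),  # granular ring amplitude
    rim_bright  = c(0.00, 0.02, 0.05, 0.30)   # high-contrast rim strength
  )
  shared <- rowMeans(p)
  shared + separability * (p - shared)
}

# seeded octave value noise on an n x n grid, values roughly in [-1, 1]
value_noise <- function(n, octaves = 3L, base_cells = 4L) {
  acc <- matrix(0, n, n)
  amp <- 1
  cells <- base_cells
  for (o in seq_len(octaves)) {
    g <- matrix(stats::runif(cells * cells, -1, 1), cells, cells)
    up <- resize_bilinear(array(g, c(cells, cells, 1L)), n, n)[, , 1]
    acc <- acc + amp * up
    amp <- amp / 2
    cells <- min(n, cells * 2L)
  }
  acc / 1.75
}

# render one image for class `cls` under interpolated params `pc`
render_lesion_image <- function(size, pc, cls, base_tone, tone_jitter, noise) {
  tone <- base_tone + stats::runif(3, -tone_jitter, tone_jitter)
  img <- array(rep(tone, each = size * size), c(size, size, 3L))
  bgn <- value_noise(size)
  for (ch in 1:3) img[, , ch] <- img[, , ch] + 0.05 * bgn
  # elliptical distance field, random placement and orientation
  cx <- stats::runif(1, 0.38, 0.62) * size
  cy <- stats::runif(1, 0.38, 0.62) * size
  r <- pc["size", cls] * size * stats::runif(1, 0.8, 1.2)
  ecc <- stats::runif(1, 0.7, 1)
  th <- stats::runif(1, 0, pi)
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
  v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
  dist <- sqrt((u / r)^2 + (v / (r * ecc))^2)
  mask <- 1 / (1 + exp((dist - 1) * pc["sharpness", cls]))
  tex <- value_noise(size, octaves = 4L, base_cells = 8L)
  core <- 1 / (1 + exp((dist - 0.45) * 10))          # inner core region
  ring <- exp(-((dist - 0.75)^2) / 0.035)            # granular annulus
  rim <- exp(-((dist - 1)^2) / 0.008)                # thin bright rim
  lesion_col <- pc[c("lesion_r", "lesion_g", "lesion_b"), cls]
  a <- pc["alpha", cls] * mask
  for (ch in 1:3) {
    plane <- img[, , ch] * (1 - a) + lesion_col[ch] * a
    plane <- plane - pc["core_dark", cls] * core * mask * lesion_col[ch]
    plane <- plane + pc["ring_tex", cls] * ring * mask * tex
    plane <- plane + pc["rim_bright", cls] * rim
    img[, , ch] <- plane
  }
  img <- img + array(stats::rnorm(size * size * 3, sd = noise),
                     c(size, size, 3L))
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a synthetic dataset in memory
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `x` (`S x S x 3 x N` array, values in `[0, 1]`),
#'   `y` (integer labels 1..4, class-blocked order) and `params` (tibble of
#'   per-image generation parameters).
#' @examples
#' d <- generate_images(synthetic_spec(per_class = 2, image_size = 32))
#' dim(d$x)
#' @export
generate_images <- function(spec) {
  stopifnot(inherits(spec, "wfpn_synth_spec"))
  n <- sum(spec$per_class)
  if (n == 0L) stop("zero total images requested")
  pc <- synth_class_params(spec$separability)
  x <- array(0, c(spec$image_size, spec$image_size, 3L, n))
  y <- integer(n)
  withr::with_seed(spec$seed, {
    i <- 0L
    for (cls in 1:4) {
      for (j in seq_len(spec$per_class[cls])) {
        i <- i + 1L
        x[, , , i] <- render_lesion_image(spec$image_size, pc, cls,
                                          spec$base_tone, spec$tone_jitter,
                                          spec$noise)
        y[i] <- cls
      }
    }
  })
  params <- tibble::tibble(
    index = seq_len(n), label = y, class = paste0("stage", y),
    separability = spec$separability, noise = spec$noise,
    image_size = spec$image_size, seed = spec$seed
  )
  list(x = x, y = y, params = params)
}

#' Write a synthetic dataset as a class-per-folder PNG tree
#'
#' Writes `stage1/ ... stage4/` PNG folders plus `manifest.csv` (path,
#' class, generation parameters) under `out_dir`.  Fully determined by the
#' spec seed: the same spec writes byte-identical trees.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created; must be writable).
#' @return The manifest tibble, invisibly.
#' @export
generate_dataset <- function(spec, out_dir) {
  d <- generate_images(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  paths <- character(length(d$y))
  for (cls in 1:4) {
    dir.create(file.path(out_dir, paste0("stage", cls)), showWarnings = FALSE)
  }
  counter <- integer(4)
  for (i in seq_along(d$y)) {
    cls <- d$y[i]
    counter[cls] <- counter[cls] + 1L
    paths[i] <- file.path(paste0("stage", cls),
                          sprintf("img_%04d.png", counter[cls]))
    png::writePNG(d$x[, , , i], file.path(out_dir, paths[i]))
  }
  manifest <- dplyr::mutate(d$params, path = paths, .before = 1L)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"),
                   progress = FALSE)
  invisible(manifest)
}
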