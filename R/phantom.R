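# Synthetic CT-like phantom slices.  A phantom emulates the qualitative
# features that make liver-tumor CT hard: a large smooth "liver" region, a
# variable number of small low-contrast "tumor" blobs with blurred
# boundaries, and additive noise.  The label mask is the exact pre-blur
# geometry, so ground truth is known to the pixel.  Generation is a pure
# function of the seed.

#' Phantom slice specification
#'
#' Defaults are in windowed-intensity units (the `[0, 1]` scale produced by
#' [hu_window()]): background 0.20, liver +0.35 above background, tumors 0.12
#' *below* liver (tumors are hypodense and deliberately low-contrast), a
#' 1.5-pixel Gaussian boundary blur and noise sd 0.03.  The tumor radius
#' range 2-12 px deliberately includes tumors only a few pixels across.
#'
#' @param height,width slice size; both divisible by 16.
#' @param liver_axes range of the liver-ellipse semi-axes in pixels; default
#'   `c(0.28, 0.42) * min(height, width)`.
#' @param n_tumors inclusive integer range for the tumor count (default 0-3).
#' @param tumor_radius tumor radius range in pixels (default 2-12).
#' @param background_intensity,liver_contrast,tumor_contrast intensity of the
#'   background and the additive offsets of liver and tumor regions.
#' @param boundary_blur_sigma Gaussian blur applied to the rendered intensity
#'   image (pixels, > 0): emulates fuzzy boundaries.
#' @param noise_sigma additive Gaussian noise sd (>= 0).
#' @param seed integer; the phantom is a pure function of this seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64L, width = 64L, liver_axes = NULL,
                         n_tumors = c(0L, 3L), tumor_radius = c(2, 12),
                         background_intensity = 0.20, liver_contrast = 0.35,
                         tumor_contrast = -0.12, boundary_blur_sigma = 1.5,
                         noise_sigma = 0.03, seed = 1L) {
  if (height %% 16L != 0L || width %% 16L != 0L)
    stop("phantom height and width must be divisible by 16")
  if (boundary_blur_sigma <= 0) stop("'boundary_blur_sigma' must be > 0")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  liver_axes <- liver_axes %||% (c(0.28, 0.42) * min(height, width))
  structure(list(height = as.integer(height), width = as.integer(width),
                 liver_axes = liver_axes, n_tumors = as.integer(n_tumors),
                 tumor_radius = tumor_radius,
                 background_intensity = background_intensity,
                 liver_contrast = liver_contrast,
                 tumor_contrast = tumor_contrast,
                 boundary_blur_sigma = boundary_blur_sigma,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# separable Gaussian blur with row-normalized band matrices (no darkening at
# the image border)
gaussian_blur <- function(img, sigma) {
  band <- function(n) {
    r <- ceiling(3 * sigma)
    K <- matrix(0, n, n)
    for (o in -r:r) {
      w <- exp(-o^2 / (2 * sigma^2))
      idx <- seq_len(n)
      j <- idx + o
      ok <- j >= 1 & j <= n
      K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + w
    }
    K / rowSums(K)
  }
  band(nrow(img)) %*% img %*% t(band(ncol(img)))
}

#' Generate a synthetic phantom slice
#'
#' Renders one CT-like slice and its exact integer label mask from a
#' [phantom_spec()].  Tumor blobs are placed entirely inside the liver
#' ellipse (placement is re-sampled up to 100 times per tumor, then an error
#' is raised if the radius cannot fit).  The same spec (same seed) always
#' produces a bitwise-identical slice.
#'
#' @param spec a [phantom_spec()].
#' @return a slice pair: `list(image, mask, provenance)` where `image` is an
#'   `H x W` matrix, `mask` an `H x W` integer matrix over
#'   `{0 = background, 1 = liver, 2 = tumor}`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    cy <- H / 2 + runif(1, -0.05, 0.05) * H
    cx <- W / 2 + runif(1, -0.05, 0.05) * W
    a <- runif(1, spec$liver_axes[1], spec$liver_axes[2])  # row semi-axis
    b <- runif(1, spec$liver_axes[1], spec$liver_axes[2])  # col semi-axis
    th <- runif(1, 0, pi)
    yy <- matrix(seq_len(H), H, W) - cy
    xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
    u <- yy * cos(th) + xx * sin(th)
    v <- -yy * sin(th) + xx * cos(th)
    liver <- (u / a)^2 + (v / b)^2 <= 1
    mask <- matrix(0L, H, W)
    mask[liver] <- 1L
    nt <- if (spec$n_tumors[1] == spec$n_tumors[2]) spec$n_tumors[1] else
      sample(spec$n_tumors[1]:spec$n_tumors[2], 1)
    tumors <- list()
    for (k in seq_len(nt)) {
      r <- runif(1, spec$tumor_radius[1], spec$tumor_radius[2])
      r <- min(r, 0.8 * min(a, b), min(a, b) - 2)
      # admissible centers form the liver ellipse shrunk by r plus a
      # one-pixel margin (keeps the discretized blob strictly interior)
      sa <- a - r - 1; sb <- b - r - 1
      if (r < spec$tumor_radius[1] / 2 || sa <= 0 || sb <= 0)
        stop(sprintf("could not place a tumor of radius %.1f inside the liver ellipse", r))
      placed <- FALSE
      for (try in 1:100) {
        tu <- runif(1, -sa, sa)
        tv <- runif(1, -sb, sb)
        if ((tu / sa)^2 + (tv / sb)^2 <= 1) {
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("could not place a tumor of radius %.1f inside the liver ellipse", r))
      ty <- cy + tu * cos(th) - tv * sin(th)
      tx <- cx + tu * sin(th) + tv * cos(th)
      tum <- (matrix(seq_len(H), H, W) - ty)^2 +
        (matrix(seq_len(W), H, W, byrow = TRUE) - tx)^2 <= r^2
      mask[tum] <- 2L
      tumors[[k]] <- list(center = c(ty, tx), radius = r)
    }
    img <- spec$background_intensity +
      spec$liver_contrast * (mask >= 1L) +
      spec$tumor_contrast * (mask == 2L)
    img <- gaussian_blur(img, spec$boundary_blur_sigma)
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(H * W, sd = spec$noise_sigma), H, W)
    list(image = img, mask = mask,
         provenance = list(volume = "phantom", slice = spec$seed,
                           tumors = tumors))
  })
}

#' Generate a phantom dataset
#'
#' Convenience wrapper producing `n` slices with per-slice seeds
#' `seed, seed + 1, ...` so the set is reproducible and each slice is
#' independently a pure function of its own seed.
#'
#' @param n number of slices.
#' @param spec template [phantom_spec()]; its `seed` field is overridden
#'   per slice.
#' @param seed first per-slice seed.
#' @return list of slice pairs (see [generate_phantom()]).
#' @export
generate_phantom_dataset <- function(n, spec = phantom_spec(), seed = 1L) {
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- as.integer(seed + i - 1L)
    generate_phantom(s)
  })
}
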