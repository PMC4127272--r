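# Seeded anatomical phantoms: piecewise-near-constant images with large
# homogeneous regions (high run-length redundancy), optional smooth
# gradient, and optional additive Gaussian noise. They emulate the kind of
# flat-background medical scans the codec targets without modeling any
# acquisition physics.

#' Specify a synthetic phantom
#'
#' @param dim Image dims `c(m, n)` (default 512 x 512).
#' @param regions Number of elliptical/rectangular regions `R >= 0`
#'   (default 4).
#' @param palette Number of distinct intensity levels available (background
#'   plus region intensities; default 5).
#' @param background_fraction Target fraction of pixels left as flat
#'   background, in `[0, 1)` (default 0.7): the redundancy knob.
#' @param gradient_amplitude Peak-to-peak amplitude of an additive smooth
#'   horizontal ramp, in intensity levels (default 0; any positive value
#'   adds roughly that many extra distinct values and shortens runs).
#' @param noise_sigma Gaussian noise standard deviation added before
#'   rounding (default 0; noise destroys runs, a documented stress case).
#' @param shapes Region shapes to draw from (`"ellipse"`, `"rectangle"`).
#' @param seed Integer seed; identical spec + seed gives identical images.
#' @return A list of class `sbpn_phantom_spec`.
#' @export
phantom_spec <- function(dim = c(512L, 512L), regions = 4L, palette = 5L,
                         background_fraction = 0.7, gradient_amplitude = 0,
                         noise_sigma = 0, shapes = c("ellipse", "rectangle"),
                         seed = 1L) {
  dim <- as.integer(dim)
  if (length(dim) != 2L || any(dim < 1L)) stop_argument("dim must be two positive integers")
  if (!is.numeric(regions) || regions < 0 || regions != floor(regions)) {
    stop_argument("regions must be a non-negative integer")
  }
  if (palette < 2L) stop_argument("palette must have at least 2 levels")
  if (background_fraction < 0 || background_fraction >= 1) {
    stop_argument("background_fraction must be in [0, 1)")
  }
  if (noise_sigma < 0) stop_argument("noise_sigma must be >= 0")
  if (!all(shapes %in% c("ellipse", "rectangle"))) {
    stop_argument("shapes must be among 'ellipse', 'rectangle'")
  }
  structure(
    list(dim = dim, regions = as.integer(regions), palette = as.integer(palette),
         background_fraction = background_fraction,
         gradient_amplitude = gradient_amplitude, noise_sigma = noise_sigma,
         shapes = shapes, seed = as.integer(seed)),
    class = "sbpn_phantom_spec"
  )
}

#' Generate a phantom image
#'
#' Flat background plus `regions` overlapping quantized regions whose total
#' area targets `(1 - background_fraction) * m * n`, then an optional
#' smooth gradient and Gaussian noise; the result is clipped to \[0, 255\]
#' and rounded once. Region layout depends only on the seed, and region
#' sizes scale with the foreground budget, so sweeping
#' `background_fraction` under a fixed seed produces nested layouts with
#' monotonically varying run-length redundancy.
#'
#' @param spec A [phantom_spec()].
#' @return A [gray_image].
#' @examples
#' img <- generate_phantom(phantom_spec(dim = c(64, 64), seed = 7))
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "sbpn_phantom_spec")) stop_argument("spec must be a phantom_spec()")
  m <- spec$dim[1]; n <- spec$dim[2]
  with_seed(spec$seed, {
    levels <- sort(sample(15:240, spec$palette))
    bg <- levels[1L]
    img <- matrix(as.numeric(bg), m, n)
    if (spec$regions > 0L) {
      fg_area <- (1 - spec$background_fraction) * m * n
      w <- stats::runif(spec$regions, 0.5, 1.5)
      areas <- w / sum(w) * fg_area
      # row/col coordinate grids for mask rasterization
      rows <- matrix(seq_len(m), m, n)
      cols <- matrix(seq_len(n), m, n, byrow = TRUE)
      for (r in seq_len(spec$regions)) {
        shape <- sample(spec$shapes, 1L)
        val <- sample(levels[-1L], 1L)
        cy <- stats::runif(1, 0.2, 0.8) * m
        cx <- stats::runif(1, 0.2, 0.8) * n
        aspect <- stats::runif(1, 0.5, 2)
        if (shape == "ellipse") {
          a <- sqrt(areas[r] / pi * aspect)   # semi-axes
          b <- areas[r] / pi / a
          if (2 * a > max(m, n) || 2 * b > max(m, n)) {
            stop_argument("region %d larger than the image: shrink regions or background_fraction", r)
          }
          th <- stats::runif(1, 0, pi)
          dy <- rows - cy; dx <- cols - cx
          u <- cos(th) * dx + sin(th) * dy
          v <- -sin(th) * dx + cos(th) * dy
          mask <- (u / a)^2 + (v / b)^2 <= 1
        } else {
          h <- sqrt(areas[r] * aspect)
          wd <- areas[r] / h
          if (h > m || wd > n) {
            stop_argument("region %d larger than the image: shrink regions or background_fraction", r)
          }
          mask <- abs(rows - cy) <= h / 2 & abs(cols - cx) <= wd / 2
        }
        img[mask] <- val
      }
    }
    if (spec$gradient_amplitude > 0) {
      ramp <- spec$gradient_amplitude * (seq_len(n) - 1) / max(1, n - 1)
      img <- img + matrix(ramp, m, n, byrow = TRUE)
    }
    if (spec$noise_sigma > 0) {
      img <- img + stats::rnorm(m * n, 0, spec$noise_sigma)
    }
    gray_image(pmin(pmax(round_half_away(img), 0), 255))
  })
}

#' Generate a reproducible suite of phantoms
#'
#' Stands in for a panel of test samples: `n_images` phantoms from
#' per-image seeds derived deterministically from `seed`. A
#' `background_sweep` (optional) overrides the base spec's background
#' fraction per image while keeping the same layout seed, producing a
#' controlled redundancy sweep.
#'
#' @param n_images Number of phantoms.
#' @param base_spec A [phantom_spec()] used as template.
#' @param seed Suite seed.
#' @param background_sweep Optional numeric vector of length `n_images`.
#' @param vary_layout If `TRUE` (default) each image gets its own derived
#'   layout seed; set `FALSE` to keep one layout across the sweep.
#' @return A named list of [gray_image]s (`Q1`, `Q2`, ...).
#' @export
generate_suite <- function(n_images, base_spec = phantom_spec(), seed = 1L,
                           background_sweep = NULL, vary_layout = TRUE) {
  if (!is_count(n_images)) stop_argument("n_images must be a positive integer")
  if (!is.null(background_sweep) && length(background_sweep) != n_images) {
    stop_argument("background_sweep must have one value per image")
  }
  imgs <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- base_spec
    sp$seed <- if (vary_layout) {
      as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
    } else {
      as.integer(seed)
    }
    if (!is.null(background_sweep)) sp$background_fraction <- background_sweep[i]
    imgs[[i]] <- generate_phantom(sp)
  }
  names(imgs) <- sprintf("Q%d", seq_len(n_images))
  imgs
}
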