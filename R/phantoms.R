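# Synthetic test objects and noise models, so every stage of the pipeline is
# testable without external data.

#' Generate a synthetic phantom volume
#'
#' Three kinds are provided:
#' * `"vesicle"`: nested soft-edged ellipsoidal shells (membrane-like) with
#'   `n_features` Gaussian blobs of interior substructure -- a stand-in for a
#'   biological vesicle.
#' * `"blobs"`: a sum of `n_features` random Gaussian blobs (smooth generic
#'   object).
#' * `"dots"`: sparse hard spheres on a jittered lattice (atomic-resolution
#'   stand-in).
#'
#' All phantoms are nonnegative, reproducible from `(size, kind, n_features,
#' seed, smoothness)`, and have all mass inside the centered
#' `(0.8 * size)^3` cube so that a loose cubic support contains them with
#' margin.
#'
#' @param size voxels per side (>= 8, even recommended; default 64).
#' @param kind one of `"vesicle"`, `"blobs"`, `"dots"`.
#' @param n_features number of interior blobs / blobs / spheres (defaults
#'   per kind: 4, 6, 40).
#' @param seed integer seed; the same spec always yields the same volume.
#' @param smoothness Gaussian blur sigma in voxels applied at the end
#'   (defaults per kind: 1, 0, 0.5).
#' @return a nonnegative `size^3` array.
#' @export
make_phantom <- function(size = 64L, kind = c("vesicle", "blobs", "dots"),
                         n_features = NULL, seed = 0L, smoothness = NULL) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 8L) stop_invalid("'size' must be >= 8")
  n_features <- as.integer(n_features %||%
                             switch(kind, vesicle = 4L, blobs = 6L, dots = 40L))
  if (n_features < 1L) stop_invalid("'n_features' must be >= 1")
  smoothness <- smoothness %||% switch(kind, vesicle = 1, blobs = 0, dots = 0.5)

  ax <- seq_len(size) - (floor(size / 2) + 1)  # centered voxel coordinates
  vol <- with_seed(seed, switch(
    kind,
    vesicle = phantom_vesicle(ax, size, n_features),
    blobs = phantom_blobs(ax, size, n_features),
    dots = phantom_dots(ax, size, n_features)
  ))
  if (smoothness > 0) {
    vol <- gaussian_blur3(vol, smoothness)
    vol[vol < 0] <- 0
  }
  # hard support margin: everything inside the centered (0.8 size)^3 cube
  margin <- abs(ax) <= 0.4 * size
  keep <- outer(outer(margin, margin, `&`), margin, `&`)
  vol[!keep] <- 0
  vol
}

gaussian_blob <- function(ax, center, sigma, amp) {
  gx <- exp(-(ax - center[1])^2 / (2 * sigma^2))
  gy <- exp(-(ax - center[2])^2 / (2 * sigma^2))
  gz <- exp(-(ax - center[3])^2 / (2 * sigma^2))
  amp * outer(outer(gx, gy), gz)
}

phantom_vesicle <- function(ax, size, n_features) {
  # two nested ellipsoidal shells with Gaussian radial profiles
  radii_out <- size * (0.30 + runif(3, -0.03, 0.03))
  radii_in <- 0.55 * radii_out
  x <- array(ax, c(size, size, size))
  y <- array(rep(ax, each = size), c(size, size, size))
  z <- array(rep(ax, each = size * size), c(size, size, size))
  rho_out <- sqrt((x / radii_out[1])^2 + (y / radii_out[2])^2 + (z / radii_out[3])^2)
  rho_in <- sqrt((x / radii_in[1])^2 + (y / radii_in[2])^2 + (z / radii_in[3])^2)
  w <- 0.05
  vol <- exp(-((rho_out - 1) / w)^2) + 0.8 * exp(-((rho_in - 1) / (1.4 * w))^2)
  for (i in seq_len(n_features)) {
    center <- runif(3, -0.25, 0.25) * radii_in
    sigma <- runif(1, size / 40, size / 25)
    vol <- vol + gaussian_blob(ax, center, sigma, runif(1, 0.4, 0.9))
  }
  vol
}

phantom_blobs <- function(ax, size, n_features) {
  vol <- array(0, c(size, size, size))
  for (i in seq_len(n_features)) {
    center <- runif(3, -0.2, 0.2) * size
    sigma <- size * runif(1, 1 / 24, 1 / 16)
    vol <- vol + gaussian_blob(ax, center, sigma, runif(1, 0.5, 1))
  }
  vol
}

phantom_dots <- function(ax, size, n_features) {
  pitch <- max(4, round(size / 8))
  g <- seq(-0.3 * size, 0.3 * size, by = pitch)
  sites <- as.matrix(expand.grid(g, g, g))
  sites <- sites[sample(nrow(sites)), , drop = FALSE]
  n <- min(n_features, nrow(sites))
  vol <- array(0, c(size, size, size))
  x <- array(ax, c(size, size, size))
  y <- array(rep(ax, each = size), c(size, size, size))
  z <- array(rep(ax, each = size * size), c(size, size, size))
  for (i in seq_len(n)) {
    c0 <- sites[i, ] + runif(3, -1, 1)
    r <- runif(1, 1.2, 1.6)
    vol <- vol + ((x - c0[1])^2 + (y - c0[2])^2 + (z - c0[3])^2 <= r^2)
  }
  vol
}

#' Add simulated noise to a tilt series
#'
#' The noise `level` is dimensionless and relative to the mean positive pixel
#' value of the stack, so settings transfer across phantoms:
#' * `"gaussian"`: adds zero-mean Gaussian noise with standard deviation
#'   `level * mean(pixels > 0)`.
#' * `"poisson_gaussian"`: scales the images to counts such that the mean
#'   positive pixel equals `1/level^2` counts, draws Poisson noise, rescales
#'   back, and adds Gaussian read noise at 10% of the count-noise standard
#'   deviation.
#'
#' @param series a [tilt_series()].
#' @param model `"gaussian"` or `"poisson_gaussian"`.
#' @param level nonnegative noise level; `level = 0` returns the input
#'   unchanged.
#' @param seed integer seed (same seed, same noise).
#' @return a `tilt_series` with noisy projections.
#' @export
add_noise <- function(series, model = c("gaussian", "poisson_gaussian"),
                      level = 0.1, seed = 0L) {
  model <- match.arg(model)
  if (!inherits(series, "tilt_series")) stop_invalid("'series' must be a tilt_series")
  if (!is.finite(level) || level < 0) stop_invalid("'level' must be >= 0")
  if (level == 0) return(series)
  p <- series$projections
  mpp <- mean(p[p > 0])
  if (!is.finite(mpp) || mpp <= 0) stop_invalid("series has no positive pixels")
  with_seed(seed, {
    if (model == "gaussian") {
      p <- p + rnorm(length(p), sd = level * mpp)
    } else {
      s <- 1 / (level^2 * mpp)  # counts per intensity unit
      counts <- rpois(length(p), pmax(p, 0) * s)
      read_sd <- 0.1 * level * mpp
      p <- array(counts / s + rnorm(length(p), sd = read_sd), dim(p))
    }
  })
  series$projections <- array(p, dim(series$projections))
  series
}
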