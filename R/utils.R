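# Internal numerical helpers shared across modules.

#' @useDynLib fouriertomo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft rnorm runif rpois sd
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("invalid_argument", "error")))
}

# circular index shifts putting the DC element at floor(n/2)+1 (fftshift)
# or back at 1 (ifftshift); floor conventions so odd sizes round-trip.
shift_indices <- function(d, inverse = FALSE) {
  lapply(d, function(n) {
    s <- if (inverse) floor(n / 2) else -floor(n / 2)
    ((seq_len(n) - 1L + s) %% n) + 1L
  })
}

apply_index <- function(x, idx) {
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

fftshift <- function(x) {
  d <- dim(x) %||% length(x)
  apply_index(x, shift_indices(d, inverse = FALSE))
}

ifftshift <- function(x) {
  d <- dim(x) %||% length(x)
  apply_index(x, shift_indices(d, inverse = TRUE))
}

# FFT wrappers: forward unnormalized, inverse normalized by 1/prod(dim).
# fftwtools matches stats::fft conventions bit-for-bit; the 3D/2D entry
# points are substantially faster than stats::fft at the grid sizes used
# by the reconstructor.
fft3 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  if (is.complex(x)) {
    fftwtools::fftw_c2c_3d(x)
  } else {
    fftwtools::fftw_r2c_3d(x)
  }
}

ifft3 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  if (!is.complex(x)) x <- x + 0i
  fftwtools::fftw_c2c_3d(x, inverse = 1) / prod(d)
}

fft2 <- function(x) {
  if (is.complex(x)) fftwtools::fftw_c2c_2d(x) else fftwtools::fftw_r2c_2d(x)
}

ifft2 <- function(x) {
  if (!is.complex(x)) x <- x + 0i
  fftwtools::fftw_c2c_2d(x, inverse = 1) / length(x)
}

# centered transforms: DC voxel at floor(M/2)+1 on each axis
cfft3 <- function(x) fftshift(fft3(ifftshift(x)))
cifft3 <- function(x) fftshift(ifft3(ifftshift(x)))
cfft2 <- function(x) fftshift(fft2(ifftshift(x)))
cifft2 <- function(x) fftshift(ifft2(ifftshift(x)))

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Crop the centered n^d block out of an array, preserving the DC-at-floor(M/2)+1
# convention (the cropped block's center voxel is the original center voxel).
crop_center <- function(x, n) {
  d <- dim(x)
  idx <- lapply(d, function(m) {
    start <- floor(m / 2) - floor(n / 2) + 1L
    seq.int(start, length.out = n)
  })
  apply_index(x, idx)
}

# Embed an array centered inside a zero block of side m.
embed_center <- function(x, m) {
  d <- dim(x)
  out <- array(if (is.complex(x)) 0i else 0, dim = rep(m, length(d)))
  idx <- lapply(d, function(n) {
    start <- floor(m / 2) - floor(n / 2) + 1L
    seq.int(start, length.out = n)
  })
  out <- do.call(`[<-`, c(list(out), idx, list(value = x)))
  out
}

# standard-layout signed frequency coordinates, in voxel units
freq_coords <- function(n) {
  s <- floor(n / 2)
  ((seq_len(n) - 1L + s) %% n) - s
}

# Gaussian blur of a 3D array by Fourier multiplication (periodic edges;
# callers keep mass away from the boundary).
gaussian_blur3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  f1 <- freq_coords(d[1]) / d[1]
  f2 <- freq_coords(d[2]) / d[2]
  f3 <- freq_coords(d[3]) / d[3]
  g <- exp(-2 * pi^2 * sigma^2 *
             (outer(outer(f1^2, f2^2, `+`), f3^2, `+`)))
  Re(ifft3(fft3(x) * g))
}

# Integer-pixel image translation with zero fill (no wraparound).
shift_image <- function(img, dx, dy) {
  d <- dim(img)
  out <- array(0, d)
  xs <- seq_len(d[1]) - dx
  ys <- seq_len(d[2]) - dy
  okx <- xs >= 1 & xs <= d[1]
  oky <- ys >= 1 & ys <= d[2]
  out[which(okx), which(oky)] <- img[xs[okx], ys[oky]]
  out
}
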