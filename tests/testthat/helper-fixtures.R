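# Shared fixtures and independent oracles, all generated in code.

# centered, zero-padded FFT of an image: the oracle for dft_point and for
# single-slice grid assembly
oracle_padded_fft <- function(img, oversampling) {
  M <- round(nrow(img) * oversampling)
  fouriertomo:::cfft2(fouriertomo:::embed_center(img, M))
}

# independent per-axis rotation matrices for checking euler_to_matrix
oracle_rz <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
oracle_ry <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# real-space rotation of a volume about the y axis by `deg` degrees
# (bilinear interpolation per y-plane), an independent oracle for the
# Fourier-slice projector
rotate_about_y <- function(vol, deg) {
  n <- dim(vol)[1]
  c0 <- floor(n / 2) + 1
  a <- deg * pi / 180
  out <- array(0, dim(vol))
  xz <- expand.grid(x = seq_len(n) - c0, z = seq_len(n) - c0)
  # inverse-map output coordinates through the rotation
  xs <- cos(a) * xz$x - sin(a) * xz$z + c0
  zs <- sin(a) * xz$x + cos(a) * xz$z + c0
  x0 <- floor(xs); z0 <- floor(zs)
  fx <- xs - x0; fz <- zs - z0
  ok <- x0 >= 1 & z0 >= 1 & x0 <= n - 1 & z0 <= n - 1
  for (y in seq_len(n)) {
    sl <- vol[, y, ]
    v <- numeric(n * n)
    v[ok] <- sl[cbind(x0[ok], z0[ok])] * (1 - fx[ok]) * (1 - fz[ok]) +
      sl[cbind(x0[ok] + 1, z0[ok])] * fx[ok] * (1 - fz[ok]) +
      sl[cbind(x0[ok], z0[ok] + 1)] * (1 - fx[ok]) * fz[ok] +
      sl[cbind(x0[ok] + 1, z0[ok] + 1)] * fx[ok] * fz[ok]
    out[, y, ] <- matrix(v, n, n)
  }
  out
}

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# small deterministic tilt series of a smooth object
fixture_series <- function(n = 16, J = 7, seed = 42, kind = "blobs",
                           theta_max = 60, pad = 2) {
  vol <- make_phantom(n, kind, seed = seed)
  tilts <- seq(-theta_max, theta_max, length.out = J)
  simulate_tilt_series(vol, tilts, projector_params(pad))
}

mean_geodesic_error <- function(a, b) {
  mean(vapply(seq_len(nrow(a)),
              function(j) angular_distance(a[j, ], b[j, ]), numeric(1)))
}
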