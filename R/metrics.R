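# Fourier shell correlation between two volumes.

#' Fourier shell correlation
#'
#' Per radial shell `s`, `FSC(s) = Re(sum(Fa * Conj(Fb))) /
#' sqrt(sum(|Fa|^2) * sum(|Fb|^2))` over voxels whose DC-centered radius
#' falls in shell `s`; the shells are equal-width in radius and partition
#' `(0, Nyquist]`. Identical volumes give 1 in every nonempty shell; a
#' global positive rescaling of either volume leaves the curve unchanged.
#'
#' @param vol_a,vol_b real cubic arrays of the same shape.
#' @param n_shells number of shells (default `size/2`, one per voxel ring).
#' @param mask if `TRUE`, a soft spherical mask (cosine edge over 10% of the
#'   radius) is applied to both volumes before transforming. Default off.
#' @return a data frame of class `fsc_curve` with columns `shell_center`
#'   (spatial frequency as a fraction of Nyquist), `correlation` (NA for
#'   empty shells), `n_voxels`.
#' @export
fsc <- function(vol_a, vol_b, n_shells = NULL, mask = FALSE) {
  da <- dim(vol_a)
  if (!identical(da, dim(vol_b))) stop_invalid("volume shape mismatch")
  if (length(da) != 3L || length(unique(da)) != 1L) {
    stop_invalid("volumes must be cubic 3D arrays")
  }
  M <- da[1]
  n_shells <- as.integer(n_shells %||% floor(M / 2))
  if (n_shells < 2L) stop_invalid("'n_shells' must be >= 2")

  if (isTRUE(mask)) {
    w <- soft_spherical_mask(M)
    vol_a <- vol_a * w
    vol_b <- vol_b * w
  }
  Fa <- fft3(vol_a)
  Fb <- fft3(vol_b)
  f1 <- freq_coords(M)
  r <- sqrt(outer(outer(f1^2, f1^2, `+`), f1^2, `+`))
  h <- (M / 2) / n_shells
  shell <- ceiling(r / h)
  ok <- shell >= 1L & shell <= n_shells

  num <- rowsum(Re(Fa[ok] * Conj(Fb[ok])), shell[ok])
  pa <- rowsum(Mod(Fa[ok])^2, shell[ok])
  pb <- rowsum(Mod(Fb[ok])^2, shell[ok])
  cnt <- rowsum(rep(1L, sum(ok)), shell[ok])

  corr <- rep(NA_real_, n_shells)
  nvox <- integer(n_shells)
  s <- as.integer(rownames(num))
  den <- sqrt(pa[, 1] * pb[, 1])
  vals <- ifelse(den > 0, num[, 1] / den, NA_real_)
  corr[s] <- vals
  nvox[s] <- cnt[, 1]

  structure(
    data.frame(shell_center = (seq_len(n_shells) - 0.5) / n_shells,
               correlation = corr, n_voxels = nvox),
    class = c("fsc_curve", "data.frame")
  )
}

soft_spherical_mask <- function(M) {
  ax <- seq_len(M) - (floor(M / 2) + 1)
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  r0 <- 0.9 * (M / 2)
  r1 <- M / 2
  w <- array(1, dim(r))
  edge <- r > r0 & r <= r1
  w[edge] <- 0.5 * (1 + cos(pi * (r[edge] - r0) / (r1 - r0)))
  w[r > r1] <- 0
  w
}
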