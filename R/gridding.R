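# Assembly of the oversampled 3D Fourier grid from a tilt series.
#
# Each projection's transform is a central plane through the object's 3D
# transform (Fourier slice theorem). For every voxel of an M^3 grid
# (M = round(N * O)) lying within the inscribed Nyquist sphere, all slices
# passing within a perpendicular distance D < D_th contribute the value of
# the projection transform at the foot of the perpendicular, combined with
# normalized inverse-distance weights. In "dft" mode the slice value at the
# (non-integer) foot is computed exactly by discrete Fourier summation; in
# "fft" mode each slice is transformed once with a zero-padded FFT and its
# samples are scattered to nearby grid voxels.

EXACT_HIT_EPS <- 1e-10

#' Gridding parameters
#'
#' @param oversampling linear oversampling ratio `O` (default 3): the grid
#'   side is `M = round(N * O)`.
#' @param distance_threshold maximum perpendicular distance `D_th` in voxels
#'   for a slice to contribute to a grid voxel (default 0.5). Values >= 1
#'   voxel degrade interpolation accuracy and emit a warning at assembly.
#' @param mode `"dft"` for exact per-voxel discrete Fourier summation
#'   (slower, more accurate) or `"fft"` for one zero-padded FFT per slice
#'   scattered to nearest voxels.
#' @param withheld_fraction fraction of known voxels randomly withheld from
#'   enforcement for free R-factor cross-validation (default 0.05).
#' @param seed integer seed controlling the withheld-voxel selection.
#' @return an object of class `gridding_params`.
#' @export
gridding_params <- function(oversampling = 3, distance_threshold = 0.5,
                            mode = c("dft", "fft"), withheld_fraction = 0.05,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (!is.finite(oversampling) || oversampling < 1) {
    stop_invalid("'oversampling' must be >= 1")
  }
  if (!is.finite(distance_threshold) || distance_threshold <= 0) {
    stop_invalid("'distance_threshold' must be > 0")
  }
  if (!is.finite(withheld_fraction) || withheld_fraction < 0 || withheld_fraction >= 1) {
    stop_invalid("'withheld_fraction' must be in [0, 1)")
  }
  structure(
    list(oversampling = oversampling, distance_threshold = distance_threshold,
         mode = mode, withheld_fraction = withheld_fraction,
         seed = as.integer(seed)),
    class = "gridding_params"
  )
}

#' Oversampled DFT of a projection at arbitrary frequencies
#'
#' Evaluates `sum_{x,y} f(x, y) exp(-2*pi*1i*(x*u + y*v)/M)` with
#' `x, y in [-N/2, N/2 - 1]` and `M = round(N * oversampling)`, i.e. the
#' zero-padded centered transform of the projection at (possibly
#' non-integer) frequency coordinates `(u, v)` in grid-voxel units. At
#' integer `(u, v)` this equals the corresponding bin of an M-point
#' zero-padded FFT.
#'
#' @param projection an `N x N` real matrix, `N` even; pixel `x = 0`
#'   corresponds to array index `N/2 + 1`.
#' @param u,v numeric vectors of equal length: frequency coordinates in
#'   voxel units of the oversampled grid.
#' @param oversampling the linear oversampling ratio.
#' @return a complex vector of length `length(u)`.
#' @export
dft_point <- function(projection, u, v, oversampling = 3) {
  if (!is.matrix(projection) || nrow(projection) != ncol(projection)) {
    stop_invalid("'projection' must be a square matrix")
  }
  if (!all(is.finite(projection))) stop_invalid("projection has non-finite values")
  N <- nrow(projection)
  if (N %% 2L != 0L) stop_invalid("'projection' side must be even")
  if (length(u) != length(v)) stop_invalid("'u' and 'v' must have equal length")
  if (length(u) == 0L) return(complex(0))
  M <- round(N * oversampling)
  xs <- seq.int(-N / 2, N / 2 - 1)
  Ex <- exp((-2i * pi / M) * outer(xs, u))
  Ey <- exp((-2i * pi / M) * outer(xs, v))
  colSums(Ex * (projection %*% Ey))
}

# linear index of the Hermitian mate under mod-M frequency arithmetic
hermitian_perm <- function(M) c(1L, M:2L)

#' Assemble the oversampled Fourier grid from a tilt series
#'
#' @param series a [tilt_series()].
#' @param params a [gridding_params()].
#' @return an object of class `fourier_grid`: complex array `values`
#'   (`M^3`, centered layout with the DC voxel at `floor(M/2) + 1`), logical
#'   masks `known` and `withheld`, `dc` index, and the geometry fields
#'   `N`, `M`, `oversampling`. The grid is Hermitian-completed: wherever the
#'   mate `-k` of an unknown voxel is known it is filled with the conjugate,
#'   and doubly-known pairs are averaged to exact conjugate symmetry.
#' @export
assemble_grid <- function(series, params = gridding_params()) {
  if (!inherits(series, "tilt_series")) stop_invalid("'series' must be a tilt_series")
  if (!inherits(params, "gridding_params")) stop_invalid("'params' must be gridding_params")
  J <- n_projections(series)
  if (J < 1L) stop_invalid("empty tilt series")
  if (params$distance_threshold >= 1) {
    warning("distance_threshold >= 1 grid voxel: interpolation accuracy degrades")
  }
  N <- image_size(series)
  M <- as.integer(round(N * params$oversampling))
  dc <- floor(M / 2) + 1L

  acc <- if (params$mode == "dft") {
    assemble_dft(series, M, dc, params)
  } else {
    assemble_fft(series, M, dc, params)
  }

  values <- acc$values
  known <- acc$known

  # Hermitian completion (projections are real, so F(-k) = conj(F(k)))
  perm <- hermitian_perm(M)
  mate_vals <- Conj(values[perm, perm, perm])
  mate_known <- known[perm, perm, perm]
  both <- known & mate_known
  values[both] <- (values[both] + mate_vals[both]) / 2
  fill <- !known & mate_known
  values[fill] <- mate_vals[fill]
  known <- known | mate_known

  grid <- structure(
    list(values = values, known = known,
         withheld = array(FALSE, dim(known)),
         dc = rep(dc, 3L), N = N, M = M,
         oversampling = params$oversampling,
         pixel_size = series$pixel_size),
    class = "fourier_grid"
  )
  if (params$withheld_fraction > 0) {
    grid <- select_withheld(grid, params$withheld_fraction, params$seed)
  }
  grid
}

# coordinates of voxels inside the inscribed Nyquist sphere
sphere_coords <- function(M, dc) {
  k1 <- seq_len(M) - dc
  kx <- array(k1, c(M, M, M))
  ky <- array(rep(k1, each = M), c(M, M, M))
  kz <- array(rep(k1, each = M * M), c(M, M, M))
  inside <- (kx * kx + ky * ky + kz * kz) <= (M / 2)^2
  idx <- which(inside)
  list(idx = idx, kx = kx[idx], ky = ky[idx], kz = kz[idx])
}

# Combine inverse-distance-weighted and exact-hit accumulators. A slice
# passing within EXACT_HIT_EPS of a voxel is an exact sample: Eq.-style
# 1/D weighting diverges there, so exact hits take over with equal weights.
combine_accumulators <- function(sub_n, wnum, wden, exnum, excnt, M, idx) {
  vals_sub <- complex(sub_n)
  has_exact <- excnt > 0
  has_w <- wden > 0
  vals_sub[has_w] <- wnum[has_w] / wden[has_w]
  vals_sub[has_exact] <- exnum[has_exact] / excnt[has_exact]
  known_sub <- has_exact | has_w

  values <- array(0i, c(M, M, M))
  known <- array(FALSE, c(M, M, M))
  values[idx] <- vals_sub
  known[idx] <- known_sub
  list(values = values, known = known)
}

assemble_dft <- function(series, M, dc, params) {
  sc <- sphere_coords(M, dc)
  n_sub <- length(sc$idx)
  wnum <- complex(n_sub); wden <- numeric(n_sub)
  exnum <- complex(n_sub); excnt <- numeric(n_sub)
  J <- n_projections(series)
  for (j in seq_len(J)) {
    pl <- slice_plane(series$angles[j, ])
    D <- abs(sc$kx * pl$normal[1] + sc$ky * pl$normal[2] + sc$kz * pl$normal[3])
    sel <- which(D < params$distance_threshold)
    if (length(sel) == 0L) next
    u <- sc$kx[sel] * pl$u_axis[1] + sc$ky[sel] * pl$u_axis[2] + sc$kz[sel] * pl$u_axis[3]
    v <- sc$kx[sel] * pl$v_axis[1] + sc$ky[sel] * pl$v_axis[2] + sc$kz[sel] * pl$v_axis[3]
    vals <- dft_point(series$projections[, , j], u, v, params$oversampling)
    d <- D[sel]
    ex <- d < EXACT_HIT_EPS
    if (any(ex)) {
      i <- sel[ex]
      exnum[i] <- exnum[i] + vals[ex]
      excnt[i] <- excnt[i] + 1
    }
    if (any(!ex)) {
      i <- sel[!ex]
      w <- 1 / d[!ex]
      wnum[i] <- wnum[i] + w * vals[!ex]
      wden[i] <- wden[i] + w
    }
  }
  combine_accumulators(n_sub, wnum, wden, exnum, excnt, M, sc$idx)
}

assemble_fft <- function(series, M, dc, params) {
  N <- image_size(series)
  J <- n_projections(series)
  # in-plane integer sample coordinates within the Nyquist disc
  k1 <- seq_len(M) - dc
  aa <- rep(k1, times = M)
  bb <- rep(k1, each = M)
  disc <- (aa * aa + bb * bb) <= (M / 2)^2
  aa <- aa[disc]; bb <- bb[disc]

  num <- array(0i, c(M, M, M))
  den <- array(0, c(M, M, M))
  exnum <- array(0i, c(M, M, M))
  excnt <- array(0, c(M, M, M))

  half <- M / 2
  for (j in seq_len(J)) {
    pl <- slice_plane(series$angles[j, ])
    Fsl <- cfft2(embed_center(series$projections[, , j, drop = TRUE], M))
    svals <- Fsl[cbind(aa + dc, bb + dc)]
    px <- aa * pl$u_axis[1] + bb * pl$v_axis[1]
    py <- aa * pl$u_axis[2] + bb * pl$v_axis[2]
    pz <- aa * pl$u_axis[3] + bb * pl$v_axis[3]
    nx <- round(px); ny <- round(py); nz <- round(pz)
    d <- sqrt((px - nx)^2 + (py - ny)^2 + (pz - nz)^2)
    keep <- d < params$distance_threshold &
      (nx * nx + ny * ny + nz * nz) <= half^2
    if (!any(keep)) next
    lin <- (nz[keep] + dc - 1) * M * M + (ny[keep] + dc - 1) * M + (nx[keep] + dc)
    dk <- d[keep]; vk <- svals[keep]
    ex <- dk < EXACT_HIT_EPS
    if (any(ex)) {
      agg <- rowsum(cbind(Re(vk[ex]), Im(vk[ex]), 1), group = lin[ex])
      ii <- as.numeric(rownames(agg))
      exnum[ii] <- exnum[ii] + complex(real = agg[, 1], imaginary = agg[, 2])
      excnt[ii] <- excnt[ii] + agg[, 3]
    }
    if (any(!ex)) {
      w <- 1 / dk[!ex]
      agg <- rowsum(cbind(w * Re(vk[!ex]), w * Im(vk[!ex]), w), group = lin[!ex])
      ii <- as.numeric(rownames(agg))
      num[ii] <- num[ii] + complex(real = agg[, 1], imaginary = agg[, 2])
      den[ii] <- den[ii] + agg[, 3]
    }
  }
  values <- array(0i, c(M, M, M))
  known <- array(FALSE, c(M, M, M))
  hw <- den > 0
  values[hw] <- num[hw] / den[hw]
  hx <- excnt > 0
  values[hx] <- exnum[hx] / excnt[hx]
  known <- hw | hx
  list(values = values, known = known)
}

#' Withhold a random subset of known voxels
#'
#' Marks a stratified random subset of the known voxels as withheld: they
#' are excluded from the Fourier constraint during reconstruction and used
#' only to compute the free R-factor. Sampling is stratified by resolution
#' shell (equal fraction per shell) and Hermitian mates are withheld
#' together.
#'
#' @param grid a `fourier_grid`.
#' @param fraction fraction in `[0, 1)` of known voxels to withhold.
#' @param seed integer seed (same seed, same selection).
#' @return the grid with an updated `withheld` mask.
#' @export
select_withheld <- function(grid, fraction, seed = 1L) {
  if (!inherits(grid, "fourier_grid")) stop_invalid("'grid' must be a fourier_grid")
  if (!is.finite(fraction) || fraction < 0 || fraction >= 1) {
    stop_invalid("'fraction' must be in [0, 1)")
  }
  M <- grid$M
  grid$withheld <- array(FALSE, dim(grid$known))
  if (fraction == 0) return(grid)

  ai <- which(grid$known, arr.ind = TRUE)
  lin <- which(grid$known)
  perm <- hermitian_perm(M)
  mi <- cbind(perm[ai[, 1]], perm[ai[, 2]], perm[ai[, 3]])
  mate_lin <- (as.numeric(mi[, 3]) - 1) * M * M + (as.numeric(mi[, 2]) - 1) * M + mi[, 1]
  canonical <- lin <= mate_lin

  dc <- grid$dc[1]
  r <- sqrt((ai[, 1] - dc)^2 + (ai[, 2] - dc)^2 + (ai[, 3] - dc)^2)
  n_strata <- 20L
  shell <- pmin(n_strata, floor(r / ((M / 2) / n_strata)) + 1L)

  withheld <- array(FALSE, dim(grid$known))
  with_seed(seed, {
    for (s in unique(shell[canonical])) {
      cand <- which(canonical & shell == s)
      n_take <- round(fraction * length(cand))
      if (n_take == 0L) next
      take <- if (length(cand) == 1L) cand else sample(cand, n_take)
      withheld[lin[take]] <- TRUE
      withheld[mate_lin[take]] <- TRUE
    }
  })
  grid$withheld <- withheld
  grid
}

#' @export
print.fourier_grid <- function(x, ...) {
  nk <- sum(x$known)
  cat("fourier grid: M = ", x$M, " (N = ", x$N, ", oversampling = ",
      x$oversampling, ")\n", sep = "")
  cat(sprintf("  known voxels: %d (%.2f%% of grid), withheld: %d\n",
              nk, 100 * nk / length(x$known), sum(x$withheld)))
  invisible(x)
}
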