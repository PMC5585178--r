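# Fourier-slice forward projector: projections are computed by sampling a
# central slice of the oversampled 3D transform of the volume (trilinear
# interpolation) and inverse-transforming the slice.

#' Projector parameters
#'
#' @param pad_factor oversampling of the volume transform before slice
#'   interpolation (default 2). Larger values reduce interpolation error at
#'   the cost of memory and speed.
#' @return an object of class `projector_params`.
#' @export
projector_params <- function(pad_factor = 2) {
  if (!is.finite(pad_factor) || pad_factor < 1) stop_invalid("'pad_factor' must be >= 1")
  structure(list(pad_factor = pad_factor), class = "projector_params")
}

# centered-layout oversampled transform of a cubic volume, plus the slice
# sample spacing in padded-grid voxels per image frequency step
padded_transform <- function(vol, pad_factor) {
  N <- dim(vol)[1]
  Mp <- as.integer(round(N * pad_factor))
  if (Mp %% 2L == 1L) Mp <- Mp + 1L
  list(F = cfft3(embed_center(vol, Mp)), Mp = Mp, spacing = Mp / N)
}

#' Forward-project a volume at given Euler angles
#'
#' Pads the volume, transforms it, samples the central slice on the plane of
#' [slice_plane()] by trilinear interpolation (samples falling outside the
#' computed transform are zero), and inverse-transforms the slice to an `N x N`
#' real projection image. At `angles = c(0, 0, 0)` this equals the direct
#' sum of the volume along z (the Fourier slice theorem with no
#' interpolation involved), and every projection's pixel sum equals the
#' volume sum (DC conservation).
#'
#' @param vol a cubic real 3D array (`N^3`, `N` even).
#' @param angles an Euler triple `c(phi, theta, psi)` in degrees.
#' @param params a [projector_params()].
#' @return an `N x N` real matrix.
#' @export
forward_project <- function(vol, angles, params = projector_params()) {
  d <- dim(vol)
  if (length(d) != 3L || length(unique(d)) != 1L) {
    stop_invalid("'vol' must be a cubic 3D array")
  }
  if (!all(is.finite(vol))) stop_invalid("'vol' has non-finite values")
  pt <- padded_transform(vol, params$pad_factor)
  project_from_transform(pt, angles, d[1])
}

project_from_transform <- function(pt, angles, N) {
  angles <- as.numeric(angles)
  if (length(angles) != 3L || !all(is.finite(angles))) {
    stop_invalid("'angles' must be a finite Euler triple")
  }
  S <- cpp_sample_slice(pt$F, dim(pt$F), angles, as.integer(N), pt$spacing)
  Re(cifft2(S))
}

#' Simulate a tilt series from a model volume
#'
#' Applies [forward_project()] at each requested orientation and bundles the
#' images with their angles into a [tilt_series()].
#'
#' @param vol a cubic real 3D array.
#' @param angle_list a `J x 3` matrix of Euler triples, or a length-`J`
#'   vector of single-tilt angles (degrees).
#' @param params a [projector_params()].
#' @return a `tilt_series` of `J` projections.
#' @export
simulate_tilt_series <- function(vol, angle_list, params = projector_params()) {
  angle_list <- as_euler_angles(angle_list)
  J <- nrow(angle_list)
  if (J < 1L) stop_invalid("'angle_list' is empty")
  N <- dim(vol)[1]
  pt <- padded_transform(vol, params$pad_factor)
  stack <- array(0, c(N, N, J))
  for (j in seq_len(J)) {
    stack[, , j] <- project_from_transform(pt, angle_list[j, ], N)
  }
  tilt_series(stack, angle_list)
}
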