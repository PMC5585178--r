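# Euler-angle conventions, slice-plane bases and perpendicular feet.
#
# Convention used throughout: intrinsic Z-Y-Z Euler angles in degrees,
# rotation matrices acting on column vectors, R = Rz(phi) %*% Ry(theta) %*%
# Rz(psi). A single-axis tilt series maps to phi = psi = 0 with theta equal
# to the tilt angle. Rotations are interpreted as rotating the measuring
# plane within a fixed object/grid frame, so the Fourier slice for a given
# triple samples the object transform on the plane spanned by the first two
# columns of R.

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' Rotation matrix from a Z-Y-Z Euler triple
#'
#' Converts Euler angles `(phi, theta, psi)` in degrees to a proper rotation
#' matrix `R = Rz(phi) Ry(theta) Rz(psi)` acting on column vectors.
#'
#' @param angles numeric length-3 vector `c(phi, theta, psi)` in degrees.
#' @return a 3x3 orthonormal matrix with determinant +1.
#' @examples
#' euler_to_matrix(c(0, 90, 0)) %*% c(0, 0, 1)  # z-axis maps onto x-axis
#' @export
euler_to_matrix <- function(angles) {
  angles <- as.numeric(angles)
  if (length(angles) != 3L || !all(is.finite(angles))) {
    stop_invalid("'angles' must be three finite Euler angles in degrees")
  }
  a <- deg2rad(angles)
  rot_z(a[1]) %*% rot_y(a[2]) %*% rot_z(a[3])
}

#' Central slice plane for an Euler triple
#'
#' The Fourier transform of a projection is a central plane through the
#' origin of the object's 3D transform. This returns the orthonormal basis
#' of that plane: `u_axis` and `v_axis` are the images of the in-plane
#' reciprocal axes of the unrotated projection, `normal` the image of the
#' z-axis.
#'
#' @inheritParams euler_to_matrix
#' @return an object of class `slice_plane` with fields `u_axis`, `v_axis`,
#'   `normal` (unit 3-vectors, `normal = u_axis x v_axis`).
#' @export
slice_plane <- function(angles) {
  R <- euler_to_matrix(angles)
  structure(
    list(u_axis = R[, 1], v_axis = R[, 2], normal = R[, 3]),
    class = "slice_plane"
  )
}

#' Perpendicular distance and foot on a slice plane
#'
#' For reciprocal grid points `k` (voxel units, relative to the DC voxel),
#' computes the perpendicular distance `D` to the plane and the in-plane
#' coordinates `(u, v)` of the foot of the perpendicular.
#'
#' @param k a length-3 vector or an n x 3 matrix of grid coordinates.
#' @param plane a [slice_plane()].
#' @return list with numeric vectors `D` (>= 0), `u`, `v`; the identity
#'   `u*u_axis + v*v_axis + (k . normal)*normal == k` holds to rounding.
#' @export
perpendicular_foot <- function(k, plane) {
  if (!inherits(plane, "slice_plane")) stop_invalid("'plane' must be a slice_plane")
  if (is.null(dim(k))) k <- matrix(as.numeric(k), nrow = 1)
  if (ncol(k) != 3L) stop_invalid("'k' must have three columns")
  list(
    D = abs(drop(k %*% plane$normal)),
    u = drop(k %*% plane$u_axis),
    v = drop(k %*% plane$v_axis)
  )
}

#' Geodesic angular distance between two orientations
#'
#' Distance on the rotation group between the orientations described by two
#' Euler triples: `arccos((trace(Ra' Rb) - 1)/2)`, in degrees, in
#' `[0, 180]`. Equivalent triples (e.g. angles differing by 360 degrees)
#' give 0.
#'
#' @param a,b Euler triples in degrees.
#' @return angular distance in degrees.
#' @export
angular_distance <- function(a, b) {
  Ra <- euler_to_matrix(a)
  Rb <- euler_to_matrix(b)
  tr <- sum(diag(crossprod(Ra, Rb)))
  arg <- (tr - 1) / 2
  rad2deg(acos(pmin(1, pmax(-1, arg))))
}
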