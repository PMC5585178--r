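# The tilt-series container: a stack of square projection images plus one
# Euler triple per image.

#' Construct a tilt series
#'
#' Bundles a stack of square, real-valued projection images with their Euler
#' angles. Images with an odd side are zero-padded by one row/column (and
#' non-square images to the enclosing even square) with a warning, keeping
#' the image center at array index `N/2 + 1` so the Fourier conventions used
#' downstream are preserved.
#'
#' @param projections an `N x N x J` array (or a single `N x N` matrix) of
#'   finite pixel values. The first index is x (MRC fast axis), the second y.
#' @param angles either a `J x 3` matrix of `(phi, theta, psi)` triples in
#'   degrees, or a length-`J` numeric vector of tilt angles interpreted as
#'   single-tilt `(0, theta, 0)`.
#' @param pixel_size optional physical length per pixel (carried through to
#'   MRC headers; not used numerically).
#' @return an object of class `tilt_series` with fields `projections`
#'   (`N x N x J`), `angles` (`J x 3`), `pixel_size`.
#' @export
tilt_series <- function(projections, angles, pixel_size = NULL) {
  if (is.matrix(projections)) {
    projections <- array(projections, c(dim(projections), 1L))
  }
  d <- dim(projections)
  if (length(d) != 3L || d[3] < 1L) {
    stop_invalid("'projections' must be an N x N x J array with J >= 1")
  }
  if (!all(is.finite(projections))) {
    stop_invalid("projections contain non-finite pixel values")
  }
  J <- d[3]
  angles <- as_euler_angles(angles, J)

  n_target <- max(d[1], d[2])
  if (n_target %% 2L == 1L) n_target <- n_target + 1L
  if (d[1] != n_target || d[2] != n_target) {
    warning("padding projections from ", d[1], "x", d[2], " to ",
            n_target, "x", n_target, " (even square required)")
    padded <- array(0, c(n_target, n_target, J))
    for (j in seq_len(J)) {
      padded[, , j] <- embed_center(projections[, , j, drop = TRUE], n_target)
    }
    projections <- padded
  }
  structure(
    list(projections = projections, angles = angles, pixel_size = pixel_size),
    class = "tilt_series"
  )
}

# Normalize user-supplied angle input to a J x 3 matrix.
as_euler_angles <- function(angles, J = NULL) {
  if (is.null(dim(angles))) {
    angles <- as.numeric(angles)
    if (!is.null(J) && length(angles) == J) {
      angles <- cbind(0, angles, 0)
    } else if (is.null(J) && length(angles) %% 1 == 0) {
      angles <- cbind(0, angles, 0)
    } else if (length(angles) == 3L && identical(J, 1L)) {
      angles <- matrix(angles, 1, 3)
    } else {
      stop_invalid("'angles' must be a J x 3 matrix or a length-J tilt vector")
    }
  }
  angles <- as.matrix(angles)
  if (ncol(angles) != 3L) stop_invalid("'angles' must have three columns (phi, theta, psi)")
  if (!is.null(J) && nrow(angles) != J) {
    stop_invalid("number of angle triples (", nrow(angles),
                 ") does not match number of projections (", J, ")")
  }
  if (!all(is.finite(angles))) stop_invalid("angles contain non-finite values")
  colnames(angles) <- c("phi", "theta", "psi")
  angles
}

n_projections <- function(series) dim(series$projections)[3]
image_size <- function(series) dim(series$projections)[1]

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$projections)
  cat("tilt series: ", d[3], " projections of ", d[1], " x ", d[2], " pixels\n", sep = "")
  th <- range(x$angles[, "theta"])
  cat("  theta range: [", th[1], ", ", th[2], "] deg\n", sep = "")
  if (!is.null(x$pixel_size)) cat("  pixel size: ", x$pixel_size, "\n", sep = "")
  invisible(x)
}
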