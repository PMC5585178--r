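# Minimal experimental-style preprocessing: background subtraction from a
# flat region, total-sum normalization (integrated density is conserved
# across a tilt series), and integer-pixel alignment by center of mass
# perpendicular to the tilt axis and cross-correlation along it.

#' Subtract a flat-region background
#'
#' Subtracts, per image, the mean pixel value over a rectangle assumed to
#' contain only background. Negative results are retained (clipping is the
#' reconstructor's positivity constraint, not a preprocessing step).
#'
#' @param series a [tilt_series()].
#' @param flat_region integer vector `c(x0, y0, x1, y1)` of 1-based inclusive
#'   pixel bounds (x = first array index).
#' @return the background-subtracted `tilt_series`.
#' @export
subtract_background <- function(series, flat_region) {
  if (!inherits(series, "tilt_series")) stop_invalid("'series' must be a tilt_series")
  fr <- as.integer(flat_region)
  if (length(fr) != 4L) stop_invalid("'flat_region' must be c(x0, y0, x1, y1)")
  N <- image_size(series)
  if (fr[1] < 1L || fr[2] < 1L || fr[3] > N || fr[4] > N ||
      fr[3] < fr[1] || fr[4] < fr[2]) {
    stop_invalid("'flat_region' must be a nonempty rectangle within image bounds")
  }
  for (j in seq_len(n_projections(series))) {
    img <- series$projections[, , j]
    series$projections[, , j] <- img - mean(img[fr[1]:fr[3], fr[2]:fr[4]])
  }
  series
}

#' Normalize projections to a common total sum
#'
#' A parallel-beam projection conserves integrated density, so all images of
#' one object should share the same pixel sum; each image is rescaled so its
#' sum equals the mean of the input sums.
#'
#' @param series a [tilt_series()]; every image must have a positive sum.
#' @return the normalized `tilt_series`.
#' @export
normalize_sums <- function(series) {
  if (!inherits(series, "tilt_series")) stop_invalid("'series' must be a tilt_series")
  sums <- apply(series$projections, 3, sum)
  bad <- which(sums <= 0)
  if (length(bad) > 0) {
    stop_invalid("projection ", bad[1], " has non-positive total sum")
  }
  target <- mean(sums)
  for (j in seq_along(sums)) {
    series$projections[, , j] <- series$projections[, , j] * (target / sums[j])
  }
  series
}

#' Align a single-tilt series by center of mass and cross-correlation
#'
#' Each image is shifted by an integer number of pixels so that its center
#' of mass along the direction perpendicular to the tilt axis coincides with
#' the image center (within half a pixel), and aligned along the tilt axis
#' by integer-shift cross-correlation of 1D profiles against the running
#' average of the already-aligned images (which avoids cumulative drift).
#' Shifts are zero-padded (no wraparound), so total intensity is preserved
#' only up to mass shifted off the edge; well-centered data loses none.
#'
#' @param series a [tilt_series()] with positive-sum images.
#' @param tilt_axis `"y"` (default; perpendicular direction is x, the first
#'   array index) or `"x"`.
#' @return the aligned `tilt_series`.
#' @export
align_center_of_mass <- function(series, tilt_axis = c("y", "x")) {
  tilt_axis <- match.arg(tilt_axis)
  if (!inherits(series, "tilt_series")) stop_invalid("'series' must be a tilt_series")
  sums <- apply(series$projections, 3, sum)
  bad <- which(sums <= 0)
  if (length(bad) > 0) stop_invalid("projection ", bad[1], " has non-positive total sum")

  N <- image_size(series)
  J <- n_projections(series)
  perp <- if (tilt_axis == "y") 1L else 2L
  along <- 3L - perp
  center <- (N + 1) / 2
  ref <- NULL
  for (j in seq_len(J)) {
    img <- series$projections[, , j]
    w <- pmax(img, 0)
    prof_perp <- apply(w, perp, sum)
    com <- sum(seq_len(N) * prof_perp) / sum(prof_perp)
    d_perp <- round(center - com)

    prof_along <- apply(pmax(img, 0), along, sum)
    d_along <- 0L
    if (!is.null(ref)) {
      rng <- -floor(N / 4):floor(N / 4)
      best <- -Inf
      for (s in rng) {
        i1 <- max(1, 1 + s):min(N, N + s)
        cc <- sum(prof_along[i1 - s] * ref[i1])
        if (cc > best) { best <- cc; d_along <- s }
      }
    }
    dx <- if (perp == 1L) d_perp else d_along
    dy <- if (perp == 1L) d_along else d_perp
    img <- shift_image(img, dx, dy)
    series$projections[, , j] <- img
    prof_new <- apply(pmax(img, 0), along, sum)
    ref <- if (is.null(ref)) prof_new else (ref * (j - 1) + prof_new) / j
  }
  series
}
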