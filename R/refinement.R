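# Projection-matching angular (and translational) refinement: reconstruct
# with the current angles, re-project the reconstruction over a Cartesian
# grid of candidate Euler triples around each projection's current estimate,
# score each candidate against the measured image, and keep the best triple;
# repeat until the angles stop changing or the outer-iteration budget is
# spent. The exhaustive grid scan can be trapped in local minima; no global
# search is attempted.

#' Angular refinement parameters
#'
#' @param delta_phi,delta_theta,delta_psi half-ranges of the angular search
#'   per Euler component, degrees (default 3).
#' @param step angular step of the search grid, degrees (default 0.2).
#' @param metric `"xcorr"` (normalized cross-correlation, maximized; the
#'   translational search over all integer shifts comes for free) or
#'   `"rfactor"` (real-space R-factor, minimized over integer shifts within
#'   `translation_radius`).
#' @param max_outer_iterations maximum number of reconstruct-and-rescan
#'   passes (default 5).
#' @param translation_radius integer-pixel translational search radius for
#'   the rfactor metric (default 2).
#' @param recon_iterations iterations used for the reconstructions inside
#'   the refinement loop (default 50; fewer than a final reconstruction,
#'   for speed).
#' @param pad_factor projector oversampling used when re-projecting.
#' @param score_tie_tolerance score differences below this are treated as
#'   ties and resolved by geodesic distance to the current estimate. The
#'   default 1e-4 is the score resolution of the trilinear Fourier-slice
#'   projector at `pad_factor = 2` (the normalized-correlation deficit
#'   observed when a reconstruction is re-projected at its own true
#'   angles); gaps below it carry no orientation evidence. Exact-equality
#'   tie handling (`0`) lets the gimbal-degenerate in-plane angles of a
#'   single-tilt series random-walk along the flat score valley.
#' @return an object of class `refinement_params`.
#' @export
refinement_params <- function(delta_phi = 3, delta_theta = 3, delta_psi = 3,
                              step = 0.2, metric = c("xcorr", "rfactor"),
                              max_outer_iterations = 5L,
                              translation_radius = 2L,
                              recon_iterations = 50L,
                              pad_factor = 2,
                              score_tie_tolerance = 1e-4) {
  metric <- match.arg(metric)
  deltas <- c(delta_phi, delta_theta, delta_psi)
  if (any(!is.finite(deltas)) || any(deltas < 0)) stop_invalid("search ranges must be >= 0")
  if (!is.finite(step) || step <= 0) stop_invalid("'step' must be > 0")
  if (any(deltas > 0) && step > 2 * max(deltas)) {
    stop_invalid("'step' must be <= twice the largest search range")
  }
  if (max_outer_iterations < 1) stop_invalid("'max_outer_iterations' must be >= 1")
  structure(
    list(delta_phi = delta_phi, delta_theta = delta_theta, delta_psi = delta_psi,
         step = step, metric = metric,
         max_outer_iterations = as.integer(max_outer_iterations),
         translation_radius = as.integer(translation_radius),
         recon_iterations = as.integer(recon_iterations),
         pad_factor = pad_factor,
         score_tie_tolerance = score_tie_tolerance),
    class = "refinement_params"
  )
}

#' Quality-of-fit between a calculated and a measured projection
#'
#' `xcorr`: maximum of the zero-mean normalized cross-correlation over all
#' integer shifts (higher is better, 1 for identical images). `rfactor`:
#' minimum over integer shifts within `translation_radius` of
#' `sum(|calc - meas|) / sum(|meas|)` (lower is better, 0 for identical
#' images). The reported shift is the displacement applied to `calc` that
#' best matches `meas`.
#'
#' @param calc,meas real `N x N` matrices.
#' @param method `"xcorr"` or `"rfactor"`.
#' @param translation_radius shift search radius in pixels (rfactor only).
#' @return list with `score` and integer `shift = c(dx, dy)`.
#' @export
quality_metric <- function(calc, meas, method = c("xcorr", "rfactor"),
                           translation_radius = 2L) {
  method <- match.arg(method)
  if (!identical(dim(calc), dim(meas))) stop_invalid("image shape mismatch")
  n <- nrow(calc)
  if (method == "xcorr") {
    calc0 <- calc - mean(calc)
    meas0 <- meas - mean(meas)
    nc <- sqrt(sum(calc0^2)); nm <- sqrt(sum(meas0^2))
    if (nc == 0 || nm == 0) {
      stop(errorCondition("zero-variance image with xcorr metric",
                          class = c("undefined_metric", "error")))
    }
    r <- Re(fft(fft(calc0 + 0i) * Conj(fft(meas0 + 0i)), inverse = TRUE)) / length(calc0)
    best <- which.max(r)
    ai <- arrayInd(best, dim(r)) - 1L
    sgn <- function(i, m) if (i <= m - 1 - floor(m / 2)) i else i - m
    list(score = r[best] / (nc * nm),
         shift = c(sgn(ai[1], n), sgn(ai[2], ncol(calc))))
  } else {
    denom <- sum(abs(meas))
    if (denom == 0) {
      stop(errorCondition("all-zero measured image with rfactor metric",
                          class = c("undefined_metric", "error")))
    }
    best <- Inf; best_shift <- c(0L, 0L)
    tr <- translation_radius
    for (dy in -tr:tr) for (dx in -tr:tr) {
      if (dx^2 + dy^2 > tr^2) next
      cs <- calc[((seq_len(n) - 1 - dx) %% n) + 1, ((seq_len(ncol(calc)) - 1 - dy) %% ncol(calc)) + 1]
      rf <- sum(abs(cs - meas)) / denom
      if (rf < best) { best <- rf; best_shift <- c(dx, dy) }
    }
    list(score = best, shift = best_shift)
  }
}

search_offsets <- function(delta, step) {
  if (delta <= 0) return(0)
  s <- seq(0, delta, by = step)
  sort(unique(c(-s, s)))
}

#' Refine projection orientations by projection matching
#'
#' Outer loop: reconstruct with the current angles; for each projection
#' independently, scan the Cartesian grid of candidate Euler triples within
#' the search ranges, forward-project the reconstruction at each candidate,
#' score against the measured image, and record the best triple; rebuild
#' with the refined angles. Stops when no angle changes or after
#' `max_outer_iterations`. Ties are broken by smallest geodesic distance to
#' the current estimate, then by scan order (phi, theta, psi lexicographic).
#'
#' @param series the measured [tilt_series()] with the current angle
#'   estimates.
#' @param recon_params a [reconstruction_params()] (the iteration count used
#'   inside the loop is `refine_params$recon_iterations`).
#' @param grid_params a [gridding_params()].
#' @param refine_params a [refinement_params()].
#' @return an object of class `angular_refinement`: `refined_angles`
#'   (`J x 3`), `refined_shifts` (`J x 2`, integer pixels; the displacement
#'   to apply to each measured image to center it), `score_history`
#'   (outer iterations x J), `angle_history` (list of `J x 3` matrices, one
#'   per outer iteration), `outer_iterations`.
#' @export
refine_angles <- function(series,
                          recon_params = reconstruction_params(),
                          grid_params = gridding_params(),
                          refine_params = refinement_params()) {
  if (!inherits(series, "tilt_series")) stop_invalid("'series' must be a tilt_series")
  J <- n_projections(series)

  offsets <- expand.grid(
    psi = search_offsets(refine_params$delta_psi, refine_params$step),
    theta = search_offsets(refine_params$delta_theta, refine_params$step),
    phi = search_offsets(refine_params$delta_phi, refine_params$step)
  )
  # scan order: lexicographic in (phi, theta, psi)
  offsets <- as.matrix(offsets[, c("phi", "theta", "psi")])

  inner_recon <- recon_params
  inner_recon$iterations <- refine_params$recon_iterations

  current <- series$angles
  shifts <- matrix(0L, J, 2)
  score_history <- NULL
  angle_history <- list()
  maximize <- refine_params$metric == "xcorr"

  # translational pre-alignment: estimate integer shifts at the current
  # angles before any angular move, so the first full scan works against a
  # reconstruction free of translational smearing
  {
    work <- series
    work$angles <- current
    grid <- assemble_grid(work, grid_params)
    recon <- reconstruct(grid, params = inner_recon)
    pt <- padded_transform(recon$volume, refine_params$pad_factor)
    for (j in seq_len(J)) {
      meas <- series$projections[, , j]
      if (all(meas == 0)) next
      scan <- cpp_refine_scan(pt$F, dim(pt$F), pt$spacing,
                              matrix(current[j, ], 1), meas,
                              refine_params$metric,
                              refine_params$translation_radius)
      shifts[j, ] <- scan$shifts[1, ]
    }
  }

  for (outer in seq_len(refine_params$max_outer_iterations)) {
    # rebuild from shift-corrected projections: the reconstructor assumes
    # centered images, so the translational misalignments recovered in the
    # previous pass are undone here (scoring below always uses the original
    # measured images, and shifts are re-estimated fresh each pass)
    work <- series
    work$angles <- current
    for (j in seq_len(J)) {
      if (any(shifts[j, ] != 0L)) {
        work$projections[, , j] <- shift_image(series$projections[, , j],
                                               shifts[j, 1], shifts[j, 2])
      }
    }
    grid <- assemble_grid(work, grid_params)
    recon <- reconstruct(grid, params = inner_recon)
    pt <- padded_transform(recon$volume, refine_params$pad_factor)

    new_angles <- current
    new_shifts <- shifts
    iter_scores <- rep(NA_real_, J)
    for (j in seq_len(J)) {
      meas <- series$projections[, , j]
      if (all(meas == 0)) {
        warning("projection ", j, " is all zero; angles left unchanged")
        next
      }
      cand <- sweep(offsets, 2, current[j, ], `+`)
      scan <- cpp_refine_scan(pt$F, dim(pt$F), pt$spacing, cand, meas,
                              refine_params$metric,
                              refine_params$translation_radius)
      sc <- scan$scores
      best_val <- if (maximize) max(sc) else min(sc)
      tol <- max(refine_params$score_tie_tolerance, 1e-12)
      tied <- which(if (maximize) sc >= best_val - tol else sc <= best_val + tol)
      if (length(tied) > 1L) {
        gd <- vapply(tied, function(i) angular_distance(cand[i, ], current[j, ]),
                     numeric(1))
        tied <- tied[gd <= min(gd) + 1e-12]
      }
      pick <- tied[1]
      new_angles[j, ] <- cand[pick, ]
      new_shifts[j, ] <- scan$shifts[pick, ]
      iter_scores[j] <- sc[pick]
    }
    score_history <- rbind(score_history, iter_scores)
    angle_history <- c(angle_history, list(new_angles))
    converged <- isTRUE(all(new_angles == current)) &&
      isTRUE(all(new_shifts == shifts))
    current <- new_angles
    shifts <- new_shifts
    if (converged) break
  }

  rownames(score_history) <- NULL
  structure(
    list(refined_angles = current, refined_shifts = shifts,
         score_history = score_history, angle_history = angle_history,
         outer_iterations = nrow(score_history)),
    class = "angular_refinement"
  )
}

#' @export
print.angular_refinement <- function(x, ...) {
  cat("angular refinement: ", nrow(x$refined_angles), " projections, ",
      x$outer_iterations, " outer iterations\n", sep = "")
  cat(sprintf("  final mean score: %.4f\n",
              mean(x$score_history[nrow(x$score_history), ], na.rm = TRUE)))
  invisible(x)
}
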