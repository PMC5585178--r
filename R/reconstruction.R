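# The iterative solver: alternating projections between real space
# (support + positivity) and reciprocal space (measured-data constraint),
# with R-factor / free R-factor monitoring and an optional resolution
# extension/suppression schedule.
#
# All three constraint sets (measured Fourier data, support, positivity)
# are convex, so the iteration is a projection-onto-convex-sets scheme.

#' Reconstruction parameters
#'
#' @param iterations number of iterations (default 100; no early stopping).
#' @param use_resolution_schedule enable resolution extension/suppression:
#'   only the lowest spatial frequencies are enforced at the first
#'   iteration, the enforced radius ramps up to full resolution at half the
#'   iterations, then back down. Helpful with noisy data, where noise
#'   dominates high spatial frequencies.
#' @param schedule_steps number of discrete radius levels in each ramp.
#' @param schedule_min_radius lowest enforced radius as a fraction of
#'   Nyquist.
#' @param init_mode `"zeros"` (deterministic default) or `"random"` start
#'   for the unknown voxels.
#' @param seed seed for `init_mode = "random"`.
#' @param keep_fourier if `TRUE`, the final Fourier iterate (after the last
#'   constraint application, centered layout) is returned in the result.
#' @return an object of class `reconstruction_params`.
#' @export
reconstruction_params <- function(iterations = 100L,
                                  use_resolution_schedule = FALSE,
                                  schedule_steps = 20L,
                                  schedule_min_radius = 0.05,
                                  init_mode = c("zeros", "random"),
                                  seed = 0L,
                                  keep_fourier = FALSE) {
  init_mode <- match.arg(init_mode)
  if (!is.finite(iterations) || iterations < 1) stop_invalid("'iterations' must be >= 1")
  if (!is.finite(schedule_steps) || schedule_steps < 1) {
    stop_invalid("'schedule_steps' must be >= 1")
  }
  if (!is.finite(schedule_min_radius) || schedule_min_radius <= 0 ||
      schedule_min_radius > 1) {
    stop_invalid("'schedule_min_radius' must be in (0, 1]")
  }
  structure(
    list(iterations = as.integer(iterations),
         use_resolution_schedule = isTRUE(use_resolution_schedule),
         schedule_steps = as.integer(schedule_steps),
         schedule_min_radius = schedule_min_radius,
         init_mode = init_mode, seed = as.integer(seed),
         keep_fourier = isTRUE(keep_fourier)),
    class = "reconstruction_params"
  )
}

#' Real-space constraint: support and positivity
#'
#' Sets voxels outside the support, and negative voxels inside it, to zero;
#' all other voxels are retained. Idempotent.
#'
#' @param vol a real 3D array.
#' @param support a logical array of the same shape.
#' @return the constrained array.
#' @export
apply_real_constraints <- function(vol, support) {
  if (!identical(dim(vol), dim(support))) stop_invalid("volume/support shape mismatch")
  vol[!support] <- 0
  vol[vol < 0] <- 0
  vol
}

#' Fourier-space constraint: enforce measured voxels
#'
#' Replaces the current Fourier iterate by the measured grid values on the
#' enforced voxels and keeps the iterate elsewhere. Idempotent. The enforce
#' mask must be a subset of the known, non-withheld voxels.
#'
#' @param F_current complex array (same centered layout as the grid).
#' @param grid a `fourier_grid`.
#' @param enforce_mask logical array of voxels to enforce.
#' @return the constrained complex array.
#' @export
apply_fourier_constraint <- function(F_current, grid, enforce_mask) {
  if (!identical(dim(F_current), dim(grid$values)) ||
      !identical(dim(enforce_mask), dim(grid$values))) {
    stop_invalid("array shape mismatch")
  }
  if (any(enforce_mask & !(grid$known & !grid$withheld))) {
    stop_invalid("enforce_mask must be a subset of known, non-withheld voxels")
  }
  F_current[enforce_mask] <- grid$values[enforce_mask]
  F_current
}

#' Fourier R-factor over a voxel set
#'
#' `sum(|F_obs - F_i|) / sum(|F_obs|)` over the masked voxels: the
#' normalized absolute mismatch used to monitor convergence (over enforced
#' voxels) and to cross-validate (over withheld voxels).
#'
#' @param F_obs,F_i complex arrays of identical shape.
#' @param mask logical array selecting the voxels.
#' @return a nonnegative number.
#' @export
r_factor <- function(F_obs, F_i, mask) {
  if (!identical(dim(F_obs), dim(F_i)) || !identical(dim(F_obs), dim(mask))) {
    stop_invalid("array shape mismatch")
  }
  if (!any(mask)) stop_invalid("'mask' selects no voxels")
  denom <- sum(Mod(F_obs[mask]))
  if (denom == 0) {
    stop(errorCondition("undefined R-factor: sum(|F_obs|) over mask is zero",
                        class = c("undefined_metric", "error")))
  }
  sum(Mod(F_obs[mask] - F_i[mask])) / denom
}

#' Resolution extension/suppression radius for an iteration
#'
#' Piecewise-constant ramp of the enforced-resolution cutoff: from
#' `schedule_min_radius` at iteration 0 up to 1.0 (all measured data) at
#' half the iterations, then mirrored back down, with
#' `cutoff(i) = cutoff(total - 1 - i)` up to step quantization.
#'
#' @param iteration 0-based iteration index.
#' @param total total number of iterations.
#' @param params a [reconstruction_params()].
#' @return the enforced radius cutoff as a fraction of Nyquist.
#' @export
resolution_schedule <- function(iteration, total, params = reconstruction_params()) {
  if (!is.finite(iteration) || iteration < 0 || iteration >= total) {
    stop_invalid("'iteration' must satisfy 0 <= iteration < total")
  }
  if (total == 1L) return(1.0)
  levels <- max(1L, min(params$schedule_steps, floor(total / 2)))
  if (levels == 1L) return(1.0)
  half <- total / 2
  it <- if (iteration >= half) total - 1 - iteration else iteration
  lev <- min(levels - 1, floor(levels * it / half))
  params$schedule_min_radius +
    lev * (1 - params$schedule_min_radius) / (levels - 1)
}

# default loose support: the centered N^3 cube separating the object region
# from the oversampling zero padding
default_support <- function(M, N) {
  s1 <- logical(M)
  start <- floor(M / 2) - floor(N / 2) + 1L
  s1[seq.int(start, length.out = N)] <- TRUE
  outer(outer(s1, s1, `&`), s1, `&`)
}

#' Iterative Fourier-grid reconstruction
#'
#' Runs the alternating-projection loop: inverse FFT of the Fourier iterate,
#' real part, support/positivity constraint, forward FFT, R-factor and free
#' R-factor evaluation, and re-enforcement of the measured voxels (optionally
#' restricted to the schedule's radial band). Returns the real-space
#' constrained volume from the iteration with minimal R-factor, cropped to
#' the central `N^3` region.
#'
#' @param grid a `fourier_grid` from [assemble_grid()].
#' @param support optional logical `M^3` array; default is the centered
#'   `N^3` cube (loose support).
#' @param params a [reconstruction_params()].
#' @return an object of class `tomo_reconstruction`: `volume` (`N^3` crop),
#'   `volume_full` (`M^3`, centered layout), `rk_history`, `rfree_history`
#'   (NA when no voxels are withheld), `best_iteration` (1-based), and
#'   `fourier_final` when requested.
#' @export
reconstruct <- function(grid, support = NULL, params = reconstruction_params()) {
  if (!inherits(grid, "fourier_grid")) stop_invalid("'grid' must be a fourier_grid")
  M <- grid$M; N <- grid$N
  enforce <- grid$known & !grid$withheld
  if (!any(enforce)) stop_invalid("grid has no known non-withheld voxels")
  if (is.null(support)) support <- default_support(M, N)
  if (!identical(dim(support), dim(grid$values))) {
    stop_invalid("support shape does not match grid")
  }
  if (!any(support)) stop_invalid("support is empty")

  # work in standard FFT layout (DC at [1,1,1]) to avoid per-iteration shifts
  support_std <- ifftshift(support)
  idx_enf <- which(ifftshift(enforce))
  vals_enf <- ifftshift(grid$values)[idx_enf]
  denom_k <- sum(Mod(vals_enf))
  idx_free <- which(ifftshift(grid$withheld))
  has_free <- length(idx_free) > 0L
  if (has_free) {
    vals_free <- ifftshift(grid$values)[idx_free]
    denom_free <- sum(Mod(vals_free))
    has_free <- denom_free > 0
  }

  # radius (voxel units) of each enforced voxel, for the schedule band
  use_sched <- params$use_resolution_schedule
  if (use_sched) {
    fx <- freq_coords(M)
    ai <- arrayInd(idx_enf, rep(M, 3L))
    r_enf <- sqrt(fx[ai[, 1]]^2 + fx[ai[, 2]]^2 + fx[ai[, 3]]^2)
  }

  Fk <- array(0i, rep(M, 3L))
  if (params$init_mode == "random") {
    dc_val <- Re(grid$values[grid$dc[1], grid$dc[2], grid$dc[3]])
    with_seed(params$seed, {
      rho0 <- array(runif(M^3), rep(M, 3L)) * support_std
      s <- sum(rho0)
      if (s > 0 && dc_val > 0) rho0 <- rho0 * (dc_val / s)
      Fk <- fft3(rho0)
    })
  }
  Fk[idx_enf] <- vals_enf

  iters <- params$iterations
  rk <- numeric(iters)
  rfree <- rep(NA_real_, iters)
  best_rk <- Inf
  best_iter <- 1L
  best_rho <- NULL

  # rho and Fp are freshly allocated every iteration, so the in-place C++
  # helpers (constraint application, mismatch sums, enforcement) never touch
  # an array visible outside this loop
  for (i in seq_len(iters)) {
    rho <- Re(ifft3(Fk))
    cpp_support_positivity(rho, support_std)
    Fp <- fft3(rho)

    mis <- cpp_mismatch_sum(Fp, idx_enf, vals_enf)
    # an all-zero measured grid has zero denominator; a zero mismatch is
    # then a perfect fit, not an undefined one
    rk[i] <- if (denom_k > 0) mis / denom_k else if (mis == 0) 0 else Inf
    if (has_free) rfree[i] <- cpp_mismatch_sum(Fp, idx_free, vals_free) / denom_free
    if (!is.finite(rk[i])) {
      stop(errorCondition(
        sprintf("numerical failure (non-finite R-factor) at iteration %d", i),
        class = c("numerical_failure", "error")
      ))
    }
    if (rk[i] < best_rk) {
      best_rk <- rk[i]
      best_iter <- i
      best_rho <- rho
    }

    if (use_sched) {
      cutoff <- resolution_schedule(i - 1, iters, params)
      cpp_enforce(Fp, idx_enf, vals_enf, r_enf <= cutoff * (M / 2))
    } else {
      cpp_enforce(Fp, idx_enf, vals_enf)
    }
    Fk <- Fp
  }

  volume_full <- fftshift(best_rho)
  res <- structure(
    list(volume = crop_center(volume_full, N),
         volume_full = volume_full,
         rk_history = rk, rfree_history = rfree,
         best_iteration = best_iter,
         N = N, M = M,
         params = params),
    class = "tomo_reconstruction"
  )
  if (params$keep_fourier) res$fourier_final <- fftshift(Fk)
  res
}

#' @export
print.tomo_reconstruction <- function(x, ...) {
  n <- length(x$rk_history)
  cat("reconstruction: ", x$N, "^3 volume (grid ", x$M, "^3), ",
      n, " iterations\n", sep = "")
  cat(sprintf("  R_k: final %.4f, best %.4f at iteration %d\n",
              x$rk_history[n], min(x$rk_history), x$best_iteration))
  if (any(is.finite(x$rfree_history))) {
    cat(sprintf("  R_free: final %.4f\n", x$rfree_history[n]))
  }
  invisible(x)
}
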