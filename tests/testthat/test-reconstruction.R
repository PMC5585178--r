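test_that("real-space constraint zeroes negatives and outside-support voxels", {
  v <- array(rnorm(4^3), rep(4, 3))
  full <- array(TRUE, rep(4, 3))
  nonneg <- abs(v)
  expect_identical(apply_real_constraints(nonneg, full), nonneg)
  expect_identical(apply_real_constraints(array(-1, rep(4, 3)), full),
                   array(0, rep(4, 3)))
  sup <- array(FALSE, rep(4, 3)); sup[2:3, 2:3, 2:3] <- TRUE
  once <- apply_real_constraints(v, sup)
  expect_true(all(once[!sup] == 0))
  expect_true(all(once >= 0))
  expect_identical(apply_real_constraints(once, sup), once)  # idempotent
  expect_error(apply_real_constraints(v, array(TRUE, rep(5, 3))),
               class = "invalid_argument")
})

test_that("Fourier constraint enforces measured voxels and is idempotent", {
  series <- fixture_series(n = 8, J = 3)
  g <- assemble_grid(series, gridding_params(withheld_fraction = 0.1, seed = 1))
  Fc <- array(complex(real = rnorm(g$M^3), imaginary = rnorm(g$M^3)), rep(g$M, 3))
  none <- array(FALSE, rep(g$M, 3))
  expect_identical(apply_fourier_constraint(Fc, g, none), Fc)
  enf <- g$known & !g$withheld
  out <- apply_fourier_constraint(Fc, g, enf)
  expect_identical(out[enf], g$values[enf])
  expect_identical(out[!enf], Fc[!enf])
  expect_identical(apply_fourier_constraint(out, g, enf), out)
  # withheld voxels may never be enforced
  expect_error(apply_fourier_constraint(Fc, g, g$known),
               class = "invalid_argument")
})

test_that("r_factor matches hand-computed values", {
  d <- c(2, 1, 1)
  Fo <- array(c(1 + 0i, 2 + 0i), d)
  Fi <- array(c(2 + 0i, 2 + 0i), d)
  mask <- array(TRUE, d)
  expect_equal(r_factor(Fo, Fi, mask), 1 / 3)
  expect_equal(r_factor(Fo, Fo, mask), 0)
  expect_equal(r_factor(Fo, array(0i, d), mask), 1)
  expect_error(r_factor(Fo, Fi, array(FALSE, d)), class = "invalid_argument")
  expect_error(r_factor(array(0i, d), Fi, mask), class = "undefined_metric")
})

test_that("resolution schedule ramps up to Nyquist and mirrors back", {
  p <- reconstruction_params(use_resolution_schedule = TRUE)
  total <- 100L
  cuts <- vapply(0:(total - 1), resolution_schedule, numeric(1),
                 total = total, params = p)
  expect_equal(cuts[1], p$schedule_min_radius)
  expect_equal(cuts[total / 2 + 1], 1.0)  # iteration = total/2 (0-based)
  expect_true(all(diff(cuts[1:(total / 2)]) >= 0))
  expect_true(all(diff(cuts[(total / 2 + 1):total]) <= 0))
  expect_equal(cuts, rev(cuts))  # cutoff(i) == cutoff(total - 1 - i)
  # short runs still reach full enforcement at the midpoint
  expect_equal(resolution_schedule(5, 10, p), 1.0)
  expect_equal(resolution_schedule(0, 10, p), p$schedule_min_radius)
  expect_error(resolution_schedule(100, 100, p), class = "invalid_argument")
  expect_error(resolution_schedule(-1, 100, p), class = "invalid_argument")
})

test_that("an all-zero fully known grid reconstructs to zero immediately", {
  M <- 12L; N <- 4L
  g <- structure(
    list(values = array(0i, rep(M, 3)), known = array(TRUE, rep(M, 3)),
         withheld = array(FALSE, rep(M, 3)), dc = rep(M %/% 2 + 1L, 3),
         N = N, M = M, oversampling = 3, pixel_size = NULL),
    class = "fourier_grid"
  )
  r <- reconstruct(g, params = reconstruction_params(iterations = 3))
  expect_equal(max(abs(r$volume)), 0)
  expect_equal(r$rk_history, rep(0, 3))
})

test_that("dense noise-free sampling recovers the object to high accuracy", {
  ph <- make_phantom(16, "vesicle", seed = 7)
  angles <- rbind(cbind(0, seq(-89, 90, by = 1), 0),
                  cbind(90, seq(-89, 90, by = 1), 0))
  ts <- simulate_tilt_series(ph, angles, projector_params(3))
  g <- assemble_grid(ts, gridding_params(withheld_fraction = 0))
  r <- reconstruct(g, params = reconstruction_params(iterations = 50))
  nrmse <- sqrt(mean((r$volume - ph)^2)) / (max(ph) - min(ph))
  expect_lt(nrmse, 1e-2)
  # convergence: the final data mismatch does not exceed the initial one
  expect_lte(r$rk_history[50], r$rk_history[1] + 1e-6)
  # output satisfies the real-space constraints bit-exactly
  expect_true(all(r$volume >= 0))
  sup <- fouriertomo:::default_support(g$M, g$N)
  expect_identical(max(abs(r$volume_full[!sup])), 0)
})

test_that("full-range sampling recovers every shell below half Nyquist", {
  # with no missing wedge the pipeline is limited only by gridding
  # interpolation: FSC against the model stays near 1 below half Nyquist
  ph <- make_phantom(32, "vesicle", seed = 7)
  ts <- simulate_tilt_series(ph, seq(-89, 89, length.out = 71))
  g <- assemble_grid(ts, gridding_params(withheld_fraction = 0))
  r <- reconstruct(g, params = reconstruction_params(iterations = 100))
  f <- fsc(r$volume, ph)
  below <- f$shell_center < 0.5
  expect_gte(min(f$correlation[below]), 0.99)
})

test_that("the solver is deterministic with zero initialization", {
  series <- fixture_series(n = 12, J = 5)
  g <- assemble_grid(series, gridding_params(withheld_fraction = 0))
  r1 <- reconstruct(g, params = reconstruction_params(iterations = 8))
  r2 <- reconstruct(g, params = reconstruction_params(iterations = 8))
  expect_identical(r1$rk_history, r2$rk_history)
  expect_identical(r1$volume, r2$volume)
})

test_that("random initialization is reproducible from its seed and converges", {
  series <- fixture_series(n = 12, J = 5)
  g <- assemble_grid(series, gridding_params(withheld_fraction = 0))
  r1 <- reconstruct(g, params = reconstruction_params(
    iterations = 8, init_mode = "random", seed = 3))
  r2 <- reconstruct(g, params = reconstruction_params(
    iterations = 8, init_mode = "random", seed = 3))
  expect_identical(r1$rk_history, r2$rk_history)
  expect_lte(r1$rk_history[8], r1$rk_history[1])
})

test_that("reconstruct validates its inputs", {
  series <- fixture_series(n = 8, J = 2)
  g <- assemble_grid(series, gridding_params(withheld_fraction = 0))
  expect_error(reconstruct(g, support = array(TRUE, rep(4, 3))),
               class = "invalid_argument")
  expect_error(reconstruct(g, support = array(FALSE, rep(g$M, 3))),
               class = "invalid_argument")
  g_empty <- g; g_empty$known[] <- FALSE
  expect_error(reconstruct(g_empty), class = "invalid_argument")
  expect_error(reconstruction_params(iterations = 0), class = "invalid_argument")
  expect_error(reconstruction_params(schedule_min_radius = 0),
               class = "invalid_argument")
})
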