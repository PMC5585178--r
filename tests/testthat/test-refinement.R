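test_that("quality metric scores identical and shifted images correctly", {
  vol <- make_phantom(16, "blobs", seed = 8)
  img <- forward_project(vol, c(0, 20, 0))
  qm <- quality_metric(img, img, "xcorr")
  expect_equal(qm$score, 1, tolerance = 1e-12)
  expect_equal(qm$shift, c(0, 0))

  shifted <- fouriertomo:::shift_image(img, 1, 0)
  qs <- quality_metric(shifted, img, "xcorr")
  expect_gt(qs$score, 0.98)  # zero-padded shift loses one edge row
  expect_equal(qs$shift, c(1, 0))

  qr <- quality_metric(img, img, "rfactor")
  expect_equal(qr$score, 0)
  expect_equal(qr$shift, c(0, 0))

  expect_error(quality_metric(matrix(1, 8, 8), img, "xcorr"),
               class = "invalid_argument")
  expect_error(quality_metric(matrix(0, 16, 16), img, "xcorr"),
               class = "undefined_metric")
})

test_that("xcorr is invariant to global intensity rescaling", {
  vol <- make_phantom(16, "blobs", seed = 8)
  a <- forward_project(vol, c(0, 10, 0))
  b <- forward_project(vol, c(0, 12, 0))
  expect_equal(quality_metric(a, b, "xcorr")$score,
               quality_metric(a, 7.3 * b, "xcorr")$score, tolerance = 1e-12)
})

test_that("the C++ candidate scan agrees with the R quality metric", {
  vol <- make_phantom(16, "blobs", seed = 15)
  pt <- fouriertomo:::padded_transform(vol, 2)
  meas <- forward_project(vol, c(0, 25, 0))
  cand <- rbind(c(0, 24, 0), c(0, 25, 0), c(0, 26, 0), c(2, 25, -1))
  for (metric in c("xcorr", "rfactor")) {
    scan <- fouriertomo:::cpp_refine_scan(pt$F, dim(pt$F), pt$spacing,
                                          cand, meas, metric, 2L)
    ref <- vapply(seq_len(nrow(cand)), function(i) {
      calc <- fouriertomo:::project_from_transform(pt, cand[i, ], 16L)
      quality_metric(calc, meas, metric, 2L)$score
    }, numeric(1))
    expect_equal(scan$scores, ref, tolerance = 1e-9)
  }
})

test_that("zero search ranges return the input angles", {
  series <- fixture_series(n = 12, J = 5)
  res <- refine_angles(
    series,
    grid_params = gridding_params(withheld_fraction = 0),
    refine_params = refinement_params(delta_phi = 0, delta_theta = 0,
                                      delta_psi = 0, step = 0.5,
                                      recon_iterations = 5)
  )
  expect_equal(res$refined_angles, series$angles, ignore_attr = TRUE)
  expect_equal(res$outer_iterations, 1L)
})

test_that("refinement recovers deliberately perturbed tilt angles", {
  # single-axis perturbation large enough to displace features by >1 pixel
  vol <- make_phantom(24, "blobs", seed = 21)
  true_angles <- cbind(0, seq(-64, 64, length.out = 13), 0)
  ts <- simulate_tilt_series(vol, true_angles)
  set.seed(31)
  pert <- true_angles
  pert[, 2] <- pert[, 2] + runif(13, -4, 4)
  work <- ts; work$angles <- pert
  res <- refine_angles(
    work,
    grid_params = gridding_params(withheld_fraction = 0),
    refine_params = refinement_params(delta_phi = 0, delta_theta = 5,
                                      delta_psi = 0, step = 0.5,
                                      max_outer_iterations = 3,
                                      recon_iterations = 20)
  )
  err_before <- mean_geodesic_error(pert, true_angles)
  err_after <- mean_geodesic_error(res$refined_angles, true_angles)
  expect_lt(err_after, err_before)
  # per-component drift is bounded by the search budget
  expect_true(all(abs(res$refined_angles - pert) <= 3 * 5 + 1e-9))
  # mean best xcorr score does not degrade across outer iterations beyond
  # the scan's own score resolution (each pass rescores against a newly
  # built reconstruction, so exact monotonicity is not guaranteed)
  if (nrow(res$score_history) > 1) {
    expect_true(all(diff(rowMeans(res$score_history)) > -1e-4))
  }
})

test_that("refinement is deterministic", {
  series <- fixture_series(n = 12, J = 4)
  work <- series
  work$angles <- series$angles + 0.7
  args <- list(
    work,
    grid_params = gridding_params(withheld_fraction = 0),
    refine_params = refinement_params(delta_phi = 1, delta_theta = 1,
                                      delta_psi = 1, step = 0.5,
                                      max_outer_iterations = 2,
                                      recon_iterations = 5)
  )
  r1 <- do.call(refine_angles, args)
  r2 <- do.call(refine_angles, args)
  expect_identical(r1$refined_angles, r2$refined_angles)
  expect_identical(r1$score_history, r2$score_history)
})

test_that("refinement parameter validation", {
  expect_error(refinement_params(step = 0), class = "invalid_argument")
  expect_error(refinement_params(delta_phi = -1), class = "invalid_argument")
  expect_error(refinement_params(delta_phi = 1, delta_theta = 0, delta_psi = 0,
                                 step = 3), class = "invalid_argument")
})
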