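test_that("projection at identity equals the direct z-sum", {
  vol <- make_phantom(16, "blobs", seed = 3)
  p <- forward_project(vol, c(0, 0, 0))
  zsum <- apply(vol, c(1, 2), sum)
  expect_lt(max(abs(p - zsum)) / max(zsum), 1e-6)
})

test_that("a center impulse projects to the center pixel at any angles", {
  n <- 16L; c0 <- n %/% 2 + 1L
  imp <- array(0, rep(n, 3)); imp[c0, c0, c0] <- 1
  for (ang in list(c(0, 0, 0), c(20, 35, 50), c(0, 70.1, 0), c(-80, 12, 133))) {
    p <- forward_project(imp, ang)
    expect_equal(which.max(p), (c0 - 1L) * n + c0)
    # rotated slices lose out-of-array corner samples, so the discrete
    # impulse spreads slightly; the center pixel still dominates
    expect_gt(p[c0, c0], 0.7)
    expect_gt(p[c0, c0], 5 * max(abs(p[-((c0 - 1L) * n + c0)])))
  }
})

test_that("tilted projections match a real-space rotation oracle", {
  vol <- make_phantom(32, "blobs", seed = 9, smoothness = 1.5)
  for (theta in c(20, -35, 55)) {
    p <- forward_project(vol, c(0, theta, 0))
    oracle <- apply(rotate_about_y(vol, -theta), c(1, 2), sum)
    expect_gt(ncc(p, oracle), 0.99)
  }
})

test_that("the projector is linear and conserves integrated density", {
  v1 <- make_phantom(12, "blobs", seed = 1)
  v2 <- make_phantom(12, "blobs", seed = 2)
  ang <- c(15, 40, -30)
  p12 <- forward_project(2 * v1 + 3 * v2, ang)
  expect_equal(p12, 2 * forward_project(v1, ang) + 3 * forward_project(v2, ang),
               tolerance = 1e-9)
  for (theta in c(0, 33.3, 70.1)) {
    p <- forward_project(v1, c(0, theta, 0))
    expect_equal(sum(p), sum(v1), tolerance = 1e-6)
  }
  expect_error(forward_project(array(0, c(4, 4, 6)), c(0, 0, 0)),
               class = "invalid_argument")
})

test_that("simulate_tilt_series stacks projections with their angles", {
  vol <- make_phantom(12, "blobs", seed = 4)
  one <- simulate_tilt_series(vol, matrix(0, 1, 3))
  expect_equal(one$projections[, , 1], forward_project(vol, c(0, 0, 0)))
  tilts <- seq(-70.1, 70.1, length.out = 71)
  ts <- simulate_tilt_series(vol, tilts)
  expect_equal(dim(ts$projections), c(12, 12, 71))
  expect_equal(ts$angles[, "theta"], tilts, ignore_attr = TRUE)
  expect_equal(ts$angles[, "phi"], rep(0, 71), ignore_attr = TRUE)
  sums <- apply(ts$projections, 3, sum)
  expect_equal(sums, rep(sum(vol), 71), tolerance = 1e-6)
  # the angle file round-trips exactly at the written precision (6 decimals)
  f <- tempfile(fileext = ".txt")
  write_angles(ts$angles, f)
  expect_lt(max(abs(read_angles(f) - ts$angles)), 5e-7)
  expect_error(simulate_tilt_series(vol, matrix(0, 0, 3)), class = "invalid_argument")
})

test_that("gridding a simulated series reproduces the object transform", {
  vol <- make_phantom(16, "vesicle", seed = 7)
  ts <- simulate_tilt_series(vol, seq(-70, 70, length.out = 15),
                             projector_params(2))
  g <- assemble_grid(ts, gridding_params(withheld_fraction = 0))
  Fobj <- fouriertomo:::cfft3(fouriertomo:::embed_center(vol, g$M))
  known <- g$known & Mod(Fobj) > 1e-9 * max(Mod(Fobj))
  # inverse-distance gridding carries a first-order interpolation error of
  # order D * dF/dn, a few percent per voxel at D_th = 0.5
  rel <- Mod(g$values[known] - Fobj[known]) / Mod(Fobj[known])
  expect_lt(median(rel), 0.1)
  expect_lt(sum(Mod(g$values[known] - Fobj[known])) / sum(Mod(Fobj[known])), 0.1)
  # the low-frequency band is much more accurate
  ax <- seq_len(g$M) - g$dc[1]
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  low <- known & r <= g$M / 12
  expect_lt(median(Mod(g$values[low] - Fobj[low]) / Mod(Fobj[low])), 0.02)
})
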