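test_that("dft_point matches the zero-padded FFT oracle at integer frequencies", {
  set.seed(10)
  for (N in c(8L, 16L)) {
    img <- matrix(rnorm(N * N), N)
    M <- 3L * N
    dc <- floor(M / 2) + 1L
    ks <- -(M %/% 2):(M %/% 2 - 1)
    u <- as.vector(outer(ks, rep(1, M)))
    v <- as.vector(outer(rep(1, M), ks))
    vals <- dft_point(img, u, v, 3)
    oracle <- oracle_padded_fft(img, 3)[cbind(u + dc, v + dc)]
    expect_lt(max(Mod(vals - oracle)) / max(Mod(oracle)), 1e-9)
  }
})

test_that("dft_point is linear and equals the image sum at DC", {
  set.seed(11)
  f <- matrix(rnorm(64), 8); g <- matrix(rnorm(64), 8)
  expect_equal(Mod(dft_point(f, 0, 0, 3) - sum(f)), 0, tolerance = 1e-10)
  u <- runif(5, -10, 10); v <- runif(5, -10, 10)
  expect_equal(dft_point(f + g, u, v, 3),
               dft_point(f, u, v, 3) + dft_point(g, u, v, 3),
               tolerance = 1e-12)
  expect_error(dft_point(matrix(1, 3, 3), 0, 0, 3), class = "invalid_argument")
})

test_that("a single 0-degree projection grids onto the kz = 0 plane exactly", {
  set.seed(12)
  N <- 8L
  img <- matrix(abs(rnorm(N * N)), N)
  series <- tilt_series(array(img, c(N, N, 1)), matrix(0, 1, 3))
  g <- assemble_grid(series, gridding_params(withheld_fraction = 0))
  oracle <- oracle_padded_fft(img, 3)
  plane <- g$values[, , g$dc[3]]
  known <- g$known[, , g$dc[3]]
  expect_gt(sum(known), 0)
  expect_lt(max(Mod(plane[known] - oracle[known])) / max(Mod(oracle[known])), 1e-9)
  # no voxel off the plane is known (D >= D_th everywhere else)
  off <- g$known; off[, , g$dc[3]] <- FALSE
  expect_equal(sum(off), 0)
  # DC voxel equals the projection sum
  expect_equal(Mod(g$values[g$dc[1], g$dc[2], g$dc[3]] - sum(img)), 0,
               tolerance = 1e-9 * sum(img))
  # nothing outside the inscribed Nyquist sphere
  ax <- seq_len(g$M) - g$dc[1]
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  expect_false(any(g$known[r2 > (g$M / 2)^2]))
})

test_that("duplicated projections reproduce the single-projection grid", {
  set.seed(13)
  N <- 8L
  img <- matrix(abs(rnorm(N * N)) + 0.5, N)
  one <- assemble_grid(tilt_series(img, matrix(c(0, 30, 0), 1)),
                       gridding_params(withheld_fraction = 0))
  two <- assemble_grid(
    tilt_series(array(rep(img, 2), c(N, N, 2)), rbind(c(0, 30, 0), c(0, 30, 0))),
    gridding_params(withheld_fraction = 0)
  )
  expect_equal(two$known, one$known)
  expect_equal(two$values, one$values, tolerance = 1e-12)
})

test_that("assembled grids are Hermitian-symmetric and DC-consistent", {
  series <- fixture_series(n = 12, J = 5)
  g <- assemble_grid(series, gridding_params(withheld_fraction = 0))
  M <- g$M
  perm <- fouriertomo:::hermitian_perm(M)
  mate_known <- g$known[perm, perm, perm]
  expect_equal(g$known, mate_known)  # completion makes knowledge symmetric
  both <- g$known & mate_known
  diff <- Mod(g$values[both] - Conj(g$values[perm, perm, perm])[both])
  expect_lt(max(diff) / max(Mod(g$values[both])), 1e-9)
  # noise-free slices of one object agree at DC with each projection's sum
  sums <- apply(series$projections, 3, sum)
  expect_equal(rep(Mod(g$values[g$dc[1], g$dc[2], g$dc[3]]), 5), sums,
               tolerance = 1e-6)
})

test_that("known coverage grows monotonically with nested angle sets", {
  vol <- make_phantom(12, "blobs", seed = 5)
  tilts <- seq(-60, 60, length.out = 7)
  frac <- vapply(c(3, 5, 7), function(J) {
    ts <- simulate_tilt_series(vol, tilts[seq_len(J)])
    mean(assemble_grid(ts, gridding_params(withheld_fraction = 0))$known)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
})

test_that("FFT-mode gridding approximates DFT mode", {
  set.seed(14)
  vol <- make_phantom(16, "blobs", seed = 6)
  ts <- simulate_tilt_series(vol, c(-40, 10, 55))
  gd <- assemble_grid(ts, gridding_params(mode = "dft", withheld_fraction = 0))
  gf <- assemble_grid(ts, gridding_params(mode = "fft", withheld_fraction = 0))
  agree <- mean(gd$known == gf$known)
  expect_gte(agree, 0.9)
  joint <- gd$known & gf$known & Mod(gd$values) > 0
  rel <- Mod(gf$values[joint] - gd$values[joint]) / Mod(gd$values[joint])
  expect_lt(median(rel), 0.1)
  # aligned-plane case: identical to DFT mode
  img <- matrix(abs(rnorm(64)) + 0.2, 8)
  s0 <- tilt_series(img, matrix(0, 1, 3))
  g1 <- assemble_grid(s0, gridding_params(mode = "dft", withheld_fraction = 0))
  g2 <- assemble_grid(s0, gridding_params(mode = "fft", withheld_fraction = 0))
  expect_equal(g1$known, g2$known)
  expect_equal(g1$values, g2$values, tolerance = 1e-9)
})

test_that("gridding parameter validation and warnings", {
  expect_error(gridding_params(oversampling = 0.5), class = "invalid_argument")
  expect_error(gridding_params(distance_threshold = 0), class = "invalid_argument")
  expect_error(gridding_params(withheld_fraction = 1), class = "invalid_argument")
  series <- fixture_series(n = 8, J = 2)
  expect_warning(
    assemble_grid(series, gridding_params(distance_threshold = 1.2,
                                          withheld_fraction = 0)),
    "interpolation accuracy"
  )
  expect_warning(tilt_series(matrix(1, 9, 9), 0), "padding")
})

test_that("select_withheld is stratified, paired, and deterministic", {
  series <- fixture_series(n = 16, J = 9)
  g <- assemble_grid(series, gridding_params(withheld_fraction = 0))
  expect_equal(sum(g$withheld), 0)

  g5 <- select_withheld(g, 0.05, seed = 7)
  n_known <- sum(g5$known)
  n_wh <- sum(g5$withheld)
  expect_gt(n_wh, 0.9 * 0.05 * n_known)
  expect_lt(n_wh, 1.1 * 0.05 * n_known)
  expect_true(all(g5$known[g5$withheld]))
  # Hermitian mates are withheld together
  perm <- fouriertomo:::hermitian_perm(g$M)
  expect_equal(g5$withheld, g5$withheld[perm, perm, perm])
  # same seed, same mask; different seed, different mask
  expect_identical(select_withheld(g, 0.05, seed = 7)$withheld, g5$withheld)
  expect_false(identical(select_withheld(g, 0.05, seed = 8)$withheld, g5$withheld))
  expect_error(select_withheld(g, 1), class = "invalid_argument")
})
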