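test_that("monopole kernel matches its closed form and homogeneity", {
  # sigma and distance scalings
  at <- build_ellipsoid_mesh(c(10, 10, 10), 1)
  to <- build_ellipsoid_mesh(c(40, 40, 40), 0)
  A1 <- kernel_transfer_matrix(at, to, conductivity_s_m = 0.2)
  A2 <- kernel_transfer_matrix(at, to, conductivity_s_m = 0.4)
  expect_equal(A2$entries, A1$entries / 2)
  to2 <- build_ellipsoid_mesh(c(80, 80, 80), 0)
  A3 <- kernel_transfer_matrix(at, to2, conductivity_s_m = 0.2)
  # doubling every electrode distance about the shared centroid: entries
  # shrink, bounded by the 1/r kernel between the two hull distances
  expect_true(all(A3$entries < A1$entries))
  # explicit closed-form value
  at1 <- build_ellipsoid_mesh(c(1, 1, 1), 1)
  to1 <- build_ellipsoid_mesh(c(5, 5, 5), 0)
  Ak <- kernel_transfer_matrix(at1, to1, conductivity_s_m = 1)
  r <- sqrt(sum((to1$vertices[1, ] - at1$vertices[1, ])^2))
  expect_equal(Ak$entries[1, 1], node_areas(at1)[1] / (4 * pi * r))
})

test_that("WCT referencing zeroes the mean over the reference leads", {
  A <- kernel_transfer_matrix(build_ellipsoid_mesh(c(10, 10, 10), 1),
                              build_ellipsoid_mesh(c(40, 40, 40), 1))
  set.seed(2)
  x <- rnorm(ncol(A$entries))
  # all leads as WCT: every column has zero mean
  Aw <- apply_wct_reference(A)
  expect_lt(max(abs(colMeans(Aw$entries))), 1e-12)
  # arbitrary WCT subset: mean of A x over the subset is 0
  W <- c(3, 7, 21)
  As <- apply_wct_reference(A, W)
  expect_lt(abs(mean((As$entries %*% x)[W])), 1e-12)
  # singleton WCT zeroes that row
  A1 <- apply_wct_reference(A, 5)
  expect_lt(max(abs(A1$entries[5, ])), 1e-12)
  # double referencing is an API error (though the projector is idempotent)
  expect_error(apply_wct_reference(Aw), "already")
  P <- diag(nrow(A$entries)) - 1 / nrow(A$entries)
  expect_equal(P %*% P %*% A$entries, P %*% A$entries, tolerance = 1e-12)
})

test_that("forward projection is the plain linear map", {
  X <- potential_field(matrix(rnorm(12), 4, 3), fs = 100)
  I4 <- transfer_matrix(diag(4), referenced = TRUE)
  expect_equal(forward_project(I4, X)$values, X$values)
  A <- transfer_matrix(matrix(rnorm(8), 2, 4), referenced = TRUE)
  X0 <- potential_field(matrix(0, 4, 3), fs = 100)
  expect_equal(forward_project(A, X0)$values, matrix(0, 2, 3))
  X2 <- potential_field(matrix(rnorm(12), 4, 3), fs = 100)
  lhs <- forward_project(A, potential_field(X$values + X2$values, 100))$values
  expect_equal(lhs, forward_project(A, X)$values + forward_project(A, X2)$values,
               tolerance = 1e-12)
  expect_error(forward_project(A, potential_field(matrix(0, 5, 3), 100)),
               "columns")
})

test_that("noise injection hits the requested global SNR", {
  set.seed(4)
  Y <- potential_field(matrix(sin(seq_len(40000) / 7), 40, 1000), fs = 500)
  expect_identical(add_noise(Y, Inf), Y)
  Yn <- add_noise(Y, 20, seed = 9)
  snr <- 10 * log10(mean(Y$values^2) / mean((Yn$values - Y$values)^2))
  expect_lt(abs(snr - 20), 0.2)
  expect_identical(add_noise(Y, 20, seed = 9)$values, Yn$values)
  Y0 <- potential_field(matrix(0, 2, 10), fs = 10)
  expect_error(add_noise(Y0, 20), "zero-power")
})

test_that("zero-phase Butterworth band filtering has the stated response", {
  fs <- 500
  tt <- seq(0, 8, by = 1 / fs)[-1]
  tone6 <- potential_field(matrix(sin(2 * pi * 6 * tt), 1), fs = fs)
  out <- bandpass_filter(tone6, 3, 30)
  mid <- 1000:3000
  gain <- sd(out$values[1, mid]) / sd(tone6$values[1, mid])
  expect_lt(abs(gain - 1), 0.02)
  drift <- potential_field(matrix(sin(2 * pi * 0.5 * tt), 1), fs = fs)
  outd <- bandpass_filter(drift, 3, 30)
  att <- 20 * log10(sd(drift$values[1, mid]) / sd(outd$values[1, mid]))
  expect_gte(att, 20)
  dc <- potential_field(matrix(1 + 0 * tt, 1), fs = fs)
  outdc <- bandpass_filter(dc, 0, 30)
  expect_equal(mean(outdc$values[1, mid]), 1, tolerance = 1e-6)
  expect_error(bandpass_filter(tone6, 30, 3), "band")
  expect_error(bandpass_filter(tone6, 3, 400), "band")
})

test_that("transfer-matrix perturbation hits the requested per-row SER", {
  set.seed(5)
  A <- transfer_matrix(matrix(rnorm(5 * 2000), 5, 2000))
  expect_identical(perturb_transfer_matrix(A, Inf), A)
  Ap <- perturb_transfer_matrix(A, 20, seed = 3)
  ser <- 10 * log10(rowMeans(A$entries^2) /
                      rowMeans((Ap$entries - A$entries)^2))
  expect_true(all(abs(ser - 20) < 0.5))
  expect_identical(perturb_transfer_matrix(A, 20, seed = 3)$entries, Ap$entries)
  A0 <- transfer_matrix(rbind(rep(0, 10), rep(1, 10)))
  expect_error(perturb_transfer_matrix(A0, 20), "zero row")
})

test_that("identity forward model round-trips through the inverse at small lambda", {
  set.seed(6)
  n <- 12; T <- 40
  X <- matrix(rnorm(n * T), n, T)
  A <- diag(n)
  Xhat <- tikhonov_global(A, diag(n), X, 1e-12)
  expect_equal(Xhat, X, tolerance = 1e-6)
})
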