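test_that("regularization operators have the stated structure", {
  m <- test_atria()
  L2 <- regularization_operator(m, 2)$matrix
  expect_lt(max(abs(L2 %*% rep(1, ncol(L2)))), 1e-12)
  L1 <- regularization_operator(m, 1)$matrix
  expect_lt(max(abs(L1 %*% rep(3, ncol(L1)))), 1e-12)
  # 2-node, 1-edge toy of length 2 mm with values (3, 5) -> (5 - 3) / 2 = 1
  e <- mesh_edges(m)[1, ]
  len <- e$length
  vals <- numeric(m$n_vertices)
  vals[e$from] <- 3; vals[e$to] <- 5
  expect_equal(sum(abs(L1[1, ])), 2 / len)
  expect_equal(as.numeric(L1[1, , drop = FALSE] %*% vals), (5 - 3) / len)
  expect_error(regularization_operator(m, 3), "order")
})

test_that("Tikhonov solutions match hand cases and the SVD filter form", {
  expect_equal(tikhonov_instant(diag(2), diag(2), c(2, 4), 1), c(1, 2))
  expect_equal(tikhonov_instant(diag(c(2, 1)), diag(2), c(2, 1), 1),
               c(0.8, 0.5))
  A <- matrix(c(2, 1, 1, 3), 2)
  y <- c(1, -1)
  expect_equal(tikhonov_instant(A, diag(2), y, 0), solve(A, y))
  # normal equations vs filter factors on random rectangular systems
  set.seed(8)
  for (rep in 1:5) {
    Ar <- matrix(rnorm(20 * 30), 20, 30)
    yr <- rnorm(20)
    lam <- 10^runif(1, -3, 1)
    expect_equal(tikhonov_instant(Ar, diag(30), yr, lam),
                 svd_filter_solve(Ar, yr, "tik0", lam), tolerance = 1e-8)
  }
})

test_that("global Tikhonov equals stacked instantaneous solutions", {
  set.seed(9)
  A <- matrix(rnorm(8 * 10), 8, 10)
  Y <- matrix(rnorm(8 * 5), 8, 5)
  lam <- 0.3
  Xg <- tikhonov_global(A, diag(10), Y, lam)
  expect_equal(Xg[, 1], tikhonov_instant(A, diag(10), Y[, 1], lam))
  Xi <- sapply(1:5, function(t) tikhonov_instant(A, diag(10), Y[, t], lam))
  expect_equal(Xg, Xi, tolerance = 1e-10)
  # local optimality of the Frobenius objective
  obj <- function(X) sum((Y - A %*% X)^2) + lam * sum(X^2)
  o0 <- obj(Xg)
  for (i in 1:5) {
    expect_gte(obj(Xg + matrix(rnorm(50, sd = 1e-3), 10, 5)), o0)
  }
})

test_that("SVD filter solvers implement their filter factors", {
  A <- diag(c(2, 1))
  expect_equal(svd_filter_solve(A, c(2, 1), "dsvd", 1), c(2 / 3, 1 / 2))
  set.seed(10)
  An <- matrix(rnorm(16), 4, 4)
  y <- rnorm(4)
  expect_equal(svd_filter_solve(An, y, "tsvd0", 4), solve(An, y),
               tolerance = 1e-8)
  expect_error(svd_filter_solve(An, y, "tsvd0", 9), "k")
  expect_error(svd_filter_solve(An, y, "tsvd0", 0), "k")
})

test_that("truncated GSVD reduces to TSVD for L = I and matches the
           standard-form oracle", {
  set.seed(12)
  A <- matrix(rnorm(6 * 8), 6, 8)
  y <- rnorm(6)
  for (k in c(2, 4, 6)) {
    expect_equal(tsvd_higher_order(A, diag(8), y, k),
                 svd_filter_solve(A, y, "tsvd0", k), tolerance = 1e-8)
  }
  # independent oracle: transform to standard form with the SVD of L A^-1,
  # truncate exactly, transform back
  Ad <- diag(c(3, 2, 1))
  L <- rbind(c(-1, 1, 0), c(0, -1, 1))
  yd <- c(1, 2, 3)
  V <- svd(L %*% solve(Ad), nv = 3)$v
  ord <- c(3, 2, 1)     # null space of L first, then decreasing gamma
  for (k in 1:3) {
    keep <- V[, ord[seq_len(k)], drop = FALSE]
    oracle <- drop(solve(Ad) %*% keep %*% crossprod(keep, yd))
    expect_equal(tsvd_higher_order(Ad, L, yd, k), oracle, tolerance = 1e-10)
  }
  expect_equal(tsvd_higher_order(Ad, L, yd, 3), solve(Ad, yd),
               tolerance = 1e-10)
})

test_that("IRLS total variation minimizes the smoothed objective", {
  set.seed(13)
  A <- matrix(rnorm(12 * 10), 12, 10)
  L <- diff(diag(10))      # 1-D first difference
  # lambda = 0 -> least squares
  y <- rnorm(12)
  expect_equal(tv_solve(A, L, y, 0)$x, qr.solve(A, y), tolerance = 1e-10)
  # piecewise-constant truth, small noise
  x_true <- c(rep(1, 5), rep(-1, 5))
  y2 <- A %*% x_true + rnorm(12, sd = 0.01)
  r <- tv_solve(A, L, y2, 0.05, epsilon = 1e-4)
  expect_true(all(diff(r$objective) <= 1e-10))
  expect_true(r$converged)
  # TV recovers a sparser gradient than Tikhonov order 1 at the same lambda
  x_tik <- tikhonov_instant(A, L, y2, 0.05)
  g_tv <- abs(L %*% r$x); g_tik <- abs(L %*% x_tik)
  thr <- 0.01 * max(g_tv, g_tik)   # near-zero relative to the true jump
  expect_gte(mean(g_tv < thr), mean(g_tik < thr))
  expect_lt(stats::median(g_tv), stats::median(g_tik))
})

test_that("prior covariance estimation follows the zero-mean convention", {
  x <- c(1, -2, 3)
  train <- matrix(x, 3, 200)
  Cx <- estimate_prior_covariance(train, n_samples = 150, seed = 1)
  expect_equal(Cx, tcrossprod(x), tolerance = 1e-12)
  expect_error(estimate_prior_covariance(train, n_samples = 500), "exceeds")
  set.seed(14)
  W <- matrix(rnorm(10 * 5000), 10, 5000)
  Cw <- estimate_prior_covariance(W, n_samples = 4000, seed = 2)
  expect_equal(Cw, t(Cw))
  expect_true(all(eigen(Cw, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  expect_lt(max(abs(Cw - diag(10))), 0.2)
})

test_that("Bayes MAP matches its closed form, the Tikhonov identity and limits", {
  expect_equal(bayes_map(matrix(1), matrix(1), matrix(1), 2), 1)
  set.seed(15)
  A <- matrix(rnorm(6 * 9), 6, 9)
  y <- rnorm(6)
  lam <- 0.7
  expect_equal(bayes_map(A, diag(9) / lam, diag(6), y),
               svd_filter_solve(A, y, "tik0", lam), tolerance = 1e-8)
  As <- matrix(rnorm(16), 4, 4)
  ys <- rnorm(4)
  expect_equal(bayes_map(As, diag(4), diag(4) * 1e-12, ys), solve(As, ys),
               tolerance = 1e-4)
  expect_error(bayes_map(A, matrix(rnorm(81), 9, 9), diag(6), y), "symmetric")
})

test_that("Greensite solution respects its construction and limits", {
  set.seed(16)
  m <- build_ellipsoid_mesh(c(1, 1, 1), 1)   # 42 nodes
  n <- m$n_vertices
  A <- matrix(rnorm(12 * n), 12, n)
  L1 <- regularization_operator(m, 1)
  # rank-1 noiseless data: temporal course is recovered exactly
  x <- rnorm(n)
  v <- sin(seq_len(30)); v <- v / sqrt(sum(v^2))
  Y <- (A %*% x) %*% t(v)
  r <- greensite_solve(A, L1, Y, k_temporal = 1, lambda = 1e-8)
  sv <- svd(r$X)
  expect_gt(abs(sum(sv$v[, 1] * v)), 1 - 1e-6)
  # all-equal lambdas with full k equals global Tikhonov
  Y2 <- matrix(rnorm(12 * 7), 12, 7)
  rg <- greensite_solve(A, L1, Y2, k_temporal = 7, lambda = 0.3)
  expect_equal(rg$X, tikhonov_global(A, L1, Y2, 0.3), tolerance = 1e-8)
  expect_equal(greensite_solve(A, L1, matrix(0, 12, 5))$X, matrix(0, n, 5))
})

test_that("GMRES regularizes by iteration count", {
  y <- c(1, 2, 3)
  r <- gmres_solve(diag(3), y, 30)
  expect_equal(r$k_selected, 1L)
  expect_equal(r$x, y, tolerance = 1e-12)
  set.seed(17)
  S <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  ys <- rnorm(5)
  rs <- gmres_solve(S, ys, 5)
  expect_equal(rs$x, solve(S, ys), tolerance = 1e-6)
  expect_true(all(diff(rs$normal_residuals) <= 1e-8))
  # batched variant agrees with the scalar one
  A <- matrix(rnorm(8 * 12), 8, 12)
  Y <- matrix(rnorm(8 * 3), 8, 3)
  rb <- ecgibench:::gmres_batch(A, Y, 10)
  for (t in 1:3) {
    r1 <- gmres_solve(A, Y[, t], 10)
    expect_equal(rb$X[, t], r1$x, tolerance = 1e-8)
  }
})

test_that("L-curve selection finds the corner of a classic ill-posed problem", {
  # random orthogonal factors with a prescribed four-decade spectrum, smooth
  # truth, 1% noise: a textbook L-shape with its corner inside the bounds
  set.seed(18)
  n <- 24
  U <- qr.Q(qr(matrix(rnorm(n * n), n)))
  V <- qr.Q(qr(matrix(rnorm(n * n), n)))
  A <- U %*% (10^seq(0, -4, length.out = n) * t(V))
  x_true <- V %*% (1 / (1:n))
  y <- A %*% x_true + rnorm(n, sd = 0.01 * sd(A %*% x_true))
  sel <- lcurve_lambda(A, NULL, y, n_points = 80)
  expect_false(sel$low_confidence)
  # independent dense evaluation: direct solves on the same grid, curvature
  # by an independently coded circumcircle formula
  grid <- sel$curve$lambda
  rho <- eta <- numeric(length(grid))
  for (i in seq_along(grid)) {
    xi <- solve(crossprod(A) + grid[i] * diag(n), crossprod(A, y))
    rho[i] <- sqrt(sum((y - A %*% xi)^2))
    eta[i] <- sqrt(sum(xi^2))
  }
  lx <- log(rho); ly <- log(eta)
  curv <- rep(NA_real_, length(grid))
  for (i in 2:(length(grid) - 1)) {
    a <- c(lx[i - 1], ly[i - 1]); b <- c(lx[i], ly[i]); cc <- c(lx[i + 1], ly[i + 1])
    cr <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
    curv[i] <- 2 * cr / (sqrt(sum((b - a)^2)) * sqrt(sum((cc - b)^2)) *
                           sqrt(sum((cc - a)^2)))
  }
  pos <- which(curv > 0)
  peaks <- pos[vapply(pos, function(i) {
    i > 1 && i < length(grid) && !is.na(curv[i - 1]) && !is.na(curv[i + 1]) &&
      curv[i] >= curv[i - 1] && curv[i] >= curv[i + 1]
  }, logical(1))]
  best <- peaks[which.max(curv[peaks])]
  expect_lte(abs(which(grid == sel$lambda) - best), 1)
  # contract basics
  expect_true(sel$lambda >= min(grid) && sel$lambda <= max(grid))
  one <- lcurve_lambda(A, NULL, y, n_points = 1, bounds = c(0.01, 0.01))
  expect_equal(one$lambda, 0.01)
})

test_that("oracle lambda minimizes RDMS and refines stably", {
  set.seed(19)
  A <- matrix(rnorm(15 * 15), 15, 15) + 5 * diag(15)
  x_true <- rnorm(15)
  y <- A %*% x_true   # noiseless
  orc <- oracle_lambda(A, NULL, y, x_true, n_points = 200)
  expect_equal(orc$lambda, min(orc$grid))  # smaller lambda always better
  # oracle beats the L-curve choice by construction
  lc <- lcurve_lambda(A, NULL, y, n_points = 200)
  idx <- which.min(abs(orc$grid - lc$lambda))
  expect_lte(orc$rdms, orc$rdms_curve[idx] + 1e-12)
  # noisy case: grid refinement changes the attained RDMS by < 1%
  yn <- y + rnorm(15, sd = 0.05 * sd(y))
  o1 <- oracle_lambda(A, NULL, yn, x_true, n_points = 100)
  o2 <- oracle_lambda(A, NULL, yn, x_true, n_points = 1000)
  expect_lt(abs(o1$rdms - o2$rdms) / o2$rdms, 0.01)
})

test_that("solver family invariants hold on random systems", {
  set.seed(20)
  A <- matrix(rnorm(10 * 14), 10, 14)
  y <- rnorm(10)
  # linearity in y for the linear solvers
  expect_equal(svd_filter_solve(A, 3 * y, "tik0", 0.2),
               3 * svd_filter_solve(A, y, "tik0", 0.2), tolerance = 1e-10)
  expect_equal(bayes_map(A, diag(14), diag(10), 3 * y),
               3 * bayes_map(A, diag(14), diag(10), y), tolerance = 1e-10)
  # monotone regularization for tik0
  lams <- 10^seq(-4, 2, length.out = 20)
  norms <- resids <- numeric(20)
  for (i in seq_along(lams)) {
    xi <- svd_filter_solve(A, y, "tik0", lams[i])
    norms[i] <- sqrt(sum(xi^2))
    resids[i] <- sqrt(sum((y - A %*% xi)^2))
  }
  expect_true(all(diff(norms) <= 1e-10))
  expect_true(all(diff(resids) >= -1e-10))
})

test_that("the named-solver interface is reproducible and validates input", {
  A <- test_transfer()
  m <- test_atria()
  ph <- test_phantom("SAF")
  Yw <- field_window(bandpass_filter(add_noise(
    forward_project(A, ph$field), 20, seed = 3), 3, 30), 4, 5)
  expect_error(ecgi_solve(A, Yw, "NotASolver"), "unknown solver")
  expect_error(ecgi_solve(A, Yw, "Bayes"), "C_x")
  s1 <- ecgi_solve(A, Yw, "Tik-g0", mesh = m)
  s2 <- ecgi_solve(A, Yw, "Tik-g0", mesh = m)
  expect_identical(s1$estimate$values, s2$estimate$values)
  td <- tidy(s1)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), ncol(Yw$values))
  expect_equal(nrow(glance(s1)), 1L)
})
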