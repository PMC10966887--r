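test_that("monomial expansion has the combinatorial count and ordering", {
  expect_identical(ncol(expand_features(matrix(rnorm(8), 2), 1)), 5L)
  expect_identical(ncol(expand_features(matrix(rnorm(8), 2), 2)), 15L)   # C(6,2)
  expect_identical(nrow(monomial_exponents(5)), 126L)                    # C(9,5)
  # brute-force enumeration oracle for degree 2
  cnt <- 0L
  for (a in 0:2) for (b in 0:2) for (c in 0:2) for (d in 0:2)
    if (a + b + c + d <= 2) cnt <- cnt + 1L
  expect_identical(nrow(monomial_exponents(2)), cnt)
  m <- expand_features(c(0, 0, 0, 0), 3)
  expect_equal(as.numeric(m), c(1, rep(0, ncol(m) - 1)))
  expect_error(monomial_exponents(6), "\\[1, 5\\]")
})

test_that("poly degree 1 interpolates exactly affine data and recovers the map", {
  s <- affine_samples(5, seed = 2)              # exactly determined: 5 samples
  f <- gaze_calib(s, method = "poly", degree = 1)
  expect_lt(max(abs(residuals(f))), 1e-9)
  cf <- coef(f)
  expect_equal(unname(cf[, "x"]), c(0.5, 0.8, -0.2, 0.3, 0.1), tolerance = 1e-9)
  expect_equal(unname(cf[, "y"]), c(0.4, -0.1, 0.7, 0.05, -0.3), tolerance = 1e-9)
})

test_that("prediction equals the manual coefficient-monomial dot product", {
  s <- affine_samples(80, seed = 3)
  f <- gaze_calib(s, method = "poly", degree = 3)
  fv <- c(0.21, -0.13, 0.05, 0.32)
  manual <- as.numeric(expand_features(fv, 3) %*% coef(f))
  expect_equal(as.numeric(predict(f, fv)), manual, tolerance = 1e-12)
  expect_identical(predict(f, fv), predict(f, fv))  # deterministic
})

test_that("zero-noise polynomial-generated targets are fitted to machine precision", {
  set.seed(8)
  X <- matrix(runif(200 * 4, -0.5, 0.5), 200, 4)
  M <- expand_features(X, 2)
  gx <- rnorm(ncol(M), sd = 0.3); gy <- rnorm(ncol(M), sd = 0.3)
  s <- data.frame(frame = 1:200, target_x = M %*% gx, target_y = M %*% gy,
                  phi_l = X[, 1], theta_l = X[, 2], phi_r = X[, 3], theta_r = X[, 4])
  for (deg in 2:3) {
    f <- gaze_calib(s, method = "poly", degree = deg)
    expect_lt(max(abs(residuals(f))), 1e-8)
  }
})

test_that("ridge converges to the least-squares solution as alpha -> 0", {
  s <- affine_samples(60, seed = 4)
  fp <- gaze_calib(s, method = "poly", degree = 2)
  dist <- vapply(c(1, 1e-4, 1e-8), function(a) {
    fr <- gaze_calib(s, method = "ridge", degree = 2, alpha = a)
    max(abs(coef(fr, standardized = FALSE) - coef(fp)))
  }, 1)
  expect_true(all(diff(dist) < 0))
  expect_lt(dist[3], 1e-6)
})

test_that("ridge closed form minimises the printed penalised loss", {
  s <- affine_samples(30, seed = 5)
  s$target_x <- s$target_x + rnorm(30, sd = 0.05)
  alpha <- 0.7
  f <- gaze_calib(s, method = "ridge", degree = 2, alpha = alpha)
  M <- expand_features(as.matrix(s[, c("phi_l", "theta_l", "phi_r", "theta_r")]), 2)
  Z <- scale(M[, -1])
  loss <- function(g) {
    pred <- g[1] + Z %*% g[-1]
    sum((s$target_x - pred)^2) + alpha * sum(g[-1]^2)
  }
  ours <- unname(f$coef[, "x"])
  # numeric minimisation oracle from a different start
  opt <- optim(rep(0, length(ours)), loss, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_lte(loss(ours), loss(opt$par) + 1e-9)
  expect_equal(ours, opt$par, tolerance = 1e-4)
})

test_that("lasso solution satisfies the KKT conditions of the printed loss", {
  set.seed(6)
  s <- affine_samples(80, seed = 6)
  s$target_x <- s$target_x + rnorm(80, sd = 0.03)
  alpha <- 0.05
  f <- gaze_calib(s, method = "lasso", degree = 2, alpha = alpha)
  M <- expand_features(as.matrix(s[, c("phi_l", "theta_l", "phi_r", "theta_r")]), 2)
  Z <- scale(M[, -1])
  g <- unname(f$coef[, "x"])
  r <- s$target_x - (g[1] + Z %*% g[-1])
  grad <- 2 * crossprod(Z, r)              # d sse / d gamma_j = -2 Z^T r
  active <- g[-1] != 0
  # tolerances reflect the coordinate-descent convergence threshold
  expect_true(all(abs(grad[active] - alpha * sign(g[-1][active])) < 0.05 * alpha))
  expect_true(all(abs(grad[!active]) <= alpha * 1.05))
  expect_lt(abs(mean(r)), 1e-8)            # intercept unpenalised
})

test_that("penalised coefficient norms are non-increasing in alpha", {
  s <- affine_samples(60, seed = 9)
  s$target_x <- s$target_x + rnorm(60, sd = 0.05)
  alphas <- c(1e-4, 1e-2, 0.1, 1, 2)
  for (fam in c("ridge", "lasso")) {
    nrm <- vapply(alphas, function(a) {
      f <- gaze_calib(s, method = fam, degree = 2, alpha = a)
      sum(abs(f$coef[-1, ]))
    }, 1)
    expect_true(all(diff(nrm) <= 1e-8))
  }
})

test_that("ransac rejects planted gross outliers that break plain least squares", {
  s <- affine_samples(50, seed = 10)
  bad <- s
  out_idx <- 1:5
  bad$target_x[out_idx] <- bad$target_x[out_idx] + c(3, -4, 5, 3.5, -3)
  bad$target_y[out_idx] <- bad$target_y[out_idx] - c(2, 3, -4, 2.5, 3)
  fr <- gaze_calib(bad, method = "ransac", degree = 1, seed = 42)
  fp <- gaze_calib(bad, method = "poly", degree = 1)
  truth <- affine_samples(50, seed = 10)
  err_r <- max(abs(predict(fr, truth) - cbind(truth$target_x, truth$target_y)))
  err_p <- max(abs(predict(fp, truth) - cbind(truth$target_x, truth$target_y)))
  expect_lt(err_r, 1e-6)        # recovers the generating affine map
  expect_gt(err_p, 0.05)        # least squares is dragged by the outliers
  expect_lt(sum(fr$ransac$inliers_x), 50)
})

test_that("ransac demands strictly more samples than monomials", {
  s <- affine_samples(15, seed = 11)
  expect_error(gaze_calib(s, method = "ransac", degree = 2), "ransac.*15")
  expect_error(gaze_calib(s, method = "ransac", degree = 4), "degrees 1-3")
})

test_that("underdetermined poly fits use the minimum-norm solution and interpolate", {
  s <- affine_samples(5, seed = 12)
  f <- gaze_calib(s, method = "poly", degree = 4)   # 70 monomials, 5 samples
  expect_lt(max(abs(residuals(f))), 1e-8)
})

test_that("fits are invariant to training-sample order", {
  s <- affine_samples(60, seed = 13)
  s$target_x <- s$target_x + rnorm(60, sd = 0.02)
  perm <- sample(60)
  fv <- c(0.1, 0.2, -0.1, 0.05)
  for (fam in c("poly", "ridge", "lasso")) {
    f1 <- gaze_calib(s, method = fam, degree = 2, alpha = 0.1)
    f2 <- gaze_calib(s[perm, ], method = fam, degree = 2, alpha = 0.1)
    expect_equal(predict(f1, fv), predict(f2, fv), tolerance = 1e-6)
  }
})

test_that("svr kernels match their closed forms and fit smooth data", {
  U <- matrix(c(1, 0, 0.5, -0.2, 0, 1, 0.3, 0.4), 2, 4, byrow = TRUE)
  V <- matrix(c(0.2, 0.1, -0.3, 0.6), 1, 4)
  lin <- gazesim:::svr_kernel_eval("linear", 0.25, 2, U, V)
  expect_equal(as.numeric(lin), as.numeric(U %*% t(V)), tolerance = 1e-12)
  pol <- gazesim:::svr_kernel_eval("poly", 0.25, 2, U, V)
  expect_equal(as.numeric(pol), (0.25 * as.numeric(U %*% t(V)))^2, tolerance = 1e-12)
  rbf <- gazesim:::svr_kernel_eval("rbf", 0.25, 2, U, V)
  d2 <- rowSums(sweep(U, 2, as.numeric(V))^2)
  expect_equal(as.numeric(rbf), exp(-0.25 * d2), tolerance = 1e-12)

  s <- clean_samples(pattern_full(), kh = 0.05)
  f <- gaze_calib(s, method = "svr", kernel = "rbf", cost = 5, epsilon = 1e-3)
  expect_lt(sqrt(mean((predict(f, s) - cbind(s$target_x, s$target_y))^2)), 0.05)
})

test_that("model print, summary, coef and plot methods run", {
  s <- affine_samples(40, seed = 14)
  f <- gaze_calib(s, method = "ridge", degree = 2, alpha = 0.01)
  expect_output(print(f), "ridge")
  expect_output(print(summary(f)), "standardized")
  expect_identical(dim(coef(f)), c(15L, 2L))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
  fs <- gaze_calib(s, method = "svr")
  expect_message(coef(fs), "no polynomial")
})
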