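make_seq <- function(phi, theta) cbind(phi = phi, theta = theta)

test_that("each noise process is the identity when its parameter is zero", {
  gv <- make_seq(seq(-0.5, 0.5, length.out = 50), seq(0.4, -0.4, length.out = 50))
  expect_equal(apply_systematic(gv, noise_config(p_error = 0)), gv)
  expect_equal(apply_precision(gv, noise_config(sigma_prec = 0)), gv)
  expect_equal(apply_false_detections(gv, noise_config(p_fd = 0)), gv)
  samp <- clean_samples(pattern_full())
  expect_equal(apply_noise(samp, noise_off()), samp)
})

test_that("systematic weight vanishes at the sequence extremes", {
  # frame 1 sits at (phi_max, theta_max): even with p_error = 1 it stays put
  gv <- make_seq(c(0.6, 0.0), c(0.5, 0.0))
  set.seed(1)
  out <- apply_systematic(gv, noise_config(p_error = 1, r_error = 0.5))
  expect_equal(out[1, ], gv[1, ], tolerance = 1e-15)
  expect_false(isTRUE(all.equal(out[2, ], gv[2, ])))
})

test_that("systematic offsets follow the adopted formula exactly", {
  n <- 200
  gv <- make_seq(runif(n, -0.6, 0.6), runif(n, -0.5, 0.5))
  cfg <- noise_config(p_error = 0.3, r_error = 0.5)
  set.seed(99)
  out <- apply_systematic(gv, cfg)
  # independent replay of the documented sampling scheme
  set.seed(99)
  hit <- runif(n) < 0.3
  u1 <- runif(n); u2 <- runif(n)
  pmax_ <- max(abs(gv[, 1])); tmax_ <- max(abs(gv[, 2]))
  w <- (2 - abs(gv[, 1]) / pmax_ - abs(gv[, 2]) / tmax_) / 2
  exp_phi <- gv[, 1] + ifelse(hit, w * 4 * (u1 - 0.5) * 0.5 / pi, 0)
  exp_theta <- gv[, 2] + ifelse(hit, w * 4 * (u2 - 0.5) * 0.5 / pi, 0)
  expect_equal(unname(out[, 1]), exp_phi, tolerance = 1e-15)
  expect_equal(unname(out[, 2]), exp_theta, tolerance = 1e-15)
  # zero-gaze frame with u = 1 would get the maximal offset 1/pi
  expect_true(all(abs(out[, 1] - gv[, 1]) <= 1 / pi + 1e-12))
})

test_that("systematic perturbation bound decreases with gaze eccentricity", {
  # magnitude bound w * 2 * r_error / pi is non-increasing in
  # |phi|/phi_max + |theta|/theta_max
  ecc <- seq(0, 2, length.out = 21)
  w <- (2 - ecc) / 2
  expect_true(all(diff(w * 2 * 0.5 / pi) <= 0))
  # empirically: maximal observed offset at high eccentricity stays below
  # the bound at low eccentricity
  gv <- make_seq(c(rep(0.01, 500), rep(0.59, 500), 0.6), rep(c(0.01, 0.6), c(1000, 1)))
  set.seed(3)
  out <- apply_systematic(gv, noise_config(p_error = 1, r_error = 0.5))
  d <- abs(out[, 1] - gv[, 1])
  expect_gt(max(d[1:500]), max(d[501:1000]))
})

test_that("precision noise is white Gaussian with the configured sd", {
  n <- 1e5
  gv <- make_seq(numeric(n), numeric(n))
  set.seed(11)
  out <- apply_precision(gv, noise_config(sigma_prec = 0.005))
  dev <- c(out[, 1], out[, 2])
  expect_lt(abs(sd(dev) - 0.005) / 0.005, 0.01)        # within 1%
  ks <- suppressWarnings(ks.test(dev[1:1e4], "pnorm", 0, 0.005))
  expect_gt(ks$p.value, 0.01)
})

test_that("false-detection offsets are bounded and bursts cover the expected fraction", {
  n <- 1e6
  gv <- make_seq(numeric(n), numeric(n))
  set.seed(21)
  out <- apply_false_detections(gv, noise_config(p_fd = 0.005, burst_min = 1, burst_max = 9))
  d <- abs(out[, 1])
  expect_true(all(d <= pi / 4 + 1e-12))
  frac <- mean(out[, 1] != 0 | out[, 2] != 0)
  # overlap-adjusted expectation ~ 1 - (1 - p)^E[n] = 2.47% for p = 0.005
  expect_gt(frac, 0.023)
  expect_lt(frac, 0.027)
})

test_that("frozen bursts hold one offset over their frames", {
  n <- 5000
  gv <- make_seq(numeric(n), numeric(n))
  set.seed(5)
  out <- apply_false_detections(gv, noise_config(p_fd = 0.004, burst_min = 5,
                                                 burst_max = 9, freeze_burst = TRUE))
  hits <- which(out[, 1] != 0)
  runs <- split(hits, cumsum(c(1, diff(hits) != 1)))
  long_runs <- Filter(function(r) length(r) >= 3, runs)
  expect_gt(length(long_runs), 0)
  reused <- vapply(long_runs, function(r) length(unique(out[r, 1])), 1L)
  expect_true(all(reused <= 2))  # one value per burst (two where bursts abut)
})

test_that("apply_noise chains the processes deterministically per seed", {
  samp <- clean_samples(pattern_full(), kh = 0.06, kv = 0.01)
  cfg <- noise_config(seed = 123)
  a <- apply_noise(samp, cfg)
  b <- apply_noise(samp, cfg)
  expect_identical(a, b)
  c2 <- apply_noise(samp, noise_config(seed = 124))
  expect_false(identical(a, c2))
  expect_equal(a$target_x, samp$target_x)  # targets untouched
})
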