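test_that("image centre maps onto the scene-camera optical axis", {
  cfg <- default_scene
  p <- image_to_scene_point(0.5, 0.5, cfg)
  expect_equal(as.numeric(p),
               cfg$scene_cam_origin + cfg$target_plane_distance * cfg$scene_cam_forward,
               tolerance = 1e-12)
  expect_equal(as.numeric(scene_point_to_image(p, cfg)), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("corner backprojections are symmetric about the axis point", {
  cfg <- default_scene
  centre <- as.numeric(image_to_scene_point(0.5, 0.5, cfg))
  p00 <- as.numeric(image_to_scene_point(0, 0, cfg))
  p11 <- as.numeric(image_to_scene_point(1, 1, cfg))
  expect_equal((p00 + p11) / 2, centre, tolerance = 1e-9)
})

test_that("lateral offset follows the equi-angular closed form", {
  cfg <- scene_config(fov_h_deg = 80, target_plane_distance = 1000)
  p <- image_to_scene_point(0.75, 0.5, cfg)
  # independent trigonometric hand computation: quarter image to the right
  # of centre is 20 deg of view angle, offset = distance * tan(20 deg)
  expect_equal(p[1, "x"] - cfg$scene_cam_origin[1], 1000 * tan(20 * pi / 180),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(p[1, "z"], 1000, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("image <-> scene round trip is the identity on the target plane", {
  cfg <- scene_config(scene_cam_forward = c(0.1, -0.05, 1))  # tilted camera
  set.seed(42)
  x <- runif(100); y <- runif(100)
  p <- image_to_scene_point(x, y, cfg)
  xy <- scene_point_to_image(p, cfg)
  expect_lt(max(abs(xy[, "x"] - x)), 1e-9)
  expect_lt(max(abs(xy[, "y"] - y)), 1e-9)
})

test_that("domain errors: fractions outside [0,1] and points behind the camera", {
  cfg <- default_scene
  expect_error(image_to_scene_point(-0.1, 0.5, cfg), "\\[0, 1\\]")
  expect_error(image_to_scene_point(0.2, 1.4, cfg), "\\[0, 1\\]")
  expect_error(scene_point_to_image(c(0, 0, -10), cfg), "behind")
})

test_that("kappa_to_alpha is zero at zero, odd, monotone, and -> kappa as b grows", {
  expect_identical(kappa_to_alpha(0, 12, 1000), 0)
  k <- seq(0.05, 1.4, by = 0.05)
  a <- kappa_to_alpha(k, 12, 500)
  expect_true(all(diff(a) > 0))                      # monotone on [0, pi/2)
  expect_equal(kappa_to_alpha(-k, 12, 500), -a, tolerance = 1e-12)  # odd
  expect_true(all(abs(a) <= abs(k)))
  expect_equal(kappa_to_alpha(0.3, 12, 1e9), 0.3, tolerance = 1e-7) # b -> Inf
  expect_error(kappa_to_alpha(0.1, 12, 10), "exceed")
})

test_that("kappa_to_alpha matches a high-precision direct evaluation", {
  k <- 5 * pi / 180
  # alpha = 5deg - asin(0.012 * sin(175 deg)), evaluated independently
  expected <- k - asin((12 / 1000) * sin(pi - k))
  expect_equal(kappa_to_alpha(k, 12, 1000), expected, tolerance = 1e-14)
  expect_equal(expected * 180 / pi, 4.94008, tolerance = 1e-4)
})

test_that("optical axis points at the target for zero kappa", {
  eye <- c(-32, 0, 0); target <- c(150, -80, 1000)
  ax <- optical_axis_for_target(eye, target, kappa_pair(0, 0), 12)
  expect_equal(ax, (target - eye) / sqrt(sum((target - eye)^2)), tolerance = 1e-12)
})

test_that("horizontal kappa rotates the axis by exactly alpha_hori", {
  eye <- c(32, 0, 0); target <- c(-100, 50, 900); r <- 12
  b <- sqrt(sum((target - eye)^2))
  for (k in c(-0.2, 0.05, 0.15)) {
    ax <- optical_axis_for_target(eye, target, kappa_pair(k, 0), r)
    d <- (target - eye) / b
    ang <- acos(min(1, sum(ax * d)))
    expect_equal(ang, abs(kappa_to_alpha(k, r, b)), tolerance = 1e-9)
  }
})

test_that("mirrored targets with mirrored kappa give mirrored axes", {
  eye_l <- c(-32, 0, 0); eye_r <- c(32, 0, 0)
  t1 <- c(200, 30, 1000); t2 <- c(-200, 30, 1000)
  a1 <- optical_axis_for_target(eye_l, t1, kappa_pair(0.1, 0.02), 12)
  a2 <- optical_axis_for_target(eye_r, t2, kappa_pair(-0.1, 0.02), 12)
  expect_equal(a1[1], -a2[1], tolerance = 1e-12)
  expect_equal(a1[2:3], a2[2:3], tolerance = 1e-12)
})

test_that("gaze vector is zero for an axis parallel to the eye-camera line", {
  eye <- c(0, 0, 0); cam <- c(0, -30, 20)
  gv <- gaze_vector(eye, cam, (cam - eye) / sqrt(sum(cam^2)))
  expect_equal(unname(gv), c(0, 0), tolerance = 1e-12)
})

test_that("planar 45-degree case and sign conventions", {
  eye <- c(0, 0, 0)
  cam <- c(0, 0, 1)            # ce along +z in the x-z plane
  gv <- gaze_vector(eye, cam, c(1, 0, 1) / sqrt(2))
  expect_equal(unname(gv["phi"]), pi / 4, tolerance = 1e-12)  # rightward positive
  gv_left <- gaze_vector(eye, cam, c(-1, 0, 1) / sqrt(2))
  expect_equal(unname(gv_left["phi"]), -pi / 4, tolerance = 1e-12) # leftward negative
  gv_down <- gaze_vector(eye, cam, c(0, -1, 2) / sqrt(5))
  expect_lt(unname(gv_down["theta"]), 0)                      # downward negative
})

test_that("gaze-vector magnitudes match the arccos formula on random axes", {
  set.seed(7)
  eye <- c(-32, 0, 0); cam <- c(-32, -30, 20)
  ce <- cam - eye
  for (i in 1:25) {
    o <- c(runif(1, -0.7, 0.7), runif(1, -0.7, 0.7), 1)
    o <- o / sqrt(sum(o^2))
    gv <- gaze_vector(eye, cam, o)
    clamp <- function(v) min(1, max(-1, v))
    phi_mag <- acos(clamp(sum(ce[c(1, 3)] * o[c(1, 3)]) /
                      (sqrt(sum(ce[c(1, 3)]^2)) * sqrt(sum(o[c(1, 3)]^2)))))
    theta_mag <- acos(clamp(sum(ce[c(2, 3)] * o[c(2, 3)]) /
                        (sqrt(sum(ce[c(2, 3)]^2)) * sqrt(sum(o[c(2, 3)]^2)))))
    # acos is ill-conditioned near zero angle, so compare absolutely
    expect_lt(abs(abs(unname(gv["phi"])) - phi_mag), 1e-12)
    expect_lt(abs(abs(unname(gv["theta"])) - theta_mag), 1e-12)
  }
})

test_that("degenerate projections raise a domain error", {
  expect_error(gaze_vector(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1)), "degenerate")
})

test_that("simulate_pattern emits one sample per target in order", {
  s <- clean_samples(pattern_grid20())
  expect_identical(nrow(s), 400L)
  expect_identical(s$frame, 1:400)
  expect_equal(s$target_x, pattern_grid20()$x)
})

test_that("central target yields near-symmetric opposite-sign vergence", {
  centre <- make_npoint(5)[5, , drop = FALSE]
  s <- simulate_pattern(centre, default_scene)
  expect_gt(s$phi_l, 0)
  expect_lt(s$phi_r, 0)
  expect_equal(s$phi_l, -s$phi_r, tolerance = 1e-9)
  expect_equal(s$theta_l, s$theta_r, tolerance = 1e-9)
})

test_that("gaze vectors vary monotonically along a grid row", {
  g <- make_grid(2, 20)
  s <- simulate_pattern(g[g$y == 0, ], default_scene)
  expect_true(all(diff(s$phi_l) > 0))
  expect_true(all(diff(s$phi_r) > 0))
})

test_that("horizontal magnitudes are mirror-symmetric for a symmetric scene", {
  pat <- data.frame(x = c(0.2, 0.8), y = c(0.4, 0.4))
  class(pat) <- c("gaze_pattern", "data.frame")
  s <- simulate_pattern(pat, default_scene)
  # target mirrored about x = 0.5: left eye at x mirrors right eye at 1 - x
  expect_equal(abs(s$phi_l[1]), abs(s$phi_r[2]), tolerance = 1e-9)
  expect_equal(abs(s$phi_r[1]), abs(s$phi_l[2]), tolerance = 1e-9)
})
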