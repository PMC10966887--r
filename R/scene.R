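#' Scene configuration for the binocular gaze simulation
#'
#' Describes the 3D layout used to synthesize gaze vectors: two eyeballs
#' (modelled as spheres), one eye camera per eye, a forward-facing scene
#' camera, and a target plane perpendicular to the scene camera's optical
#' axis on which calibration targets are placed.  All positions are in
#' millimetres in a right-handed frame where x is width, y is height and z
#' is depth (the viewing direction).
#'
#' The scene camera is equi-angular (f-theta): the horizontal/vertical view
#' angle of a target is linear in its image fraction, so image coordinate
#' `x` corresponds to view angle `(x - 0.5) * fov_h`.  This keeps angular
#' target spacing uniform for uniformly spaced image fractions, which is the
#' natural parameterisation for wide field-of-view head-mounted scene
#' cameras.
#'
#' @param eye_centre_left,eye_centre_right Eyeball centres (mm).  Defaults
#'   give a 64 mm interpupillary distance centred on the scene camera.
#' @param eyeball_radius Eyeball radius r in mm (default 12).
#' @param eye_cam_left,eye_cam_right Eye-camera positions (mm).  Defaults
#'   place each camera 30 mm below and 20 mm in front of its eye centre.
#' @param scene_cam_origin Scene-camera centre of projection (mm).
#' @param scene_cam_forward Unit viewing direction of the scene camera.
#' @param fov_h_deg,fov_v_deg Horizontal/vertical field of view in degrees,
#'   each in (0, 180).
#' @param target_plane_distance Distance (mm) from the scene camera to the
#'   target plane, measured along `scene_cam_forward`.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(eye_centre_left = c(-32, 0, 0),
                         eye_centre_right = c(32, 0, 0),
                         eyeball_radius = 12,
                         eye_cam_left = eye_centre_left + c(0, -30, 20),
                         eye_cam_right = eye_centre_right + c(0, -30, 20),
                         scene_cam_origin = c(0, 0, 0),
                         scene_cam_forward = c(0, 0, 1),
                         fov_h_deg = 80,
                         fov_v_deg = 60,
                         target_plane_distance = 1000) {
  as_point <- function(p, what) {
    p <- as.numeric(p)
    if (length(p) != 3L || anyNA(p)) stop(sprintf("'%s' must be a numeric 3-vector", what))
    p
  }
  cfg <- list(
    eye_centre_left = as_point(eye_centre_left, "eye_centre_left"),
    eye_centre_right = as_point(eye_centre_right, "eye_centre_right"),
    eyeball_radius = as.numeric(eyeball_radius),
    eye_cam_left = as_point(eye_cam_left, "eye_cam_left"),
    eye_cam_right = as_point(eye_cam_right, "eye_cam_right"),
    scene_cam_origin = as_point(scene_cam_origin, "scene_cam_origin"),
    scene_cam_forward = as_point(scene_cam_forward, "scene_cam_forward"),
    fov_h_deg = as.numeric(fov_h_deg),
    fov_v_deg = as.numeric(fov_v_deg),
    target_plane_distance = as.numeric(target_plane_distance)
  )
  if (!is.finite(cfg$eyeball_radius) || cfg$eyeball_radius <= 0)
    stop("'eyeball_radius' must be > 0")
  if (!is.finite(cfg$target_plane_distance) ||
      cfg$target_plane_distance <= cfg$eyeball_radius)
    stop("'target_plane_distance' must exceed the eyeball radius")
  if (cfg$fov_h_deg <= 0 || cfg$fov_h_deg >= 180)
    stop("'fov_h_deg' must lie in (0, 180)")
  if (cfg$fov_v_deg <= 0 || cfg$fov_v_deg >= 180)
    stop("'fov_v_deg' must lie in (0, 180)")
  nf <- sqrt(sum(cfg$scene_cam_forward^2))
  if (nf < 1e-12) stop("'scene_cam_forward' must be non-zero")
  cfg$scene_cam_forward <- cfg$scene_cam_forward / nf
  # orthonormal camera basis; world up is +y
  up_world <- c(0, 1, 0)
  right <- cross3(up_world, cfg$scene_cam_forward)
  nr <- sqrt(sum(right^2))
  if (nr < 1e-9) stop("'scene_cam_forward' may not be vertical")
  right <- right / nr
  cfg$cam_right <- right
  cfg$cam_up <- cross3(cfg$scene_cam_forward, right)
  class(cfg) <- "scene_config"
  cfg
}

#' @export
print.scene_config <- function(x, ...) {
  cat("Scene configuration (mm, degrees)\n")
  cat(sprintf("  eye centres     L (%s)  R (%s)\n",
              paste(x$eye_centre_left, collapse = ", "),
              paste(x$eye_centre_right, collapse = ", ")))
  cat(sprintf("  eyeball radius  %g\n", x$eyeball_radius))
  cat(sprintf("  eye cameras     L (%s)  R (%s)\n",
              paste(x$eye_cam_left, collapse = ", "),
              paste(x$eye_cam_right, collapse = ", ")))
  cat(sprintf("  scene camera    origin (%s), forward (%s)\n",
              paste(x$scene_cam_origin, collapse = ", "),
              paste(round(x$scene_cam_forward, 6), collapse = ", ")))
  cat(sprintf("  field of view   %g x %g deg; target plane at %g mm\n",
              x$fov_h_deg, x$fov_v_deg, x$target_plane_distance))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Pair of kappa angles (optical vs visual axis offset)
#'
#' @param hori,vert Horizontal and vertical kappa in radians; each must have
#'   magnitude below pi/2.
#' @return A list of class `kappa_pair`.
#' @export
kappa_pair <- function(hori = 0, vert = 0) {
  hori <- as.numeric(hori); vert <- as.numeric(vert)
  if (length(hori) != 1L || length(vert) != 1L || !all(is.finite(c(hori, vert))))
    stop("kappa angles must be finite scalars")
  if (abs(hori) >= pi / 2 || abs(vert) >= pi / 2)
    stop("kappa angles must have magnitude below pi/2 radians")
  structure(list(hori = hori, vert = vert), class = "kappa_pair")
}

# backproject image fractions to the target plane; clip governs whether the
# [0,1] domain of calibration targets is enforced (prediction points may
# leave the image during extrapolation but must stay within the half-space
# in front of the camera, i.e. |view angle| < 90 deg).
image_to_plane <- function(x, y, cfg, clip = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (clip && (any(x < 0 | x > 1, na.rm = TRUE) || any(y < 0 | y > 1, na.rm = TRUE)))
    stop("image fractions must lie in [0, 1]")
  ah <- (x - 0.5) * deg2rad(cfg$fov_h_deg)
  av <- (y - 0.5) * deg2rad(cfg$fov_v_deg)
  ok <- is.finite(ah) & is.finite(av) & abs(ah) < pi / 2 & abs(av) < pi / 2
  d <- cfg$target_plane_distance
  tx <- ifelse(ok, d * tan(ah), NA_real_)
  ty <- ifelse(ok, d * tan(av), NA_real_)
  p <- cbind(
    cfg$scene_cam_origin[1] + d * cfg$scene_cam_forward[1] +
      tx * cfg$cam_right[1] + ty * cfg$cam_up[1],
    cfg$scene_cam_origin[2] + d * cfg$scene_cam_forward[2] +
      tx * cfg$cam_right[2] + ty * cfg$cam_up[2],
    cfg$scene_cam_origin[3] + d * cfg$scene_cam_forward[3] +
      tx * cfg$cam_right[3] + ty * cfg$cam_up[3]
  )
  colnames(p) <- c("x", "y", "z")
  p
}

#' Map image fractions to a 3D point on the target plane
#'
#' Backprojects image coordinates (fractions of the scene image, origin at
#' the bottom-left corner) through the equi-angular scene camera onto the
#' target plane.  The image centre (0.5, 0.5) maps onto the scene camera's
#' optical axis.
#'
#' @param x,y Image fractions in `[0, 1]` (vectors allowed).
#' @param cfg A [scene_config()].
#' @return A numeric matrix with one row per input point and columns x, y, z
#'   (mm).
#' @export
image_to_scene_point <- function(x, y, cfg) {
  image_to_plane(x, y, cfg, clip = TRUE)
}

#' Project a 3D point to image fractions
#'
#' Exact inverse of [image_to_scene_point()] for points on the target plane;
#' defined for any point strictly in front of the scene camera.
#'
#' @param p A numeric 3-vector or an n x 3 matrix of points (mm).
#' @param cfg A [scene_config()].
#' @return A matrix with columns x, y of image fractions.
#' @export
scene_point_to_image <- function(p, cfg) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), nrow = 1)
  v <- sweep(p, 2, cfg$scene_cam_origin)
  z <- as.vector(v %*% cfg$scene_cam_forward)
  if (any(z <= 0)) stop("point lies behind the scene camera")
  rx <- as.vector(v %*% cfg$cam_right)
  ry <- as.vector(v %*% cfg$cam_up)
  cbind(x = 0.5 + atan(rx / z) / deg2rad(cfg$fov_h_deg),
        y = 0.5 + atan(ry / z) / deg2rad(cfg$fov_v_deg))
}

#' Rotation angle compensating a kappa offset
#'
#' The eyeball can only be rotated about its centre, but the kappa angle is
#' defined at the pupil where the visual axis leaves the eye.  By the law of
#' sines in the triangle (eye centre, pupil, target), rotating the sphere by
#' `alpha = kappa - asin((r / b) * sin(pi - kappa))` makes the visual axis
#' (offset by kappa from the optical axis) pass through a target at distance
#' `b` from the eye centre.
#'
#' @param kappa Kappa angle(s) in radians, `|kappa| < pi/2`.
#' @param r Eyeball radius (mm).
#' @param b Distance(s) from eye centre to target (mm); must exceed `r`.
#' @return Rotation angle(s) alpha in radians, odd in `kappa` and satisfying
#'   `|alpha| <= |kappa|`.
#' @export
kappa_to_alpha <- function(kappa, r, b) {
  if (any(!is.finite(kappa)) || any(abs(kappa) >= pi / 2))
    stop("'kappa' must be finite with magnitude below pi/2")
  if (any(b <= r)) stop("target distance 'b' must exceed the eyeball radius 'r'")
  # sin(pi - kappa) = sin(kappa); the direct form is exact at kappa = 0 and odd
  kappa - asin((r / b) * sin(kappa))
}

# Rotate unit direction rows by alpha_hori about the local vertical axis,
# then alpha_vert about the local horizontal axis, both axes taken
# perpendicular to the original direction (so a pure horizontal or pure
# vertical rotation deviates the direction by exactly its alpha).  Positive
# horizontal angles rotate toward +x, positive vertical angles toward +y.
apply_kappa_rotation <- function(dirs, ah, av) {
  dx <- dirs[, 1]; dy <- dirs[, 2]; dz <- dirs[, 3]
  hn <- sqrt(dx^2 + dz^2)
  if (any(hn < 1e-12)) stop("gaze direction may not be vertical")
  # horizontal right axis h = cross(up, d) / |.| = (dz, 0, -dx) / hn
  hx <- dz / hn; hz <- -dx / hn
  # local up axis u = cross(d, h): unit, perpendicular to d
  ux <- dy * hz; uy <- dz * hx - dx * hz; uz <- -dy * hx
  rodrigues <- function(vx, vy, vz, ax, ay, az, ang) {
    ca <- cos(ang); sa <- sin(ang)
    dot <- ax * vx + ay * vy + az * vz
    cx <- ay * vz - az * vy
    cy <- az * vx - ax * vz
    cz <- ax * vy - ay * vx
    cbind(vx * ca + cx * sa + ax * dot * (1 - ca),
          vy * ca + cy * sa + ay * dot * (1 - ca),
          vz * ca + cz * sa + az * dot * (1 - ca))
  }
  d1 <- rodrigues(dx, dy, dz, ux, uy, uz, ah)
  # vertical rotation about -h so positive angles pitch the axis upward
  rodrigues(d1[, 1], d1[, 2], d1[, 3], -hx, 0, -hz, av)
}

#' Optical-axis direction for an eye fixating a target
#'
#' With zero kappa the optical axis points straight at the target.  A
#' non-zero kappa pair is compensated by rotating the target direction by
#' `alpha_hori` about the vertical axis, then `alpha_vert` about the
#' horizontal axis, where each alpha is obtained from [kappa_to_alpha()]
#' with `b` the eye-to-target distance (recomputed per target).  Positive
#' horizontal angles rotate toward +x, positive vertical angles toward +y.
#'
#' @param eye_centre Eyeball centre (mm).
#' @param target Target point (mm); must differ from the eye centre.
#' @param kappa A [kappa_pair()].
#' @param r Eyeball radius (mm).
#' @return Unit 3-vector of the optical axis.
#' @export
optical_axis_for_target <- function(eye_centre, target, kappa = kappa_pair(), r = 12) {
  d <- as.numeric(target) - as.numeric(eye_centre)
  b <- sqrt(sum(d^2))
  if (b < 1e-9) stop("target must differ from the eye centre")
  dir <- matrix(d / b, nrow = 1)
  if (kappa$hori != 0 || kappa$vert != 0) {
    ah <- kappa_to_alpha(kappa$hori, r, b)
    av <- kappa_to_alpha(kappa$vert, r, b)
    dir <- apply_kappa_rotation(dir, ah, av)
  }
  as.numeric(dir)
}

signed_angle_2d <- function(ax, ay, bx, by) {
  # signed angle of a relative to b: positive when a lies counter-clockwise
  # of b in the (first, second) component plane
  atan2(ax * by - ay * bx, ax * bx + ay * by)
}

#' Gaze vector (phi, theta) of an optical axis
#'
#' The gaze vector is the pair of signed horizontal and vertical angles
#' between the optical axis and the line from the eyeball centre to the eye
#' camera.  The horizontal angle phi is measured in the x-z plane (the
#' y-components dropped) and the vertical angle theta in the y-z plane (the
#' x-components dropped); the magnitudes equal the arccos of the normalised
#' dot products of the projected vectors.  Signs come from the 2D cross
#' product so that leftward (-x) and downward (-y) deviations of the axis
#' relative to the eye-to-camera line are negative.
#'
#' @param eye_centre,eye_cam Eyeball centre and eye-camera position (mm).
#' @param optical_axis Direction vector of the optical axis.
#' @return Named numeric vector `c(phi =, theta =)` in radians.
#' @export
gaze_vector <- function(eye_centre, eye_cam, optical_axis) {
  ce <- as.numeric(eye_cam) - as.numeric(eye_centre)
  o <- as.numeric(optical_axis)
  if (sqrt(ce[1]^2 + ce[3]^2) < 1e-12 || sqrt(o[1]^2 + o[3]^2) < 1e-12)
    stop("degenerate horizontal projection: zero-length 2D vector")
  if (sqrt(ce[2]^2 + ce[3]^2) < 1e-12 || sqrt(o[2]^2 + o[3]^2) < 1e-12)
    stop("degenerate vertical projection: zero-length 2D vector")
  c(phi = signed_angle_2d(o[1], o[3], ce[1], ce[3]),
    theta = signed_angle_2d(o[2], o[3], ce[2], ce[3]))
}

# vectorised core used by simulate_pattern: targets is n x 3
eye_gaze_angles <- function(targets, eye_centre, eye_cam, kappa, r) {
  dx <- targets[, 1] - eye_centre[1]
  dy <- targets[, 2] - eye_centre[2]
  dz <- targets[, 3] - eye_centre[3]
  b <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(b <= r)) stop("eye-to-target distance must exceed the eyeball radius")
  x <- dx / b; y <- dy / b; z <- dz / b
  if (kappa$hori != 0 || kappa$vert != 0) {
    ah <- kappa_to_alpha(kappa$hori, r, b)
    av <- kappa_to_alpha(kappa$vert, r, b)
    rot <- apply_kappa_rotation(cbind(x, y, z), ah, av)
    x <- rot[, 1]; y <- rot[, 2]; z <- rot[, 3]
  }
  ce <- eye_cam - eye_centre
  cbind(phi = signed_angle_2d(x, z, ce[1], ce[3]),
        theta = signed_angle_2d(y, z, ce[2], ce[3]))
}

#' Simulate noise-free binocular gaze vectors for a target pattern
#'
#' For every target of a calibration pattern the two eyeballs are oriented
#' so that their (kappa-compensated) optical axes fixate the backprojected
#' 3D target, and the resulting left/right gaze vectors are recorded.
#'
#' @param pattern A pattern (see [make_grid()] and friends): a data frame
#'   with columns `x`, `y` of image fractions.
#' @param cfg A [scene_config()].
#' @param kappa_left,kappa_right Per-eye [kappa_pair()]s (radians).
#' @return A data frame with one row per pattern point and columns `frame`,
#'   `target_x`, `target_y`, `phi_l`, `theta_l`, `phi_r`, `theta_r` (angles
#'   in radians).
#' @export
simulate_pattern <- function(pattern, cfg = scene_config(),
                             kappa_left = kappa_pair(),
                             kappa_right = kappa_pair()) {
  if (NROW(pattern) == 0L) stop("pattern must be non-empty")
  targets <- image_to_scene_point(pattern$x, pattern$y, cfg)
  r <- cfg$eyeball_radius
  gl <- eye_gaze_angles(targets, cfg$eye_centre_left, cfg$eye_cam_left, kappa_left, r)
  gr <- eye_gaze_angles(targets, cfg$eye_centre_right, cfg$eye_cam_right, kappa_right, r)
  data.frame(frame = seq_len(NROW(pattern)),
             target_x = pattern$x, target_y = pattern$y,
             phi_l = gl[, "phi"], theta_l = gl[, "theta"],
             phi_r = gr[, "phi"], theta_r = gr[, "theta"])
}
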