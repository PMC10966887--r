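#' Angular error between estimated and true gaze points
#'
#' Backprojects both image points onto the target plane and measures the
#' angle between the scene-camera rays through them.  Estimates may lie
#' outside `[0, 1]` (extrapolation); an estimate whose view angle reaches
#' 90 degrees or is non-finite yields `NA` (callers count these as
#' excluded).
#'
#' @param est,true Image coordinates: two-column matrices/data frames or
#'   length-2 vectors.
#' @param cfg A [scene_config()].
#' @return Vector of angles in degrees (`>= 0`, symmetric in the
#'   arguments), `NA` where the estimate is invalid.
#' @export
angular_error <- function(est, true, cfg) {
  as_xy <- function(p) {
    if (is.null(dim(p))) matrix(as.numeric(p), ncol = 2) else as.matrix(p)[, 1:2, drop = FALSE]
  }
  est <- as_xy(est); true <- as_xy(true)
  if (nrow(est) != nrow(true)) stop("'est' and 'true' must have equal length")
  pe <- image_to_plane(est[, 1], est[, 2], cfg, clip = FALSE)
  pt <- image_to_plane(true[, 1], true[, 2], cfg, clip = FALSE)
  ve <- sweep(pe, 2, cfg$scene_cam_origin)
  vt <- sweep(pt, 2, cfg$scene_cam_origin)
  num <- rowSums(ve * vt)
  den <- sqrt(rowSums(ve^2) * rowSums(vt^2))
  rad2deg(acos(pmin(pmax(num / den, -1), 1)))
}

#' Mean angular error of a calibration on a test set
#'
#' Predicts the gaze point for every test sample and averages the angular
#' error against the true targets.  Non-finite or out-of-view predictions
#' are excluded; their count is attached as attribute `n_excluded` (and as
#' attribute `unreliable = TRUE` when more than 5% of the test points were
#' excluded).
#'
#' @param model A fitted [gaze_calib()] model.
#' @param test Binocular test samples (see [simulate_pattern()]).
#' @param cfg A [scene_config()].
#' @return Mean angular error in degrees with attribute `n_excluded`.
#' @export
mean_angular_error <- function(model, test, cfg) {
  if (NROW(test) == 0L) stop("'test' must be non-empty")
  pred <- predict(model, test)
  err <- angular_error(pred, cbind(test$target_x, test$target_y), cfg)
  bad <- !is.finite(err)
  if (all(bad)) stop("all test predictions were excluded as invalid")
  out <- mean(err[!bad])
  attr(out, "n_excluded") <- sum(bad)
  if (sum(bad) > 0.05 * length(err)) attr(out, "unreliable") <- TRUE
  out
}

#' Split test samples by the calibration range
#'
#' The calibration range is the axis-aligned bounding box of the
#' calibration pattern's targets; test samples whose true target lies
#' within the box (inclusive) are "inside" (interpolation), the rest
#' "outside" (extrapolation).  The two parts partition the input.
#'
#' @param test Binocular test samples.
#' @param calib_pattern The calibration `gaze_pattern` (or any data frame
#'   with `x`, `y` columns).
#' @return A list with elements `inside` and `outside` (data frames).
#' @export
split_by_range <- function(test, calib_pattern) {
  bx <- range(calib_pattern$x)
  by <- range(calib_pattern$y)
  inside <- test$target_x >= bx[1] & test$target_x <= bx[2] &
    test$target_y >= by[1] & test$target_y <= by[2]
  list(inside = test[inside, , drop = FALSE],
       outside = test[!inside, , drop = FALSE])
}

#' Mean squared error in image space
#'
#' Mean squared Euclidean distance (in squared image fractions) between
#' predicted and true gaze points.
#'
#' @param model A fitted [gaze_calib()] model.
#' @param test Binocular test samples.
#' @return Scalar MSE.
#' @export
image_mse <- function(model, test) {
  if (NROW(test) == 0L) stop("'test' must be non-empty")
  pred <- predict(model, test)
  d2 <- (pred[, 1] - test$target_x)^2 + (pred[, 2] - test$target_y)^2
  keep <- is.finite(d2)
  if (!any(keep)) stop("all test predictions were non-finite")
  mean(d2[keep])
}
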