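#' @title Calibration target patterns
#' @description Generators for calibration and test target patterns.  A
#'   pattern is an ordered data frame of image-fraction coordinates `x`,
#'   `y` in `[0, 1]^2` (origin bottom-left) with a `name` attribute, of
#'   class `gaze_pattern`.  Discrete n-point patterns emit one sample per
#'   target; pursuit-style patterns (snake, spiral) emit several hundred
#'   samples, emulating 30 Hz tracking of a moving marker over 10-13 s.
#' @name patterns
NULL

new_pattern <- function(x, y, name) {
  if (length(x) == 0L) stop("pattern must be non-empty")
  if (any(x < -1e-12 | x > 1 + 1e-12) || any(y < -1e-12 | y > 1 + 1e-12))
    stop("pattern points must lie in [0, 1]^2")
  out <- data.frame(x = pmin(pmax(x, 0), 1), y = pmin(pmax(y, 0), 1))
  attr(out, "name") <- name
  class(out) <- c("gaze_pattern", "data.frame")
  out
}

#' @export
print.gaze_pattern <- function(x, ...) {
  cat(sprintf("Calibration pattern '%s': %d targets, bbox [%.3f, %.3f] x [%.3f, %.3f]\n",
              attr(x, "name") %||% "?", nrow(x),
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' n-point calibration pattern
#'
#' The 5-point pattern places one target in each corner (inset by `margin`)
#' plus one in the centre; the 9-point pattern is a 3 x 3 grid spanning
#' `[margin, 1 - margin]^2`, row-major from the bottom-left.  Targets sit
#' close to the image edges so the calibration covers the whole field.
#'
#' @param n Number of targets, 5 or 9.
#' @param margin Inset from the image border, a fraction in `[0, 0.2]`.
#' @param repeats Samples emitted per target (default 1).
#' @return A `gaze_pattern`.
#' @export
make_npoint <- function(n, margin = 0.02, repeats = 1L) {
  if (margin < 0 || margin > 0.2) stop("'margin' must lie in [0, 0.2]")
  m <- margin
  if (n == 5L) {
    x <- c(m, 1 - m, m, 1 - m, 0.5)
    y <- c(m, m, 1 - m, 1 - m, 0.5)
  } else if (n == 9L) {
    g <- seq(m, 1 - m, length.out = 3)
    gg <- expand.grid(x = g, y = g)
    x <- gg$x; y <- gg$y
  } else {
    stop("'n' must be 5 or 9")
  }
  new_pattern(rep(x, each = repeats), rep(y, each = repeats),
              sprintf("%dp", n))
}

#' Snake (boustrophedon) smooth-pursuit pattern
#'
#' A back-and-forth raster path emulating a marker swept across the field:
#' `rows` horizontal sweeps with alternating direction, each sampled at
#' `cols * samples_per_leg` evenly spaced points, rows evenly spaced over
#' the bounding box.  Total point count is `rows * cols * samples_per_leg`.
#'
#' @param rows,cols Sweep rows and legs per sweep (each >= 1; `rows >= 2`
#'   for a non-degenerate vertical extent).
#' @param bbox Bounding box `c(x0, y0, x1, y1)` within `[0, 1]^2`.
#' @param samples_per_leg Samples per leg.
#' @param name Pattern label.
#' @return A `gaze_pattern`.
#' @export
make_snake <- function(rows = 10, cols = 8, bbox = c(0.02, 0.02, 0.98, 0.98),
                       samples_per_leg = 5, name = "snake") {
  check_bbox(bbox)
  if (rows < 1 || cols < 1 || samples_per_leg < 1)
    stop("'rows', 'cols' and 'samples_per_leg' must be >= 1")
  per_row <- cols * samples_per_leg
  ys <- if (rows == 1) (bbox[2] + bbox[4]) / 2 else seq(bbox[2], bbox[4], length.out = rows)
  xs_fwd <- seq(bbox[1], bbox[3], length.out = per_row)
  x <- numeric(0); y <- numeric(0)
  for (i in seq_len(rows)) {
    xs <- if (i %% 2 == 1) xs_fwd else rev(xs_fwd)
    x <- c(x, xs)
    y <- c(y, rep(ys[i], per_row))
  }
  new_pattern(x, y, name)
}

#' Archimedean spiral smooth-pursuit pattern
#'
#' Emulates the instruction to move the calibration marker in a spiral from
#' the centre of the field outwards: an Archimedean spiral starting at the
#' bounding-box centre, growing linearly to the inscribed ellipse of the
#' box, sampled uniformly in the spiral parameter (so sample density is
#' highest near the centre, as in real smooth-pursuit recordings).
#'
#' @param turns Number of full turns (>= 1).
#' @param bbox Bounding box `c(x0, y0, x1, y1)` within `[0, 1]^2`.
#' @param n_samples Number of samples (>= 8 * turns).
#' @param name Pattern label.
#' @return A `gaze_pattern`; the first point is the bbox centre.
#' @export
make_spiral <- function(turns = 4, bbox = c(0.05, 0.05, 0.95, 0.95),
                        n_samples = 400, name = "spiral") {
  check_bbox(bbox)
  if (turns < 1) stop("'turns' must be >= 1")
  if (n_samples < 8 * turns) stop("'n_samples' must be at least 8 * turns")
  t <- seq(0, 1, length.out = n_samples)
  cx <- (bbox[1] + bbox[3]) / 2
  cy <- (bbox[2] + bbox[4]) / 2
  rx <- (bbox[3] - bbox[1]) / 2
  ry <- (bbox[4] - bbox[2]) / 2
  ang <- 2 * pi * turns * t
  new_pattern(cx + rx * t * cos(ang), cy + ry * t * sin(ang), name)
}

#' Uniform full-field grid pattern
#'
#' `rows * cols` targets evenly spaced over the whole image `[0, 1]^2`,
#' row-major from the bottom-left.  The 20 x 20 version is the standard
#' full-field test pattern for evaluating calibrations.
#'
#' @param rows,cols Grid dimensions (each >= 2).
#' @return A `gaze_pattern`.
#' @export
make_grid <- function(rows = 20, cols = 20) {
  if (rows < 2 || cols < 2) stop("'rows' and 'cols' must be >= 2")
  gg <- expand.grid(x = seq(0, 1, length.out = cols),
                    y = seq(0, 1, length.out = rows))
  new_pattern(gg$x, gg$y, sprintf("grid%dx%d", rows, cols))
}

check_bbox <- function(bbox) {
  if (length(bbox) != 4L || any(!is.finite(bbox)))
    stop("'bbox' must be c(x0, y0, x1, y1)")
  if (bbox[1] >= bbox[3] || bbox[2] >= bbox[4])
    stop("'bbox' is empty")
  if (any(bbox < 0) || any(bbox > 1)) stop("'bbox' must lie within [0, 1]^2")
  invisible(bbox)
}

#' Standard pattern roster
#'
#' Convenience constructors for the study patterns: 5-point, 9-point,
#' centre snake (central 40% of the field), full-field snake, large and
#' small subject-like spirals, and the 20 x 20 evaluation grid.
#' `pattern_by_name()` resolves the names used in configuration files:
#' `"5p"`, `"9p"`, `"centre"`, `"full"`, `"subject_huge"`,
#' `"subject_small"`, `"grid20"`.
#'
#' @param name Pattern name (for `pattern_by_name`).
#' @return A `gaze_pattern`.
#' @export
pattern_by_name <- function(name) {
  switch(name,
         "5p" = pattern_5p(),
         "9p" = pattern_9p(),
         "centre" = pattern_centre(),
         "full" = pattern_full(),
         "subject_huge" = pattern_subject_huge(),
         "subject_small" = pattern_subject_small(),
         "grid20" = pattern_grid20(),
         stop(sprintf("unknown pattern name '%s'", name)))
}

#' @rdname pattern_by_name
#' @export
pattern_5p <- function() make_npoint(5L)

#' @rdname pattern_by_name
#' @export
pattern_9p <- function() make_npoint(9L)

#' @rdname pattern_by_name
#' @export
pattern_centre <- function()
  make_snake(bbox = c(0.3, 0.3, 0.7, 0.7), name = "centre")

#' @rdname pattern_by_name
#' @export
pattern_full <- function()
  make_snake(bbox = c(0.02, 0.02, 0.98, 0.98), name = "full")

#' @rdname pattern_by_name
#' @export
pattern_subject_huge <- function()
  make_spiral(bbox = c(0.05, 0.05, 0.95, 0.95), name = "subject_huge")

#' @rdname pattern_by_name
#' @export
pattern_subject_small <- function()
  make_spiral(bbox = c(0.3, 0.3, 0.7, 0.7), name = "subject_small")

#' @rdname pattern_by_name
#' @export
pattern_grid20 <- function() make_grid(20, 20)

#' Read or write a pattern as two-column CSV
#'
#' The on-disk format is a CSV with header `x,y`; the pattern name is taken
#' from the file name (without extension).
#'
#' @param pattern A `gaze_pattern`.
#' @param path File path.
#' @return `read_pattern_csv` returns a `gaze_pattern`;
#'   `write_pattern_csv` returns `path` invisibly.
#' @export
write_pattern_csv <- function(pattern, path) {
  utils::write.csv(data.frame(x = pattern$x, y = pattern$y), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @export
read_pattern_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("pattern CSV must have columns 'x' and 'y'")
  new_pattern(df$x, df$y, sub("\\.[^.]*$", "", basename(path)))
}
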