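#' Measurement-noise configuration
#'
#' Parameters of the three stochastic corruption processes applied to
#' simulated gaze-vector sequences, in order: gaze-direction-dependent
#' systematic error, Gaussian precision noise, and burst-like false pupil
#' detections.
#'
#' @param p_error Per-frame probability of a systematic-error perturbation.
#' @param r_error Maximum-error scale of the systematic perturbation
#'   (dimensionless; the offset magnitude is bounded by
#'   `2 * r_error / pi` radians at gaze straight toward the eye camera).
#' @param sigma_prec Standard deviation (radians) of the white precision
#'   noise added to every component of every frame.
#' @param p_fd Per-frame, per-eye probability that a false-detection burst
#'   starts.
#' @param burst_min,burst_max Burst length range (frames); a burst corrupts
#'   the triggering frame and the following `n - 1` frames with `n` drawn
#'   uniformly from `burst_min:burst_max`.
#' @param freeze_burst If `TRUE`, one offset is drawn per burst and held
#'   over its frames; the default redraws the offset every corrupted frame.
#' @param seed Optional RNG seed making [apply_noise()] reproducible.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(p_error = 0.1, r_error = 0.5, sigma_prec = 0.005,
                         p_fd = 0.005, burst_min = 1L, burst_max = 9L,
                         freeze_burst = FALSE, seed = NULL) {
  stopifnot(length(p_error) == 1L, length(r_error) == 1L,
            length(sigma_prec) == 1L, length(p_fd) == 1L)
  if (!is.finite(p_error) || p_error < 0 || p_error > 1)
    stop("'p_error' must be a probability in [0, 1]")
  if (!is.finite(p_fd) || p_fd < 0 || p_fd > 1)
    stop("'p_fd' must be a probability in [0, 1]")
  if (!is.finite(sigma_prec) || sigma_prec < 0)
    stop("'sigma_prec' must be >= 0")
  if (!is.finite(r_error) || r_error < 0)
    stop("'r_error' must be >= 0")
  burst_min <- as.integer(burst_min); burst_max <- as.integer(burst_max)
  if (burst_min < 1L || burst_min > burst_max)
    stop("burst lengths must satisfy 1 <= burst_min <= burst_max")
  structure(list(p_error = p_error, r_error = r_error,
                 sigma_prec = sigma_prec, p_fd = p_fd,
                 burst_min = burst_min, burst_max = burst_max,
                 freeze_burst = isTRUE(freeze_burst),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_config")
}

#' @export
print.noise_config <- function(x, ...) {
  cat(sprintf(paste0("Noise configuration: p_error = %g, r_error = %g, ",
                     "sigma_prec = %g rad, p_fd = %g, bursts %d-%d frames%s\n"),
              x$p_error, x$r_error, x$sigma_prec, x$p_fd,
              x$burst_min, x$burst_max,
              if (x$freeze_burst) " (frozen offsets)" else ""))
  invisible(x)
}

check_gv_matrix <- function(gv) {
  gv <- as.matrix(gv)
  if (ncol(gv) != 2L) stop("a gaze-vector sequence must have columns phi, theta")
  storage.mode(gv) <- "double"
  colnames(gv) <- c("phi", "theta")
  gv
}

#' Apply gaze-direction-dependent systematic error
#'
#' Trackers struggle most when the gaze is directed into the eye camera
#' (the pupil outline becomes near-circular), so the perturbation is
#' largest for small gaze angles.  Each frame is perturbed independently
#' with probability `p_error`; a perturbed frame's components each receive
#' a fresh offset `w * 4 * (u - 0.5) * r_error / pi` with `u ~ U(0, 1)` and
#' weight `w = (2 - |phi|/phi_max - |theta|/theta_max) / 2`, which is 1 at
#' zero gaze angle and 0 at the sequence extremes.
#'
#' @param gv A two-column matrix (phi, theta) in radians, one eye.
#' @param cfg A [noise_config()].
#' @param phi_max,theta_max Largest horizontal/vertical angle magnitudes
#'   used in the weight; default the maxima of the sequence itself.
#' @return The perturbed matrix.
#' @export
apply_systematic <- function(gv, cfg, phi_max = NULL, theta_max = NULL) {
  gv <- check_gv_matrix(gv)
  if (cfg$p_error == 0 || cfg$r_error == 0) return(gv)
  if (is.null(phi_max)) phi_max <- max(abs(gv[, "phi"]))
  if (is.null(theta_max)) theta_max <- max(abs(gv[, "theta"]))
  if (phi_max <= 0 || theta_max <= 0)
    stop("'phi_max' and 'theta_max' must be positive")
  n <- nrow(gv)
  hit <- stats::runif(n) < cfg$p_error
  w <- (2 - abs(gv[, "phi"]) / phi_max - abs(gv[, "theta"]) / theta_max) / 2
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  scale <- 4 * cfg$r_error / pi
  gv[hit, "phi"] <- gv[hit, "phi"] + w[hit] * (u1[hit] - 0.5) * scale
  gv[hit, "theta"] <- gv[hit, "theta"] + w[hit] * (u2[hit] - 0.5) * scale
  gv
}

#' Apply Gaussian precision noise
#'
#' Adds independent white noise `N(0, sigma_prec)` (radians) to each
#' component of each frame, modelling the device-specific frame-to-frame
#' scatter of the gaze signal.
#'
#' @inheritParams apply_systematic
#' @return The perturbed matrix.
#' @export
apply_precision <- function(gv, cfg) {
  gv <- check_gv_matrix(gv)
  if (cfg$sigma_prec == 0) return(gv)
  n <- nrow(gv)
  gv[, "phi"] <- gv[, "phi"] + stats::rnorm(n, 0, cfg$sigma_prec)
  gv[, "theta"] <- gv[, "theta"] + stats::rnorm(n, 0, cfg$sigma_prec)
  gv
}

#' Apply false-detection bursts
#'
#' Models transient gross pupil mislocalisation: with probability `p_fd` a
#' frame starts a burst corrupting that frame and the next `n - 1` frames,
#' `n` uniform on `burst_min:burst_max` (bursts truncate at the sequence
#' end and may overlap).  Every corrupted frame's components receive
#' offsets `(u - 0.5) * pi / 2`, bounded by +/- pi/4 radians; with
#' `freeze_burst` the offset is drawn once per burst.
#'
#' @inheritParams apply_systematic
#' @return The perturbed matrix.
#' @export
apply_false_detections <- function(gv, cfg) {
  gv <- check_gv_matrix(gv)
  if (cfg$p_fd == 0) return(gv)
  n <- nrow(gv)
  starts <- which(stats::runif(n) < cfg$p_fd)
  if (length(starts) == 0L) return(gv)
  lens_pool <- seq(cfg$burst_min, cfg$burst_max)
  lens <- lens_pool[sample.int(length(lens_pool), length(starts), replace = TRUE)]
  if (cfg$freeze_burst) {
    off <- matrix(NA_real_, n, 2)
    for (k in seq_along(starts)) {
      idx <- starts[k]:min(starts[k] + lens[k] - 1L, n)
      off[idx, 1] <- (stats::runif(1) - 0.5) * pi / 2
      off[idx, 2] <- (stats::runif(1) - 0.5) * pi / 2
    }
    hit <- !is.na(off[, 1])
    gv[hit, ] <- gv[hit, ] + off[hit, , drop = FALSE]
  } else {
    hit <- logical(n)
    for (k in seq_along(starts))
      hit[starts[k]:min(starts[k] + lens[k] - 1L, n)] <- TRUE
    m <- sum(hit)
    gv[hit, "phi"] <- gv[hit, "phi"] + (stats::runif(m) - 0.5) * pi / 2
    gv[hit, "theta"] <- gv[hit, "theta"] + (stats::runif(m) - 0.5) * pi / 2
  }
  gv
}

#' Apply all three noise processes to a binocular sample sequence
#'
#' Chains systematic error, precision noise and false detections, in that
#' order, independently per eye (left eye first).  The weight extremes
#' `phi_max`/`theta_max` of the systematic error are computed per eye from
#' the input sequence.  Deterministic given `cfg$seed`.
#'
#' @param samples A binocular sample data frame as returned by
#'   [simulate_pattern()].
#' @param cfg A [noise_config()].
#' @return The data frame with perturbed `phi_l`, `theta_l`, `phi_r`,
#'   `theta_r`; target coordinates are unchanged.
#' @export
apply_noise <- function(samples, cfg) {
  need <- c("phi_l", "theta_l", "phi_r", "theta_r")
  if (!all(need %in% names(samples)))
    stop("'samples' must contain columns ", paste(need, collapse = ", "))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  for (eye in c("l", "r")) {
    cols <- paste0(c("phi_", "theta_"), eye)
    gv <- as.matrix(samples[, cols])
    gv <- apply_systematic(gv, cfg)
    gv <- apply_precision(gv, cfg)
    gv <- apply_false_detections(gv, cfg)
    samples[[cols[1]]] <- gv[, "phi"]
    samples[[cols[2]]] <- gv[, "theta"]
  }
  samples
}
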