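#' Configuration of the repeated-simulation experiment
#'
#' Describes one full benchmark run: per repetition a fresh pair of
#' person-specific kappa angles is drawn (horizontal ~ N(3.9, 2.2) deg,
#' vertical ~ N(0.2, 1.7) deg, population values for the optical/visual
#' axis offset), each calibration pattern is simulated and
#' noise-corrupted, every method configuration is fitted, and its mean
#' angular error on the full-field test grid is recorded.
#'
#' @param patterns Named list of calibration `gaze_pattern`s, or a
#'   character vector of [pattern_by_name()] names.
#' @param methods A specification data frame (rows as in [method_grid()])
#'   or a character vector of family names whose full grids are used.
#' @param noise A [noise_config()] (its `seed` field is ignored here; the
#'   experiment derives per-repetition noise seeds from `seed`).
#' @param scene A [scene_config()].
#' @param n_reps Number of repetitions (kappa draws).
#' @param kappa_hori_mean,kappa_hori_sd,kappa_vert_mean,kappa_vert_sd
#'   Kappa population parameters in degrees.
#' @param kappa_mode `"independent"` (default): per-eye independent draws;
#'   `"shared"`: both eyes get the same draw; `"mirrored"`: the left eye's
#'   horizontal kappa is sign-flipped relative to the right eye's.
#' @param noisy_test Whether the test-grid gaze vectors are also
#'   noise-corrupted (default `TRUE`, matching a real recording where the
#'   validation sequence passes through the same tracker).
#' @param test_pattern Test pattern (default the 20 x 20 full-field grid).
#' @param seed Top-level seed; all randomness (kappa draws, noise,
#'   stochastic fits) is derived from it, so results are fully
#'   reproducible and adding a method does not change the simulated data.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(patterns = c("full", "centre", "subject_small"),
                              methods = c("poly", "ridge"),
                              noise = noise_config(),
                              scene = scene_config(),
                              n_reps = 100L,
                              kappa_hori_mean = 3.9, kappa_hori_sd = 2.2,
                              kappa_vert_mean = 0.2, kappa_vert_sd = 1.7,
                              kappa_mode = c("independent", "shared", "mirrored"),
                              noisy_test = TRUE,
                              test_pattern = pattern_grid20(),
                              seed = 1L) {
  kappa_mode <- match.arg(kappa_mode)
  if (is.character(patterns)) {
    patterns <- stats::setNames(lapply(patterns, pattern_by_name), patterns)
  }
  if (is.null(names(patterns)) || any(names(patterns) == ""))
    stop("'patterns' must be named")
  if (is.character(methods)) {
    methods <- do.call(rbind, lapply(methods, method_grid))
  }
  methods <- spec_frame(methods)
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("'n_reps' must be >= 1")
  if (any(c(kappa_hori_sd, kappa_vert_sd) < 0))
    stop("kappa standard deviations must be >= 0")
  structure(list(patterns = patterns, methods = methods, noise = noise,
                 scene = scene, n_reps = n_reps,
                 kappa_hori_mean = kappa_hori_mean, kappa_hori_sd = kappa_hori_sd,
                 kappa_vert_mean = kappa_vert_mean, kappa_vert_sd = kappa_vert_sd,
                 kappa_mode = kappa_mode, noisy_test = isTRUE(noisy_test),
                 test_pattern = test_pattern, seed = as.integer(seed)),
            class = "experiment_config")
}

draw_kappas <- function(cfg) {
  draw <- function() kappa_pair(
    deg2rad(stats::rnorm(1, cfg$kappa_hori_mean, cfg$kappa_hori_sd)),
    deg2rad(stats::rnorm(1, cfg$kappa_vert_mean, cfg$kappa_vert_sd)))
  right <- draw()
  left <- switch(cfg$kappa_mode,
                 independent = draw(),
                 shared = right,
                 mirrored = kappa_pair(-right$hori, right$vert))
  list(left = left, right = right)
}

#' Run the repeated-simulation benchmark experiment
#'
#' Executes the full protocol of [experiment_config()]: for each
#' repetition and calibration pattern, simulate and corrupt the
#' calibration and test sequences, fit every method configuration on the
#' calibration samples, and record its mean angular error on the test
#' grid, the inside/outside-calibration-range decomposition (by the
#' calibration pattern's bounding box) and the image-space MSE.
#' Individual fit failures are recorded in the `error` column, not fatal.
#'
#' @param cfg An [experiment_config()].
#' @param progress Print a line per repetition.
#' @return A data frame of class `gaze_experiment` with one row per
#'   (repetition, pattern, method configuration): columns `rep`,
#'   `pattern`, the method-specification fields, `mean_deg`, `inside_deg`, `outside_deg`,
#'   `mse`, `n_excluded`, `error`.  Summarise with
#'   [summarise_experiment()].
#' @export
run_experiment <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  pats <- cfg$patterns
  n_pat <- length(pats)
  set.seed(cfg$seed)
  # deterministic sub-seeds: per rep one kappa seed, per (rep, pattern) a
  # calibration-noise and a test-noise seed, per rep one fitting seed
  pool <- matrix(sample.int(.Machine$integer.max - 1L,
                            cfg$n_reps * (2L + 2L * n_pat)),
                 nrow = cfg$n_reps)
  rows <- vector("list", cfg$n_reps * n_pat)
  k <- 0L
  for (rep_i in seq_len(cfg$n_reps)) {
    set.seed(pool[rep_i, 1L])
    kap <- draw_kappas(cfg)
    fit_seed <- pool[rep_i, 2L]
    test_clean <- simulate_pattern(cfg$test_pattern, cfg$scene, kap$left, kap$right)
    for (pat_i in seq_len(n_pat)) {
      calib <- simulate_pattern(pats[[pat_i]], cfg$scene, kap$left, kap$right)
      ncfg <- cfg$noise
      ncfg$seed <- pool[rep_i, 2L + pat_i]
      calib <- apply_noise(calib, ncfg)
      test <- test_clean
      if (cfg$noisy_test) {
        ncfg$seed <- pool[rep_i, 2L + n_pat + pat_i]
        test <- apply_noise(test, ncfg)
      }
      parts <- split_by_range(test, pats[[pat_i]])
      res <- cfg$methods
      res$mean_deg <- NA_real_; res$inside_deg <- NA_real_
      res$outside_deg <- NA_real_; res$mse <- NA_real_
      res$n_excluded <- NA_integer_; res$error <- NA_character_
      for (m in seq_len(nrow(cfg$methods))) {
        out <- tryCatch({
          fit <- fit_spec(cfg$methods[m, ], calib, seed = fit_seed)
          mae <- mean_angular_error(fit, test, cfg$scene)
          ins <- if (nrow(parts$inside))
            as.numeric(mean_angular_error(fit, parts$inside, cfg$scene)) else NA_real_
          outs <- if (nrow(parts$outside))
            as.numeric(mean_angular_error(fit, parts$outside, cfg$scene)) else NA_real_
          list(mean = as.numeric(mae), ins = ins, outs = outs,
               mse = image_mse(fit, test),
               nexcl = attr(mae, "n_excluded"))
        }, error = function(e) e)
        if (inherits(out, "error")) {
          res$error[m] <- conditionMessage(out)
        } else {
          res$mean_deg[m] <- out$mean
          res$inside_deg[m] <- out$ins
          res$outside_deg[m] <- out$outs
          res$mse[m] <- out$mse
          res$n_excluded[m] <- out$nexcl
        }
      }
      k <- k + 1L
      rows[[k]] <- cbind(data.frame(rep = rep_i, pattern = names(pats)[pat_i],
                                    stringsAsFactors = FALSE), res)
    }
    if (progress)
      message(sprintf("rep %d/%d done", rep_i, cfg$n_reps))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gaze_experiment", "data.frame")
  attr(out, "config_seed") <- cfg$seed
  out
}

#' Aggregate experiment results over repetitions
#'
#' Per (pattern, method configuration): grand mean and standard deviation
#' of the per-repetition mean angular error, mean inside/outside errors,
#' mean MSE, total excluded predictions and the number of repetitions
#' that fitted successfully.
#'
#' @param res A result frame from [run_experiment()].
#' @return A data frame, one row per pattern x configuration.
#' @export
summarise_experiment <- function(res) {
  key <- paste(res$pattern, res$family, res$degree, res$alpha,
               res$kernel, res$cost, res$epsilon, sep = "\r")
  pieces <- split(seq_len(nrow(res)), key)
  out <- do.call(rbind, lapply(pieces, function(idx) {
    r <- res[idx, , drop = FALSE]
    ok <- is.finite(r$mean_deg)
    data.frame(pattern = r$pattern[1], family = r$family[1],
               degree = r$degree[1], alpha = r$alpha[1],
               kernel = r$kernel[1], cost = r$cost[1], epsilon = r$epsilon[1],
               mean_deg = mean(r$mean_deg[ok]),
               sd_deg = stats::sd(r$mean_deg[ok]),
               inside_deg = mean(r$inside_deg[ok]),
               outside_deg = mean(r$outside_deg[ok]),
               mse = mean(r$mse[ok]),
               n_excluded = sum(r$n_excluded[ok]),
               n_reps = sum(ok),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$pattern, out$family, out$degree), ]
}

#' Best configuration per pattern and family
#'
#' Picks, for each calibration pattern and method family, the
#' configuration with the smallest aggregated value of `by` (an oracle
#' selection on the evaluation results, mirroring "best result" report
#' tables).
#'
#' @param summ A summary frame from [summarise_experiment()].
#' @param by Column to minimise (default `"mean_deg"`).
#' @return Subset of `summ` with one row per pattern x family.
#' @export
best_configs <- function(summ, by = "mean_deg") {
  key <- interaction(summ$pattern, summ$family, drop = TRUE)
  out <- do.call(rbind, lapply(split(summ, key), function(s) {
    s[which.min(s[[by]]), , drop = FALSE]
  }))
  rownames(out) <- NULL
  out[order(out$pattern, out[[by]]), ]
}
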