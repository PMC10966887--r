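#' Default run configuration
#'
#' The documented defaults of a full run: scene geometry, noise parameters
#' and experiment protocol.  Angles are radians internally everywhere;
#' configuration files carry kappa parameters and fields of view in
#' degrees (keys suffixed `_deg`) and they are converted on load.
#'
#' @return A list of class `run_config` with elements `seed`, `scene`,
#'   `noise`, `experiment`, `output_dir`, `log_level`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    scene = scene_config(),
    noise = noise_config(),
    experiment = list(
      n_reps = 100L,
      kappa_hori_mean_deg = 3.9, kappa_hori_sd_deg = 2.2,
      kappa_vert_mean_deg = 0.2, kappa_vert_sd_deg = 1.7,
      kappa_mode = "independent",
      noisy_test = TRUE,
      patterns = c("full", "centre", "subject_small"),
      methods = c("poly", "ridge")
    ),
    output_dir = ".",
    log_level = "info"
  ), class = "run_config")
}

scene_keys <- c("eye_centre_left", "eye_centre_right", "eyeball_radius",
                "eye_cam_left", "eye_cam_right", "scene_cam_origin",
                "scene_cam_forward", "fov_h_deg", "fov_v_deg",
                "target_plane_distance")
noise_keys <- c("p_error", "r_error", "sigma_prec", "p_fd", "burst_min",
                "burst_max", "freeze_burst", "seed")
experiment_keys <- c("n_reps", "kappa_hori_mean_deg", "kappa_hori_sd_deg",
                     "kappa_vert_mean_deg", "kappa_vert_sd_deg",
                     "kappa_mode", "noisy_test", "patterns", "methods")

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown configuration key%s in %s: %s",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", ")))
  invisible(x)
}

#' Load and validate a run configuration file
#'
#' Reads a YAML or JSON configuration, rejects unknown keys (naming the
#' offender), fills all documented defaults, converts degree-valued keys,
#' and returns a fully validated `run_config`.  A minimal configuration
#' needs only `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file '%s' does not exist", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else stop("configuration file must be .yaml, .yml or .json")
  if (is.null(raw)) raw <- list()
  check_keys(raw, c("seed", "scene", "noise", "experiment", "output_dir",
                    "log_level"), "top level")
  if (is.null(raw$seed)) stop("configuration must provide a 'seed'")
  cfg <- default_config()
  cfg$seed <- as.integer(raw$seed)
  if (!is.null(raw$output_dir)) cfg$output_dir <- as.character(raw$output_dir)
  if (!is.null(raw$log_level)) cfg$log_level <- as.character(raw$log_level)
  if (!is.null(raw$scene)) {
    check_keys(raw$scene, scene_keys, "scene")
    cfg$scene <- do.call(scene_config, raw$scene)
  }
  if (!is.null(raw$noise)) {
    check_keys(raw$noise, noise_keys, "noise")
    cfg$noise <- do.call(noise_config, raw$noise)
  }
  if (!is.null(raw$experiment)) {
    check_keys(raw$experiment, experiment_keys, "experiment")
    cfg$experiment <- utils::modifyList(cfg$experiment, raw$experiment)
    cfg$experiment$n_reps <- as.integer(cfg$experiment$n_reps)
    if (cfg$experiment$n_reps < 1L) stop("'n_reps' must be >= 1")
    if (!cfg$experiment$kappa_mode %in% c("independent", "shared", "mirrored"))
      stop("'kappa_mode' must be independent, shared or mirrored")
    if (cfg$experiment$kappa_hori_sd_deg < 0 || cfg$experiment$kappa_vert_sd_deg < 0)
      stop("kappa standard deviations must be >= 0")
    fams <- c("poly", "lasso", "ridge", "ransac", "svr")
    bad <- setdiff(cfg$experiment$methods, fams)
    if (length(bad)) stop(sprintf("unknown method family: %s", paste(bad, collapse = ", ")))
    for (p in cfg$experiment$patterns) pattern_by_name(p)  # validates names
  }
  cfg
}

#' Write a run configuration to YAML or JSON
#'
#' Inverse of [load_config()]: loading the dumped file reproduces the
#' configuration.
#'
#' @param cfg A `run_config`.
#' @param path Destination (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  plain <- list(
    seed = cfg$seed,
    scene = unclass(cfg$scene)[scene_keys],
    noise = Filter(Negate(is.null), unclass(cfg$noise)),
    experiment = cfg$experiment,
    output_dir = cfg$output_dir,
    log_level = cfg$log_level
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(plain, path)
  } else {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 digest of the canonical JSON serialisation; written into every
#' output manifest so artifacts can be traced to the configuration that
#' produced them.
#'
#' @param cfg A `run_config` (or any serialisable list).
#' @return Hex digest string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 15,
                                           force = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}

#' Convert a run configuration to an experiment configuration
#'
#' @param cfg A `run_config` from [load_config()] or [default_config()].
#' @return An [experiment_config()].
#' @export
as_experiment_config <- function(cfg) {
  ex <- cfg$experiment
  experiment_config(patterns = ex$patterns, methods = ex$methods,
                    noise = cfg$noise, scene = cfg$scene,
                    n_reps = ex$n_reps,
                    kappa_hori_mean = ex$kappa_hori_mean_deg,
                    kappa_hori_sd = ex$kappa_hori_sd_deg,
                    kappa_vert_mean = ex$kappa_vert_mean_deg,
                    kappa_vert_sd = ex$kappa_vert_sd_deg,
                    kappa_mode = ex$kappa_mode,
                    noisy_test = ex$noisy_test,
                    seed = cfg$seed)
}

gaze_csv_cols <- c("frame", "target_x", "target_y",
                   "phi_l", "theta_l", "phi_r", "theta_r")

#' Read or write binocular gaze samples as CSV
#'
#' The on-disk format has the header
#' `frame,target_x,target_y,phi_l,theta_l,phi_r,theta_r` with angles in
#' radians, one row per frame.  Malformed rows are rejected with their
#' line number.
#'
#' @param samples A binocular sample data frame.
#' @param path File path.
#' @return `read_gaze_csv` returns the sample data frame;
#'   `write_gaze_csv` returns `path` invisibly.
#' @export
write_gaze_csv <- function(samples, path) {
  if (!all(gaze_csv_cols %in% names(samples)))
    stop("'samples' must contain columns ", paste(gaze_csv_cols, collapse = ", "))
  df <- samples[, gaze_csv_cols]
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("gaze CSV '%s' does not exist", path))
  lines <- readLines(path)
  if (length(lines) == 0L || all(!nzchar(lines)))
    stop(sprintf("gaze CSV '%s' is empty", path))
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  missing_cols <- setdiff(gaze_csv_cols, header)
  if (length(missing_cols))
    stop("gaze CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop(sprintf("gaze CSV '%s' contains no samples", path))
  parts <- strsplit(body, ",", fixed = TRUE)
  ncols <- length(header)
  out <- matrix(NA_real_, length(body), ncols)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != ncols)
      stop(sprintf("malformed row at line %d of '%s': expected %d fields, got %d",
                   i + 1L, path, ncols, length(parts[[i]])))
    vals <- suppressWarnings(as.numeric(parts[[i]]))
    if (anyNA(vals))
      stop(sprintf("malformed row at line %d of '%s': non-numeric value", i + 1L, path))
    out[i, ] <- vals
  }
  df <- as.data.frame(out)
  names(df) <- header
  df <- df[, gaze_csv_cols]
  df$frame <- as.integer(df$frame)
  df
}

#' Serialize or restore a fitted calibration model as JSON
#'
#' Polynomial-family models store their specification, monomial exponents,
#' coefficients and standardization constants; svr models store the
#' support vectors, dual coefficients, offsets and kernel parameters.
#' Restored models predict identically to the originals.
#'
#' @param model A fitted [gaze_calib()] model.
#' @param path File path (`.json`).
#' @return `read_model_json` returns a `gaze_calib` model;
#'   `write_model_json` returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "gaze_calib"))
  doc <- list(spec = model_spec(model), n = model$n,
              training_rmse = as.list(model$training_rmse),
              standardized = isTRUE(model$standardized) || model$method == "svr")
  if (model$method == "svr") {
    doc$std <- model$std
    doc$gamma <- model$gamma
    doc$svr <- lapply(model$svr, function(comp)
      list(sv = comp$sv, coefs = comp$coefs, rho = comp$rho))
  } else {
    doc$exponents <- unname(model$exponents)
    doc$coef <- list(terms = rownames(model$coef),
                     x = unname(model$coef[, 1]), y = unname(model$coef[, 2]))
    if (isTRUE(model$standardized)) doc$std <- model$std
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  spec <- doc$spec
  obj <- list(method = spec$family, degree = as.integer(spec$degree),
              n = doc$n, restored = TRUE,
              training_rmse = unlist(doc$training_rmse))
  if (spec$family == "svr") {
    obj$kernel <- spec$kernel; obj$cost <- spec$cost; obj$epsilon <- spec$epsilon
    obj$gamma <- doc$gamma
    obj$std <- list(mu = as.numeric(doc$std$mu), sd = as.numeric(doc$std$sd))
    obj$svr <- lapply(seq_len(2), function(j) {
      if (is.data.frame(doc$svr)) {
        list(sv = as.matrix(doc$svr$sv[[j]]),
             coefs = as.numeric(doc$svr$coefs[[j]]),
             rho = as.numeric(doc$svr$rho[j]))
      } else {
        comp <- doc$svr[[j]]
        list(sv = as.matrix(comp$sv), coefs = as.numeric(comp$coefs),
             rho = as.numeric(comp$rho))
      }
    })
  } else {
    if (!is.null(spec$alpha) && is.finite(spec$alpha)) obj$alpha <- spec$alpha
    obj$exponents <- as.matrix(doc$exponents)
    dimnames(obj$exponents) <- list(NULL, feature_cols)
    cf <- cbind(x = as.numeric(doc$coef$x), y = as.numeric(doc$coef$y))
    rownames(cf) <- doc$coef$terms
    obj$coef <- cf
    obj$standardized <- isTRUE(doc$standardized)
    if (obj$standardized)
      obj$std <- list(mu = as.numeric(doc$std$mu), sd = as.numeric(doc$std$sd))
  }
  class(obj) <- "gaze_calib"
  obj
}

#' Write a run manifest
#'
#' Every artifact-producing command writes a sidecar manifest recording
#' the configuration hash, seed, package version and timestamp.
#'
#' @param path Path of the artifact the manifest describes; the manifest
#'   is written to `<path>.manifest.json`.
#' @param cfg The configuration that produced the artifact.
#' @param extra Optional named list of additional fields.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(path, cfg, extra = list()) {
  man <- c(list(artifact = basename(path),
                config_hash = config_hash(cfg),
                seed = cfg$seed,
                package = "gazesim",
                version = as.character(utils::packageVersion("gazesim")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  mp <- paste0(path, ".manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
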