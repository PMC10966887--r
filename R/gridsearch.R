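#' Hyperparameter grid of a method family
#'
#' The studied grids: `poly` degrees 1-5; `lasso`/`ridge` degrees 1-5
#' crossed with `alpha` in {1e-4, 1e-3, 1e-2, 0.1, 1, 2}; `ransac` degrees
#' 1-3; `svr` kernels {linear, poly, rbf} crossed with degrees 1-5, `C` in
#' {1e-5, 1e-4, 1e-3, 1e-2, 0.1, 0.5, 1, 2, 5} and `epsilon` in
#' {1e-4, 1e-3, 1e-2, 0.1, 0.2, 0.5, 1}.
#'
#' @param family One of `"poly"`, `"lasso"`, `"ridge"`, `"ransac"`,
#'   `"svr"`.
#' @return A data frame of method specifications with columns `family`,
#'   `degree`, `alpha`, `kernel`, `cost`, `epsilon` (irrelevant fields
#'   `NA`).
#' @export
method_grid <- function(family = c("poly", "lasso", "ridge", "ransac", "svr")) {
  family <- match.arg(family)
  alphas <- c(1e-4, 1e-3, 1e-2, 0.1, 1, 2)
  base <- switch(family,
    poly = data.frame(degree = 1:5),
    ransac = data.frame(degree = 1:3),
    lasso = ,
    ridge = expand.grid(degree = 1:5, alpha = alphas),
    svr = expand.grid(kernel = c("linear", "poly", "rbf"), degree = 1:5,
                      cost = c(1e-5, 1e-4, 1e-3, 1e-2, 0.1, 0.5, 1, 2, 5),
                      epsilon = c(1e-4, 1e-3, 1e-2, 0.1, 0.2, 0.5, 1),
                      stringsAsFactors = FALSE))
  spec_frame(cbind(data.frame(family = family), base))
}

spec_frame <- function(df) {
  for (col in c("degree", "alpha", "kernel", "cost", "epsilon"))
    if (is.null(df[[col]])) df[[col]] <- if (col == "kernel") NA_character_ else NA_real_
  df$degree <- as.integer(df$degree)
  df[, c("family", "degree", "alpha", "kernel", "cost", "epsilon")]
}

#' A single method specification row
#'
#' @param family Method family.
#' @param degree,alpha,kernel,cost,epsilon Family-relevant hyperparameters
#'   (see [method_grid()]).
#' @return A one-row specification data frame.
#' @export
method_spec <- function(family, degree = 3L, alpha = NA_real_,
                        kernel = NA_character_, cost = NA_real_,
                        epsilon = NA_real_) {
  spec_frame(data.frame(family = family, degree = degree, alpha = alpha,
                        kernel = kernel, cost = cost, epsilon = epsilon,
                        stringsAsFactors = FALSE))
}

fit_spec <- function(spec, data, seed = NULL) {
  args <- list(data = data, method = spec$family, degree = spec$degree,
               seed = seed)
  if (spec$family %in% c("lasso", "ridge")) args$alpha <- spec$alpha
  if (spec$family == "svr") {
    args$kernel <- as.character(spec$kernel)
    args$cost <- spec$cost
    args$epsilon <- spec$epsilon
  }
  do.call(gaze_calib, args)
}

#' Grid search over a method family
#'
#' Fits every configuration of the family's grid on the training samples
#' and scores it on the evaluation samples with the supplied error
#' functional.  Note that selecting the best configuration on the
#' evaluation set itself is an oracle selection: it reports the best
#' achievable score of the family on that set, not a generalisation
#' estimate.
#'
#' @param family Method family name, or a specification data frame (as
#'   from [method_grid()]) to search over.
#' @param train,eval_set Binocular sample data frames (see
#'   [simulate_pattern()]).
#' @param metric Error functional `function(model, samples)` returning a
#'   scalar; default [image_mse()], or mean angular error if `scene` is
#'   given.
#' @param scene Optional [scene_config()]; when supplied the default
#'   metric becomes `mean_angular_error(model, eval_set, scene)`.
#' @param seed Optional seed passed to each (stochastic) fit.
#' @return A list of class `gaze_grid_search` with elements `best` (the
#'   winning spec row), `score` (its metric value), `model` (the refitted
#'   winner) and `table` (all specs with their scores; failed fits carry
#'   `NA` score and the error message).
#' @export
grid_search <- function(family, train, eval_set, metric = NULL, scene = NULL,
                        seed = NULL) {
  grid <- if (is.data.frame(family)) spec_frame(family) else method_grid(family)
  if (nrow(grid) == 0L) stop("empty method grid")
  if (is.null(metric)) {
    metric <- if (is.null(scene)) {
      function(model, samples) image_mse(model, samples)
    } else {
      function(model, samples) as.numeric(mean_angular_error(model, samples, scene))
    }
  }
  scores <- rep(NA_real_, nrow(grid))
  errors <- rep(NA_character_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      m <- fit_spec(grid[i, ], train, seed = seed)
      metric(m, eval_set)
    }, error = function(e) e)
    if (inherits(res, "error")) errors[i] <- conditionMessage(res)
    else scores[i] <- res
  }
  tab <- cbind(grid, score = scores, error = errors)
  if (all(is.na(scores))) stop("every configuration in the grid failed to fit")
  best_i <- which.min(scores)
  best_model <- fit_spec(grid[best_i, ], train, seed = seed)
  structure(list(best = grid[best_i, ], score = scores[best_i],
                 model = best_model, table = tab),
            class = "gaze_grid_search")
}

#' @export
print.gaze_grid_search <- function(x, ...) {
  n_fail <- sum(!is.na(x$table$error))
  cat(sprintf("Grid search over %d configurations (%d failed to fit)\n",
              nrow(x$table), n_fail))
  cat("  best:", format_spec(as.list(x$best)), sprintf(" score = %.6g\n", x$score))
  invisible(x)
}
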