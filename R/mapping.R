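#' Multivariate monomial exponents
#'
#' All exponent vectors over `nvars` variables with total degree at most
#' `degree`, ordered by total degree then lexicographically.  The count is
#' `choose(nvars + degree, degree)`.
#'
#' @param degree Maximum total degree, between 1 and 5.
#' @param nvars Number of variables (default 4 binocular angle features).
#' @return Integer matrix, one row per monomial (first row is the
#'   intercept, all zeros).
#' @export
monomial_exponents <- function(degree, nvars = 4L) {
  if (degree < 1 || degree > 5) stop("'degree' must lie in [1, 5]")
  g <- as.matrix(expand.grid(rep(list(0:degree), nvars)))[, nvars:1, drop = FALSE]
  g <- g[rowSums(g) <= degree, , drop = FALSE]
  # total degree first, then variables in feature order (phi_l before theta_r)
  g <- g[order(rowSums(g), -as.numeric(apply(g, 1, paste, collapse = ""))), , drop = FALSE]
  dimnames(g) <- list(NULL, c("phi_l", "theta_l", "phi_r", "theta_r")[seq_len(nvars)])
  g
}

#' Expand binocular angle features into monomials
#'
#' Maps the four features (phi_l, theta_l, phi_r, theta_r) to all
#' multivariate monomials of total degree `<= degree`, cross terms and
#' intercept included.
#'
#' @param X Numeric matrix or data frame with the four feature columns (a
#'   single feature vector of length 4 is also accepted).
#' @param degree Maximum total degree in `[1, 5]`.
#' @param exponents Optional precomputed [monomial_exponents()] matrix.
#' @return Numeric matrix with `choose(4 + degree, degree)` columns; the
#'   first column is the intercept (all ones).
#' @export
expand_features <- function(X, degree, exponents = NULL) {
  X <- feature_matrix(X)
  if (is.null(exponents)) exponents <- monomial_exponents(degree)
  n <- nrow(X)
  p <- nrow(exponents)
  maxd <- max(exponents)
  # per-variable power tables
  pw <- lapply(1:4, function(v) {
    m <- matrix(1, n, maxd + 1L)
    for (k in seq_len(maxd)) m[, k + 1L] <- m[, k] * X[, v]
    m
  })
  out <- matrix(1, n, p)
  for (j in seq_len(p)) {
    col <- rep(1, n)
    for (v in 1:4) {
      e <- exponents[j, v]
      if (e > 0) col <- col * pw[[v]][, e + 1L]
    }
    out[, j] <- col
  }
  colnames(out) <- apply(exponents, 1, function(e) {
    if (all(e == 0)) return("(Intercept)")
    paste(mapply(function(nm, k) if (k == 1) nm else sprintf("%s^%d", nm, k),
                 colnames(exponents)[e > 0], e[e > 0]), collapse = "*")
  })
  out
}

feature_cols <- c("phi_l", "theta_l", "phi_r", "theta_r")

feature_matrix <- function(X) {
  if (is.data.frame(X)) {
    if (!all(feature_cols %in% names(X)))
      stop("data must contain columns ", paste(feature_cols, collapse = ", "))
    X <- as.matrix(X[, feature_cols])
  } else if (is.null(dim(X))) {
    if (length(X) != 4L) stop("a feature vector must have length 4")
    X <- matrix(as.numeric(X), nrow = 1, dimnames = list(NULL, feature_cols))
  } else {
    X <- as.matrix(X)
    if (ncol(X) != 4L) stop("feature matrix must have 4 columns")
    colnames(X) <- feature_cols
  }
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("features must be finite")
  X
}

# minimum-norm least squares via SVD (matches numpy/sklearn lstsq for
# underdetermined designs, where overfitting behaviour is part of the model
# under study)
lstsq_minnorm <- function(A, y) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  as.numeric(coef)
}

std_fit <- function(M) {
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

std_apply <- function(M, std) sweep(sweep(M, 2, std$mu), 2, std$sd, "/")

fit_ridge_closed <- function(Z, y, alpha) {
  # minimises sum((y - b0 - Z g)^2) + alpha * sum(g^2), intercept unpenalised
  ybar <- mean(y)
  G <- crossprod(Z) + diag(alpha, ncol(Z))
  g <- solve(G, crossprod(Z, y - ybar))
  list(intercept = ybar, gamma = as.numeric(g))
}

fit_lasso_glmnet <- function(Z, y, alpha) {
  # glmnet minimises RSS/(2n) + lambda * |g|_1, so lambda = alpha / (2n)
  # recovers the loss sum((y - yhat)^2) + alpha * sum(|g|).  The solver is
  # warm-started along a decreasing lambda path ending at the target value
  # (coordinate descent converges poorly when jumping straight to a tiny
  # penalty on correlated monomials).
  n <- nrow(Z)
  lam <- alpha / (2 * n)
  lam_max <- max(abs(crossprod(Z, y - mean(y)))) / n
  path <- if (lam_max > lam) {
    exp(seq(log(lam_max), log(lam), length.out = 25L))
  } else lam
  fit <- suppressWarnings(
    glmnet::glmnet(Z, y, family = "gaussian", alpha = 1,
                   lambda = path, standardize = FALSE,
                   intercept = TRUE, thresh = 1e-9, maxit = 2e5))
  k <- length(fit$lambda)          # last converged (= target) lambda
  cf <- as.numeric(stats::coef(fit)[, k])
  list(intercept = cf[1], gamma = cf[-1])
}

fit_ransac <- function(A, y, max_iter = 100L, threshold = NULL) {
  # random sample consensus around an unpenalised least-squares fit; the
  # minimal sample size is the number of monomials, so strictly more
  # samples than monomials are required
  n <- nrow(A); p <- ncol(A)
  if (n <= p)
    stop(sprintf("ransac requires more samples (%d) than monomials (%d)", n, p))
  full <- lstsq_minnorm(A, y)
  # default residual threshold: median absolute deviation of the target
  # values about their median (the scikit-learn RANSAC convention, which
  # admits every sample that is not a gross outlier)
  if (is.null(threshold)) threshold <- stats::median(abs(y - stats::median(y)))
  # floor keeps numerically exact fits from rejecting their own inliers
  threshold <- max(threshold, 1e-10)
  best_inl <- NULL; best_count <- -1L; best_loss <- Inf
  for (it in seq_len(max_iter)) {
    idx <- sample.int(n, p)
    # minimum-norm solve tolerates rank-deficient minimal subsets (exact
    # feature collinearities arise, e.g., for symmetric zero-kappa scenes)
    cf <- lstsq_minnorm(A[idx, , drop = FALSE], y[idx])
    r <- abs(y - A %*% cf)
    inl <- r < threshold
    cnt <- sum(inl)
    if (cnt < p) next
    loss <- mean(r[inl])
    if (cnt > best_count || (cnt == best_count && loss < best_loss)) {
      best_count <- cnt; best_inl <- inl; best_loss <- loss
    }
  }
  if (is.null(best_inl)) {
    warning("ransac found no consensus set; falling back to the full fit")
    return(list(gamma = full, inliers = rep(TRUE, n), threshold = threshold))
  }
  cf <- lstsq_minnorm(A[best_inl, , drop = FALSE], y[best_inl])
  list(gamma = cf, inliers = as.vector(best_inl), threshold = threshold)
}

svr_kernel_eval <- function(kernel, gamma, degree, U, V) {
  # K(u, v) rows of U vs rows of V
  switch(kernel,
         linear = U %*% t(V),
         poly = (gamma * (U %*% t(V)))^degree,
         rbf = {
           d2 <- outer(rowSums(U^2), rowSums(V^2), "+") - 2 * (U %*% t(V))
           exp(-gamma * pmax(d2, 0))
         },
         stop(sprintf("unknown svr kernel '%s'", kernel)))
}

fit_svr <- function(Z, y, kernel, degree, cost, epsilon, gamma) {
  ek <- switch(kernel, linear = "linear", poly = "polynomial", rbf = "radial")
  m <- e1071::svm(x = Z, y = y, type = "eps-regression", kernel = ek,
                  degree = degree, gamma = gamma, coef0 = 0,
                  cost = cost, epsilon = epsilon, scale = FALSE)
  list(sv = unname(as.matrix(m$SV)), coefs = as.numeric(m$coefs),
       rho = as.numeric(m$rho))
}

svr_predict <- function(comp, Znew, kernel, degree, gamma) {
  K <- svr_kernel_eval(kernel, gamma, degree, Znew, comp$sv)
  as.numeric(K %*% comp$coefs - comp$rho)
}

#' Fit a gaze-mapping calibration model
#'
#' Fits the mapping from the four binocular angle features (phi_l, theta_l,
#' phi_r, theta_r, radians) to target image coordinates as two independent
#' single-output regressions, one per coordinate.  Five method families are
#' available:
#'
#' * `poly` — polynomial least squares on the multivariate monomial
#'   expansion of the features (all cross terms up to total `degree`),
#'   minimising the residual sum of squares `sse`.  Underdetermined designs
#'   use the minimum-norm solution.
#' * `lasso` — minimises `sse + alpha * sum(|gamma|)` (intercept
#'   unpenalised) on standardized monomials, via glmnet with the penalty
#'   rescaled to this exact loss.
#' * `ridge` — minimises `sse + alpha * sum(gamma^2)` (intercept
#'   unpenalised) on standardized monomials, in closed form.
#' * `ransac` — random sample consensus around unpenalised least squares on
#'   raw monomials: repeatedly fits minimal subsets, keeps the largest
#'   inlier consensus (residual threshold: median absolute deviation of the
#'   target values, the scikit-learn convention), and refits on the
#'   consensus set.
#' * `svr` — epsilon support vector regression (libsvm via e1071) on the
#'   standardized raw features with `linear`, `poly` or `rbf` kernel,
#'   kernel scale `1 / (4 * Var(X))` where 4 is the number of features and
#'   `Var(X)` the variance of the (standardized) feature matrix.
#'
#' Penalized and SVR fits standardize their design columns to zero mean and
#' unit training variance (penalty fairness across monomial scales);
#' `poly` and `ransac` fit raw monomials.  The standardization constants
#' are stored in the model and compensated at prediction time.
#'
#' @param data Training samples: a data frame with columns `phi_l`,
#'   `theta_l`, `phi_r`, `theta_r`, `target_x`, `target_y` (as produced by
#'   [simulate_pattern()]).
#' @param method Method family: `"poly"`, `"lasso"`, `"ridge"`,
#'   `"ransac"` or `"svr"`.
#' @param degree Polynomial degree (1-5; ransac supports 1-3; for svr the
#'   degree only affects the `poly` kernel).
#' @param alpha Penalty weight for lasso/ridge.
#' @param kernel SVR kernel: `"linear"`, `"poly"` or `"rbf"`.
#' @param cost SVR penalty weight C.
#' @param epsilon SVR margin.
#' @param ransac_max_iter,ransac_threshold RANSAC iteration budget and
#'   residual threshold (default: median absolute deviation of the target
#'   values about their median).
#' @param seed Optional seed for the stochastic fitters (ransac).
#' @return An object of class `gaze_calib` with `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals` and `plot` methods.
#' @examples
#' samp <- simulate_pattern(pattern_full())
#' fit <- gaze_calib(samp, method = "ridge", degree = 3, alpha = 0.01)
#' head(predict(fit, samp))
#' @export
gaze_calib <- function(data,
                       method = c("poly", "lasso", "ridge", "ransac", "svr"),
                       degree = 3L, alpha = 0.01, kernel = c("rbf", "linear", "poly"),
                       cost = 1, epsilon = 0.1,
                       ransac_max_iter = 100L, ransac_threshold = NULL,
                       seed = NULL) {
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  degree <- as.integer(degree)
  if (degree < 1L || degree > 5L) stop("'degree' must lie in [1, 5]")
  if (method == "ransac" && degree > 3L)
    stop("ransac supports degrees 1-3 only")
  if (method %in% c("lasso", "ridge") && (!is.finite(alpha) || alpha <= 0))
    stop("'alpha' must be > 0 for lasso/ridge")
  need <- c(feature_cols, "target_x", "target_y")
  if (!all(need %in% names(data)))
    stop("'data' must contain columns ", paste(need, collapse = ", "))
  X <- feature_matrix(data)
  Y <- cbind(x = data$target_x, y = data$target_y)
  n <- nrow(X)
  if (n < 2L) stop(sprintf("%s needs at least 2 samples", method))
  if (!is.null(seed)) set.seed(seed)

  obj <- list(method = method, degree = degree, n = n, call = match.call())

  if (method == "svr") {
    std <- std_fit(X)
    Z <- std_apply(X, std)
    gamma <- 1 / (4 * stats::var(as.vector(Z)))
    comps <- lapply(1:2, function(j)
      fit_svr(Z, Y[, j], kernel, degree, cost, epsilon, gamma))
    obj <- c(obj, list(kernel = kernel, cost = cost, epsilon = epsilon,
                       gamma = gamma, std = std, svr = comps))
  } else {
    exponents <- monomial_exponents(degree)
    M <- expand_features(X, degree, exponents)
    terms <- colnames(M)
    if (method %in% c("lasso", "ridge")) {
      D <- M[, -1, drop = FALSE]             # intercept handled separately
      std <- std_fit(D)
      Z <- std_apply(D, std)
      fits <- lapply(1:2, function(j)
        if (method == "ridge") fit_ridge_closed(Z, Y[, j], alpha)
        else fit_lasso_glmnet(Z, Y[, j], alpha))
      coefs <- cbind(x = c(fits[[1]]$intercept, fits[[1]]$gamma),
                     y = c(fits[[2]]$intercept, fits[[2]]$gamma))
      rownames(coefs) <- terms
      obj <- c(obj, list(alpha = alpha, exponents = exponents, std = std,
                         coef = coefs, standardized = TRUE))
    } else if (method == "poly") {
      coefs <- cbind(x = lstsq_minnorm(M, Y[, 1]),
                     y = lstsq_minnorm(M, Y[, 2]))
      rownames(coefs) <- terms
      obj <- c(obj, list(exponents = exponents, std = NULL, coef = coefs,
                         standardized = FALSE))
    } else { # ransac
      fx <- fit_ransac(M, Y[, 1], ransac_max_iter, ransac_threshold)
      fy <- fit_ransac(M, Y[, 2], ransac_max_iter, ransac_threshold)
      coefs <- cbind(x = fx$gamma, y = fy$gamma)
      rownames(coefs) <- terms
      obj <- c(obj, list(exponents = exponents, std = NULL, coef = coefs,
                         standardized = FALSE,
                         ransac = list(inliers_x = fx$inliers,
                                       inliers_y = fy$inliers,
                                       threshold_x = fx$threshold,
                                       threshold_y = fy$threshold,
                                       max_iter = ransac_max_iter)))
    }
  }
  class(obj) <- "gaze_calib"
  fv <- predict(obj, X)
  obj$fitted.values <- fv
  obj$residuals <- Y - fv
  obj$training_rmse <- sqrt(colMeans(obj$residuals^2))
  obj
}

#' Predict image coordinates from binocular angle features
#'
#' @param object A fitted [gaze_calib()] model.
#' @param newdata A data frame containing the four feature columns, a
#'   numeric matrix with 4 columns, or a single feature vector of length 4.
#' @param ... Unused.
#' @return Numeric matrix with columns `x`, `y` of predicted image
#'   fractions (unclipped; extrapolated predictions may leave `[0, 1]`).
#' @export
predict.gaze_calib <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  X <- feature_matrix(newdata)
  if (object$method == "svr") {
    Z <- std_apply(X, object$std)
    out <- cbind(
      x = svr_predict(object$svr[[1]], Z, object$kernel, object$degree, object$gamma),
      y = svr_predict(object$svr[[2]], Z, object$kernel, object$degree, object$gamma))
  } else {
    M <- expand_features(X, object$degree, object$exponents)
    if (isTRUE(object$standardized)) {
      Z <- cbind(1, std_apply(M[, -1, drop = FALSE], object$std))
      out <- Z %*% object$coef
    } else {
      out <- M %*% object$coef
    }
    colnames(out) <- c("x", "y")
  }
  out
}

#' Model coefficients of a polynomial-family calibration
#'
#' @param object A fitted [gaze_calib()] model of family poly, lasso,
#'   ridge or ransac.
#' @param standardized If `TRUE` (default for standardized fits), return
#'   coefficients on the standardized monomial scale; if `FALSE`,
#'   back-transform to raw monomials.
#' @param ... Unused.
#' @return Matrix of coefficients (monomials x the two outputs), or `NULL`
#'   with a message for svr models (which are kernel expansions, not
#'   polynomials).
#' @export
coef.gaze_calib <- function(object, standardized = object$standardized %||% FALSE, ...) {
  if (object$method == "svr") {
    message("svr models have no polynomial coefficients")
    return(invisible(NULL))
  }
  cf <- object$coef
  if (isTRUE(object$standardized) && !standardized) {
    sc <- object$std
    out <- cf
    out[-1, ] <- cf[-1, ] / sc$sd
    out[1, ] <- cf[1, ] - colSums(cf[-1, , drop = FALSE] * (sc$mu / sc$sd))
    return(out)
  }
  cf
}

#' @export
fitted.gaze_calib <- function(object, ...) object$fitted.values

#' @export
residuals.gaze_calib <- function(object, ...) object$residuals

#' @export
print.gaze_calib <- function(x, ...) {
  cat(sprintf("Gaze-mapping calibration (%s)\n", x$method))
  cat("  ", format_spec(model_spec(x)), "\n", sep = "")
  cat(sprintf("  %d training samples; training RMSE (image fractions): x %.4g, y %.4g\n",
              x$n, x$training_rmse[1], x$training_rmse[2]))
  invisible(x)
}

#' @export
summary.gaze_calib <- function(object, ...) {
  out <- list(method = object$method, spec = model_spec(object),
              n = object$n, rmse = object$training_rmse,
              resid_quantiles = apply(object$residuals, 2, stats::quantile,
                                      probs = c(0, 0.25, 0.5, 0.75, 1)))
  if (object$method %in% c("poly", "lasso", "ridge", "ransac")) {
    out$n_terms <- nrow(object$coef)
    out$standardized <- isTRUE(object$standardized)
  }
  if (object$method == "ransac")
    out$n_inliers <- c(x = sum(object$ransac$inliers_x),
                       y = sum(object$ransac$inliers_y))
  if (object$method == "svr")
    out$n_support <- c(x = length(object$svr[[1]]$coefs),
                       y = length(object$svr[[2]]$coefs))
  class(out) <- "summary.gaze_calib"
  out
}

#' @export
print.summary.gaze_calib <- function(x, ...) {
  cat(sprintf("Gaze-mapping calibration (%s), %d samples\n", x$method, x$n))
  cat("  spec:", format_spec(x$spec), "\n")
  if (!is.null(x$n_terms))
    cat(sprintf("  %d monomial terms; features standardized: %s\n",
                x$n_terms, x$standardized))
  if (!is.null(x$n_inliers))
    cat(sprintf("  consensus inliers: x %d, y %d\n", x$n_inliers[1], x$n_inliers[2]))
  if (!is.null(x$n_support))
    cat(sprintf("  support vectors: x %d, y %d\n", x$n_support[1], x$n_support[2]))
  cat(sprintf("  training RMSE: x %.4g, y %.4g (image fractions)\n",
              x$rmse[1], x$rmse[2]))
  cat("  residual quantiles:\n")
  print(round(x$resid_quantiles, 5))
  invisible(x)
}

#' @export
plot.gaze_calib <- function(x, ...) {
  fv <- x$fitted.values
  tg <- fv + x$residuals
  graphics::plot(tg[, 1], tg[, 2], pch = 1, col = "grey40",
                 xlab = "target x (image fraction)", ylab = "target y",
                 main = sprintf("gaze_calib (%s): targets and fitted points", x$method),
                 ...)
  graphics::points(fv[, 1], fv[, 2], pch = 20, col = "firebrick", cex = 0.6)
  graphics::segments(tg[, 1], tg[, 2], fv[, 1], fv[, 2], col = "grey70")
  invisible(x)
}

model_spec <- function(object) {
  spec <- list(family = object$method, degree = object$degree)
  if (object$method %in% c("lasso", "ridge")) spec$alpha <- object$alpha
  if (object$method == "svr") {
    spec$kernel <- object$kernel
    spec$cost <- object$cost
    spec$epsilon <- object$epsilon
  }
  spec
}

format_spec <- function(spec) {
  parts <- c(sprintf("family = %s", spec$family),
             sprintf("degree = %d", spec$degree))
  if (!is.null(spec$alpha) && is.finite(spec$alpha))
    parts <- c(parts, sprintf("alpha = %g", spec$alpha))
  if (!is.null(spec$kernel) && !is.na(spec$kernel))
    parts <- c(parts, sprintf("kernel = %s", spec$kernel),
               sprintf("C = %g", spec$cost),
               sprintf("epsilon = %g", spec$epsilon))
  paste(parts, collapse = ", ")
}
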