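#' Weighted elastic net coefficient path by coordinate descent
#'
#' Minimizes, along a decreasing lambda path with warm starts,
#' \deqn{\frac{1}{2n}\|y - \beta_0 - X\beta\|^2 +
#'   \lambda \sum_j w_j \left(\alpha |\beta_j| +
#'   \frac{1-\alpha}{2}\beta_j^2\right)}
#' by cyclic coordinate descent with covariance updates. Penalty factors
#' `w_j = 1` for penalized columns (CpGs) and `w_j = 0` for unpenalized
#' covariates, which are updated without shrinkage. The intercept is always
#' unpenalized and obtained by centering.
#'
#' When `lambda` is `NULL` the path is `nlambda` geometrically spaced values
#' from `lambda_max` down to `lambda_max * lambda_min_ratio`, where
#' `lambda_max` is computed from the partial residual after an OLS fit of `y`
#' on the unpenalized columns, so the first path solution has every penalized
#' coefficient exactly zero.
#'
#' @param x Numeric predictor matrix (n x p) or a `design_matrix` from
#'   [build_design()] (in which case `y` and `penalty_factor` are taken from
#'   it).
#' @param y Numeric outcome vector.
#' @param penalty_factor Vector of 0/1 penalty weights, one per column.
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (1 = lasso,
#'   0 = ridge).
#' @param lambda Optional decreasing vector of penalties; computed when `NULL`.
#' @param nlambda,lambda_min_ratio Path geometry when `lambda` is `NULL`.
#' @param tol Convergence tolerance on the maximum absolute coefficient change
#'   per sweep.
#' @param maxit Maximum sweeps per lambda.
#' @return An object of class `enet_path`: `lambda`, `beta` (p x nlambda),
#'   `intercept` (per lambda), `df` (nonzero penalized coefficients),
#'   `penalty_factor`, `alpha`.
#' @export
enet_path <- function(x, y = NULL, penalty_factor = NULL, alpha = 0.5,
                      lambda = NULL, nlambda = 100, lambda_min_ratio = 1e-4,
                      tol = 1e-7, maxit = 1e5) {
  if (inherits(x, "design_matrix")) {
    y <- x$y
    penalty_factor <- x$info$penalty_factor
    x <- x$x
  }
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1].")
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(penalty_factor)) penalty_factor <- rep(1, p)
  stopifnot(length(y) == n, length(penalty_factor) == p)

  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2, xm)
  yc <- y - ym
  xtx <- crossprod(xc) / n
  xty <- as.numeric(crossprod(xc, yc)) / n

  if (is.null(lambda)) {
    lambda_max <- lambda_max_enet(xc, yc, penalty_factor, alpha)
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    lambda <- sort(lambda, decreasing = TRUE)
  }

  fit <- enet_cd_path(xtx, xty, as.numeric(penalty_factor), alpha,
                      lambda, tol, as.integer(maxit))
  if (!all(fit$converged)) {
    bad <- which(!fit$converged)[1]
    abort(sprintf("coordinate descent did not converge at lambda = %.6g (maxit = %d).",
                  lambda[bad], as.integer(maxit)))
  }
  beta <- fit$beta
  rownames(beta) <- colnames(x)
  intercept <- ym - as.numeric(xm %*% beta)
  structure(
    list(lambda = lambda, beta = beta, intercept = intercept,
         df = colSums(beta[penalty_factor > 0, , drop = FALSE] != 0),
         penalty_factor = penalty_factor, alpha = alpha,
         iters = fit$iters),
    class = "enet_path"
  )
}

# smallest lambda at which all penalized coefficients are zero: computed on
# the partial residual after an OLS fit on the unpenalized columns (plus the
# intercept, i.e. centering). alpha floored at 1e-3 as is conventional for
# the ridge end of the grid.
lambda_max_enet <- function(xc, yc, penalty_factor, alpha) {
  unpen <- which(penalty_factor == 0)
  r <- if (length(unpen)) {
    xu <- xc[, unpen, drop = FALSE]
    keep <- apply(xu, 2, function(v) any(v != 0))
    if (any(keep)) resid(lm.fit(xu[, keep, drop = FALSE], yc)) else yc
  } else {
    yc
  }
  n <- length(yc)
  pen <- which(penalty_factor > 0)
  g <- abs(as.numeric(crossprod(xc[, pen, drop = FALSE], r))) / n /
    penalty_factor[pen]
  max(g) / max(alpha, 1e-3)
}

#' Predict from an elastic net path
#'
#' @param object An `enet_path`.
#' @param newx Matrix of predictors (same columns as the training design).
#' @param ... Unused.
#' @return Matrix of fitted values, one column per lambda.
#' @export
predict.enet_path <- function(object, newx, ...) {
  sweep(newx %*% object$beta, 2, object$intercept, "+")
}

#' Karush-Kuhn-Tucker residuals of an elastic net solution
#'
#' For each penalized coordinate the stationarity condition is
#' `|x_j' r / n - lambda (1 - alpha) w_j beta_j| <= lambda alpha w_j`, with
#' equality (and matching sign) when `beta_j != 0`; unpenalized coordinates
#' must have zero gradient. Returns the worst violation per lambda -- a
#' correct solution has residuals at numerical-noise level.
#'
#' @param object An `enet_path`.
#' @param x,y The training data the path was fit on.
#' @return Numeric vector of maximum KKT violations, one per lambda.
#' @export
kkt_residuals <- function(object, x, y) {
  n <- nrow(x)
  w <- object$penalty_factor
  vapply(seq_along(object$lambda), function(l) {
    lam <- object$lambda[l]
    b <- object$beta[, l]
    r <- y - object$intercept[l] - as.numeric(x %*% b)
    grad <- as.numeric(crossprod(x, r)) / n - lam * (1 - object$alpha) * w * b
    viol <- numeric(length(b))
    active <- which(b != 0 & w > 0)
    inactive <- which(b == 0 & w > 0)
    free <- which(w == 0 & apply(x, 2, function(v) var(v) > 0))
    viol[active] <- abs(grad[active] - lam * object$alpha * w[active] * sign(b[active]))
    viol[inactive] <- pmax(abs(grad[inactive]) - lam * object$alpha * w[inactive], 0)
    viol[free] <- abs(grad[free])
    max(viol)
  }, numeric(1))
}

#' Reference elastic net solver (proximal gradient)
#'
#' A slow, simple FISTA solver for the same weighted elastic net objective as
#' [enet_path()], kept deliberately independent of the coordinate-descent code
#' path so the two can be cross-checked. Intended for small instances.
#'
#' @inheritParams enet_path
#' @param lambda A single penalty value.
#' @return A list with `intercept` and `beta`.
#' @export
enet_reference <- function(x, y, penalty_factor, alpha, lambda,
                           tol = 1e-12, maxit = 2e5) {
  n <- nrow(x)
  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2, xm)
  yc <- y - ym
  L <- max(eigen(crossprod(xc) / n, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / L
  p <- ncol(x)
  b <- numeric(p)
  z <- b
  tk <- 1
  obj_old <- Inf
  for (it in seq_len(maxit)) {
    grad <- -as.numeric(crossprod(xc, yc - xc %*% z)) / n
    u <- z - step * grad
    # prox of step * lambda * w_j * (alpha|b| + (1-alpha)/2 b^2)
    thr <- step * lambda * alpha * penalty_factor
    denom <- 1 + step * lambda * (1 - alpha) * penalty_factor
    b_new <- sign(u) * pmax(abs(u) - thr, 0) / denom
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- b_new + ((tk - 1) / t_new) * (b_new - b)
    b <- b_new
    tk <- t_new
    if (it %% 50 == 0) {
      r <- yc - xc %*% b
      obj <- sum(r^2) / (2 * n) +
        lambda * sum(penalty_factor * (alpha * abs(b) + (1 - alpha) / 2 * b^2))
      if (abs(obj_old - obj) < tol * max(1, abs(obj))) break
      obj_old <- obj
    }
  }
  list(intercept = ym - sum(xm * b), beta = b)
}

#' @export
print.enet_path <- function(x, ...) {
  cat(sprintf("<enet_path> alpha = %.2f, %d lambdas in [%.4g, %.4g]\n",
              x$alpha, length(x$lambda), min(x$lambda), max(x$lambda)))
  cat(sprintf("  df range (nonzero penalized coefficients): %d..%d\n",
              min(x$df), max(x$df)))
  invisible(x)
}
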