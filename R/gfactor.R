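#' Impute missing cognitive test scores from the battery correlation structure
#'
#' Each test is z-scored on its observed values; a subject's missing tests are
#' predicted from their observed tests via the conditional mean implied by the
#' battery correlation matrix (`z_miss = R[m,o] R[o,o]^{-1} z_obs`), then
#' mapped back to the raw scale. Subjects missing half or more of the battery
#' are excluded (returned in the `excluded` attribute).
#'
#' @param tests Data frame with `sample_id` and numeric test columns (`NA` for
#'   missing scores).
#' @return A completed tibble; excluded subjects (if any) in
#'   `attr(, "excluded")`.
#' @export
impute_tests <- function(tests) {
  test_cols <- setdiff(names(tests), "sample_id")
  x <- as.matrix(tests[test_cols])
  k <- ncol(x)
  frac_missing <- rowMeans(is.na(x))
  excluded <- tests$sample_id[frac_missing >= 0.5]
  if (length(excluded)) {
    inform(sprintf("%d subject(s) missing >= 50%% of tests excluded from imputation.",
                   length(excluded)))
    keep <- frac_missing < 0.5
    tests <- tests[keep, , drop = FALSE]
    x <- x[keep, , drop = FALSE]
  }
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    sdv <- apply(x, 2, sd, na.rm = TRUE)
    z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    r <- cor(z, use = "pairwise.complete.obs")
    r[is.na(r)] <- 0
    diag(r) <- 1
    for (i in which(rowSums(is.na(z)) > 0)) {
      m <- is.na(z[i, ])
      o <- !m
      roo <- r[o, o, drop = FALSE]
      # small ridge keeps near-singular batteries invertible
      pred <- r[m, o, drop = FALSE] %*%
        solve(roo + diag(1e-8, nrow(roo)), z[i, o])
      z[i, m] <- pred
    }
    x <- sweep(sweep(z, 2, sdv, "*"), 2, mu, "+")
  }
  out <- tibble::as_tibble(tests)
  out[test_cols] <- tibble::as_tibble(x)
  attr(out, "excluded") <- excluded
  out
}

#' Derive the general cognitive ability factor (g)
#'
#' z-standardizes every test, eigendecomposes the battery correlation matrix,
#' and extracts the first unrotated principal component. PC1 loadings are
#' sign-fixed so the mean loading is positive (higher g = better performance);
#' subject scores on PC1 are standardized to mean 0, SD 1.
#'
#' @param tests Data frame with `sample_id` and complete numeric test columns
#'   (use [impute_tests()] first if scores are missing).
#' @return An object of class `gfactor`: `loadings` (unit-norm eigenvector
#'   entries per test), `eigenvalues` (sum to the number of tests),
#'   `prop_var_pc1`, and `scores` (tibble `sample_id`, `g`).
#' @export
derive_g <- function(tests) {
  test_cols <- setdiff(names(tests), "sample_id")
  if (length(test_cols) < 2) abort("at least 2 tests are required.")
  x <- as.matrix(tests[test_cols])
  if (anyNA(x)) abort("missing test scores; run impute_tests() first.")
  sdv <- apply(x, 2, sd)
  if (any(sdv == 0)) {
    abort(paste0("constant test column(s): ",
                 paste(test_cols[sdv == 0], collapse = ", ")))
  }
  z <- scale(x)
  r <- cor(z)
  eig <- eigen(r, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  if (mean(v1) < 0) v1 <- -v1
  g <- as.numeric(scale(z %*% v1))
  structure(
    list(
      loadings = tibble::tibble(test = test_cols, loading = v1),
      eigenvalues = eig$values,
      prop_var_pc1 = eig$values[1] / length(test_cols),
      scores = tibble::tibble(sample_id = tests$sample_id, g = g),
      correlation = r
    ),
    class = "gfactor"
  )
}

#' Proportion of battery variance explained by an eigenvalue
#'
#' For correlation-matrix PCA the eigenvalues sum to the number of tests, so
#' the variance share of a component is `eigenvalue / n_tests`.
#'
#' @param eigenvalue Non-negative eigenvalue.
#' @param n_tests Number of tests in the battery.
#' @return The fraction of variance explained.
#' @examples
#' variance_explained(7.90, 19)  # 0.4158
#' variance_explained(5.53, 14)  # 0.395
#' @export
variance_explained <- function(eigenvalue, n_tests) {
  if (any(n_tests < 1)) abort("n_tests must be at least 1.")
  if (any(eigenvalue < 0)) abort("eigenvalue must be non-negative.")
  eigenvalue / n_tests
}

#' @export
print.gfactor <- function(x, ...) {
  cat(sprintf("<gfactor> PC1 of %d tests, n = %d subjects\n",
              nrow(x$loadings), nrow(x$scores)))
  cat(sprintf("  eigenvalue 1 = %.3f (%.1f%% of battery variance)\n",
              x$eigenvalues[1], 100 * x$prop_var_pc1))
  invisible(x)
}

#' @export
tidy.gfactor <- function(x, ...) x$loadings

#' @export
glance.gfactor <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$loadings),
    n = nrow(x$scores),
    eigenvalue_1 = x$eigenvalues[1],
    prop_var_pc1 = x$prop_var_pc1
  )
}

#' @export
autoplot.gfactor <- function(object, ...) {
  df <- tibble::tibble(component = seq_along(object$eigenvalues),
                       eigenvalue = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Principal component", y = "Eigenvalue",
                  title = "Scree plot of the cognitive battery") +
    ggplot2::theme_minimal()
}
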