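test_that("univariate lasso reproduces the soft-thresholding closed form", {
  set.seed(1)
  n <- 200
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x1"))
  y <- 0.5 * x[, 1] + rnorm(n)
  xc <- x[, 1] - mean(x[, 1])
  yc <- y - mean(y)
  for (lam in c(0.02, 0.1, 0.3)) {
    fit <- enet_path(x, y, penalty_factor = 1, alpha = 1, lambda = c(1, lam),
                     tol = 1e-13)
    z <- sum(xc * yc) / n
    bhat <- sign(z) * max(abs(z) - lam, 0) / (sum(xc^2) / n)
    expect_equal(unname(fit$beta[1, 2]), bhat, tolerance = 1e-8)
  }
})

test_that("the path boundary zeroes all penalized coefficients, covariates stay OLS", {
  set.seed(2)
  n <- 120
  x <- cbind(matrix(rnorm(n * 6), n, 6), rnorm(n), rnorm(n))
  colnames(x) <- c(paste0("cg", 1:6), "cov1", "cov2")
  y <- x[, 7] * 0.8 + x[, 1] * 0.5 + rnorm(n)
  w <- c(rep(1, 6), 0, 0)
  fit <- enet_path(x, y, w, alpha = 0.7, nlambda = 25)
  expect_true(all(fit$beta[1:6, 1] == 0))
  ols <- lm(y ~ x[, 7] + x[, 8])
  expect_equal(unname(fit$beta[7:8, 1]), unname(coef(ols)[2:3]), tolerance = 1e-6)
  expect_equal(fit$intercept[1], unname(coef(ols)[1]), tolerance = 1e-6)
  # sparsity grows along the decreasing path
  expect_equal(fit$df[1], 0)
  expect_gt(cor(seq_along(fit$lambda), fit$df), 0)
  expect_error(enet_path(x, y, w, alpha = 1.2), "alpha")
})

test_that("coordinate descent matches the proximal-gradient oracle with clean KKT", {
  set.seed(3)
  for (i in 1:5) {
    n <- 60; p <- 8
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- as.numeric(x[, 1:3] %*% c(1, -0.5, 0.25) + rnorm(n))
    w <- c(rep(1, 6), 0, 0)
    for (a in c(0, 0.5, 1)) {
      fit <- enet_path(x, y, w, alpha = a, nlambda = 12)
      expect_lt(max(kkt_residuals(fit, x, y)), 1e-6)
      for (l in c(4, 8, 12)) {
        ref <- enet_reference(x, y, w, a, fit$lambda[l])
        expect_lt(max(abs(ref$beta - fit$beta[, l])), 1e-5)
      }
    }
  }
})

test_that("solutions agree with glmnet under its penalty parameterization", {
  library(glmnet)
  set.seed(4)
  n <- 150; p <- 12
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- as.numeric(x %*% c(rep(0.7, 3), rep(0, p - 3)) + rnorm(n))
  # lasso: identical objectives
  fit <- enet_path(x, y, rep(1, p), alpha = 1, nlambda = 25)
  g <- glmnet(x, y, alpha = 1, standardize = FALSE, lambda = fit$lambda,
              thresh = 1e-14, maxit = 1e7)
  expect_lt(max(abs(as.matrix(coef(g))[-1, ] - fit$beta)), 1e-6)
  # mixed alpha: glmnet scales the ridge term by the (1/n) SD of y; map
  # (alpha, lambda) onto glmnet's parameterization before comparing
  alpha <- 0.4
  fit2 <- enet_path(x, y, rep(1, p), alpha = alpha, nlambda = 10)
  sy <- sd(y) * sqrt((n - 1) / n)
  for (i in c(3, 6, 9)) {
    lam2 <- fit2$lambda[i] * alpha + sy * fit2$lambda[i] * (1 - alpha)
    al2 <- fit2$lambda[i] * alpha / lam2
    g2 <- glmnet(x, y, alpha = al2, standardize = FALSE,
                 lambda = lam2 * c(4, 2, 1), thresh = 1e-14, maxit = 1e7)
    expect_lt(max(abs(as.matrix(coef(g2))[-1, 3] - fit2$beta[, i])), 1e-6)
  }
})

test_that("design matrix standardization, exclusion, and zero-fill contracts hold", {
  cfg <- small_config(missing_rate = 0)
  co <- generate_cohort(cfg)
  bat <- generate_test_battery(co$truth$g_true, cfg)
  pheno <- dplyr::inner_join(co$pheno, derive_g(bat)$scores, by = "sample_id")
  candidates <- co$annotation$probe_id[co$annotation$candidate]
  absent <- c("cg99999991", "cg99999992")
  d <- build_design(co$beta, pheno, c(candidates, absent))
  is_cpg <- d$info$kind == "cpg"
  xz <- d$x[, is_cpg & !colnames(d$x) %in% absent]
  expect_lt(max(abs(colMeans(xz))), 1e-10)
  expect_equal(unname(apply(xz, 2, sd)), rep(1, ncol(xz)), tolerance = 1e-10)
  expect_true(all(d$x[, absent] == 0))
  expect_false(any(d$info$penalty_factor == 0 & d$info$kind == "cpg"))
  expect_equal(sum(d$info$kind == "covariate"),
               5 + 1 + (nlevels(pheno$batch) - 1))

  # a subject missing >10% of the measured pool is excluded
  vals <- co$beta$values
  vals[seq_len(ceiling(0.11 * length(candidates))), 1] <- NA
  d2 <- build_design(beta_matrix(vals), pheno, candidates)
  expect_true(sample_ids(co$beta)[1] %in% d2$excluded$sample_id)
  expect_false(sample_ids(co$beta)[1] %in% d2$sample_ids)

  # zero-variance probes are dropped with a warning
  vals3 <- co$beta$values
  vals3[candidates[1], ] <- 0.5
  expect_warning(d3 <- build_design(beta_matrix(vals3), pheno, candidates),
                 "zero-variance")
  expect_false(candidates[1] %in% colnames(d3$x))
})

test_that("the 1-SE rule matches the hand-checked toy path", {
  cvm <- c(1.00, 0.90, 0.85, 0.88)
  cvse <- c(0.06, 0.05, 0.05, 0.05)
  expect_equal(one_se_index(cvm, cvse), 2L)     # 0.90 <= 0.85 + 0.05
  expect_equal(one_se_index(c(1, 0.8, 0.79), c(0.001, 0.001, 0.001)), 3L)
  expect_equal(one_se_index(c(0.5, 0.6), c(0.01, 0.01)), 1L)
})

test_that("cross-validation is deterministic and validates folds", {
  set.seed(5)
  n <- 80; p <- 20
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("cg", 1:p)))
  y <- as.numeric(x[, 1:4] %*% rep(0.4, 4) + rnorm(n))
  d <- raw_design(x, y)
  cv1 <- cross_validate(d, alpha_grid = c(0.5, 1), n_folds = 5, seed = 9,
                        nlambda = 30)
  cv2 <- cross_validate(d, alpha_grid = c(0.5, 1), n_folds = 5, seed = 9,
                        nlambda = 30)
  expect_identical(cv1$path, cv2$path)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_error(cross_validate(d, n_folds = 60), "fewer than 2")
  # lambda path decreasing, SEs non-negative, 1-SE above the minimizer
  per_a <- dplyr::group_split(cv1$path, .data$alpha)
  for (pa in per_a) {
    expect_true(all(diff(pa$lambda) < 0))
    expect_true(all(pa$cvse >= 0))
  }
  expect_true(all(cv1$summary$lambda_1se >= cv1$summary$lambda_min))
})

test_that("pure-noise outcomes select (near-)empty models in most seeds", {
  sizes <- vapply(1:20, function(s) {
    set.seed(s + 300)
    n <- 150; p <- 60
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("cg", 1:p)))
    cv <- cross_validate(raw_design(x, rnorm(n)), alpha_grid = 0.5,
                         n_folds = 5, seed = s, nlambda = 50)
    cv$summary$nzero_1se[1]
  }, numeric(1))
  expect_gte(mean(sizes <= 1), 0.9)
})

test_that("selection ties break toward the smallest alpha and refits are exact", {
  set.seed(6)
  n <- 100; p <- 15
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("cg", 1:p)))
  y <- as.numeric(x[, 1:3] %*% rep(0.6, 3) + rnorm(n))
  d <- raw_design(x, y)
  cv <- cross_validate(d, alpha_grid = c(0.3, 0.8), n_folds = 5, seed = 2,
                       nlambda = 40)
  # force an exact tie in CV MSE between the two alphas
  cv$summary$cvm_1se <- c(0.5, 0.5)
  model <- select_and_fit(d, cv)
  expect_equal(model$alpha, 0.3)

  # cold-start fit at the selected lambda reproduces the path solution
  single <- enet_path(x, y, rep(1, p), alpha = model$alpha,
                      lambda = model$lambda)
  full <- enet_path(x, y, rep(1, p), alpha = model$alpha, nlambda = 40)
  idx <- which.min(abs(full$lambda - model$lambda))
  expect_lt(max(abs(single$beta[, 1] - full$beta[, idx])), 1e-8)
  w <- setNames(rep(0, p), colnames(x))
  w[model$weights$probe_id] <- model$weights$weight
  expect_equal(unname(w[rownames(full$beta)]), unname(full$beta[, idx]),
               tolerance = 1e-12)
})

test_that("model artifacts round-trip bit-exactly and reject bad schemas", {
  set.seed(7)
  cfg <- small_config(missing_rate = 0)
  co <- generate_cohort(cfg)
  pheno <- dplyr::inner_join(
    co$pheno, derive_g(generate_test_battery(co$truth$g_true, cfg))$scores,
    by = "sample_id")
  model <- train_methylcog(co$beta, pheno,
                           co$annotation$probe_id[co$annotation$candidate],
                           alpha_grid = c(0.5, 1), n_folds = 5)
  attr(model, "cv") <- NULL
  path <- tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back, model)
  expect_identical(back$weights$weight, model$weights$weight)

  txt <- readLines(path)
  bad <- sub('"alpha":([0-9.]+)', '"alpha":"zero point five"', paste(txt, collapse = ""))
  f1 <- tempfile(fileext = ".json"); writeLines(bad, f1)
  expect_error(read_model(f1), "alpha")

  legacy <- sub('"schema_version":"1.0"', '"schema_version":"0.9"',
                paste(txt, collapse = ""))
  f2 <- tempfile(fileext = ".json"); writeLines(legacy, f2)
  expect_error(read_model(f2), "unsupported")

  f3 <- tempfile(fileext = ".json"); writeLines("{not json", f3)
  expect_error(read_model(f3), "malformed")
})
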