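#' Build the training design matrix
#'
#' Assembles the penalized CpG block and the unpenalized covariate block.
#' Candidate CpG columns are standardized with training means and SDs
#' (mu_j, sigma_j, stored for portable scoring); candidate probes not measured
#' in the cohort enter as all-zero standardized columns. Cell-type fractions
#' are z-scored with one reference cell type omitted; sex and batch are
#' dummy-coded with the reference level dropped. Subjects missing more than
#' `max_missing` of the measured candidate pool are excluded.
#'
#' @param beta A QC'd `beta_matrix` (no missing cells expected; any remaining
#'   `NA`s count toward subject missingness and are zeroed after
#'   standardization).
#' @param pheno Phenotype data frame with `sample_id`, a `g` outcome column,
#'   cell fraction columns (`cell_*`), `sex` and `batch`.
#' @param candidate_probes Character vector: the candidate CpG allowlist.
#' @param outcome Name of the outcome column, default `"g"`.
#' @param reference_cell Cell column treated as the compositional reference
#'   and omitted, default `"cell_cd8t"`.
#' @param max_missing Maximum tolerated fraction of missing candidate-pool
#'   values per subject, default 0.10.
#' @return An object of class `design_matrix`: `x`, `y`, `info` (per-column
#'   `column`, `kind`, `penalty_factor`), `cpg_scaling` (tibble `probe_id`,
#'   `mu`, `sigma`, `measured`), `sample_ids`, `excluded`.
#' @export
build_design <- function(beta, pheno, candidate_probes, outcome = "g",
                         reference_cell = "cell_cd8t", max_missing = 0.10) {
  beta <- as_beta_matrix(beta)
  if (!outcome %in% names(pheno)) {
    abort(sprintf("outcome column '%s' not found in pheno.", outcome))
  }
  common <- intersect(pheno$sample_id, sample_ids(beta))
  pheno <- pheno[match(common, pheno$sample_id), ]
  measured <- intersect(candidate_probes, probe_ids(beta))
  unmeasured <- setdiff(candidate_probes, measured)
  xb <- t(beta$values[measured, common, drop = FALSE])   # samples x probes

  miss_frac <- rowMeans(is.na(xb))
  drop <- miss_frac > max_missing
  excluded <- tibble::tibble(
    sample_id = common[drop],
    reason = sprintf("missing %.1f%% of candidate pool", 100 * miss_frac[drop])
  )
  if (any(drop)) {
    xb <- xb[!drop, , drop = FALSE]
    pheno <- pheno[!drop, , drop = FALSE]
    common <- common[!drop]
  }

  mu <- unname(colMeans(xb, na.rm = TRUE))
  sigma <- unname(apply(xb, 2, sd, na.rm = TRUE))
  zero_var <- sigma == 0 | is.na(sigma)
  if (any(zero_var)) {
    warn(sprintf("%d zero-variance candidate CpG(s) dropped from the design.",
                 sum(zero_var)))
    xb <- xb[, !zero_var, drop = FALSE]
    measured <- measured[!zero_var]
    mu <- mu[!zero_var]
    sigma <- sigma[!zero_var]
  }
  xz <- sweep(sweep(xb, 2, mu), 2, sigma, "/")
  xz[!is.finite(xz)] <- 0
  if (length(unmeasured)) {
    zeros <- matrix(0, nrow(xz), length(unmeasured),
                    dimnames = list(NULL, unmeasured))
    xz <- cbind(xz, zeros)
  }

  ## unpenalized covariates: cells (reference dropped, z-scored), sex, batch
  cov_blocks <- list()
  cell_cols <- grep("^cell_", names(pheno), value = TRUE)
  if (length(cell_cols)) {
    use <- setdiff(cell_cols, reference_cell)
    cov_blocks$cells <- scale(as.matrix(pheno[use]))
  }
  if ("sex" %in% names(pheno)) {
    sx <- factor(pheno$sex)
    if (nlevels(sx) > 1) {
      cov_blocks$sex <- model.matrix(~sx)[, -1, drop = FALSE]
      colnames(cov_blocks$sex) <- paste0("sex_", levels(sx)[-1])
    }
  }
  if ("batch" %in% names(pheno)) {
    bt <- factor(pheno$batch)
    if (nlevels(bt) > 1) {
      cov_blocks$batch <- model.matrix(~bt)[, -1, drop = FALSE]
      colnames(cov_blocks$batch) <- paste0("batch_", levels(bt)[-1])
    }
  }
  xcov <- do.call(cbind, cov_blocks)
  x <- if (is.null(xcov)) xz else cbind(xz, xcov)
  n_cov <- if (is.null(xcov)) 0L else ncol(xcov)

  info <- tibble::tibble(
    column = colnames(x),
    kind = rep(c("cpg", "covariate"), c(ncol(xz), n_cov)),
    penalty_factor = rep(c(1, 0), c(ncol(xz), n_cov))
  )
  structure(
    list(
      x = x,
      y = pheno[[outcome]],
      info = info,
      cpg_scaling = tibble::tibble(
        probe_id = c(measured, unmeasured),
        mu = c(mu, rep(0, length(unmeasured))),
        sigma = c(sigma, rep(NA_real_, length(unmeasured))),
        measured = rep(c(TRUE, FALSE), c(length(measured), length(unmeasured)))
      ),
      sample_ids = common,
      excluded = excluded
    ),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d subjects x %d columns (%d CpG, %d covariate)\n",
              nrow(x$x), ncol(x$x), sum(x$info$kind == "cpg"),
              sum(x$info$kind == "covariate")))
  invisible(x)
}

#' Cross-validate the elastic net over an alpha grid
#'
#' One fixed, seeded fold assignment is drawn once and reused for every alpha.
#' For each alpha the lambda path is computed on the full design, every fold
#' model is fit along that path, and held-out MSE is summarized as a mean and
#' a standard error (SD of fold MSEs / sqrt(n_folds)). Per alpha, `lambda_1se`
#' is the largest lambda whose mean MSE is within one standard error of the
#' path minimum.
#'
#' @param design A `design_matrix`.
#' @param alpha_grid Alphas to search, default `seq(0, 1, 0.1)`.
#' @param n_folds Number of CV folds, default 10.
#' @param seed Seed for the fold assignment (default 20251014).
#' @inheritParams enet_path
#' @return An object of class `enet_cv`: `path` (tibble alpha/lambda/cvm/cvse),
#'   `summary` (per-alpha lambda_1se, its CV MSE, nonzero count),
#'   `fold_assignment`, `seed`, `alpha_grid`.
#' @export
cross_validate <- function(design, alpha_grid = seq(0, 1, by = 0.1),
                           n_folds = 10, seed = .default_fold_seed,
                           nlambda = 100, lambda_min_ratio = 1e-4,
                           tol = 1e-7, maxit = 1e5) {
  if (n_folds < 2) abort("n_folds must be at least 2.")
  x <- design$x
  y <- design$y
  w <- design$info$penalty_factor
  n <- nrow(x)
  set.seed(seed)
  folds <- sample(rep(seq_len(n_folds), length.out = n))
  if (min(table(folds)) < 2) abort("a fold has fewer than 2 subjects.")

  path_rows <- list()
  summ_rows <- list()
  for (a in alpha_grid) {
    full <- enet_path(x, y, w, alpha = a, nlambda = nlambda,
                      lambda_min_ratio = lambda_min_ratio,
                      tol = tol, maxit = maxit)
    lam <- full$lambda
    mse_fold <- matrix(NA_real_, n_folds, length(lam))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- enet_path(x[tr, , drop = FALSE], y[tr], w, alpha = a,
                       lambda = lam, tol = tol, maxit = maxit)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      mse_fold[f, ] <- colMeans((y[!tr] - pred)^2)
    }
    cvm <- colMeans(mse_fold)
    cvse <- apply(mse_fold, 2, sd) / sqrt(n_folds)
    i_min <- which.min(cvm)
    # largest lambda within one SE of the minimum (path is decreasing)
    i_1se <- which(cvm <= cvm[i_min] + cvse[i_min])[1]
    path_rows[[length(path_rows) + 1]] <- tibble::tibble(
      alpha = a, lambda = lam, cvm = cvm, cvse = cvse,
      nzero = as.integer(full$df)
    )
    summ_rows[[length(summ_rows) + 1]] <- tibble::tibble(
      alpha = a, lambda_min = lam[i_min], cvm_min = cvm[i_min],
      lambda_1se = lam[i_1se], cvm_1se = cvm[i_1se],
      nzero_1se = as.integer(full$df[i_1se])
    )
  }
  structure(
    list(path = dplyr::bind_rows(path_rows),
         summary = dplyr::bind_rows(summ_rows),
         fold_assignment = setNames(folds, design$sample_ids),
         seed = seed, alpha_grid = alpha_grid,
         settings = list(nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                         tol = tol, maxit = maxit)),
    class = "enet_cv"
  )
}

#' Apply the one-standard-error rule to a CV curve
#'
#' Given mean CV errors and their standard errors over a decreasing lambda
#' path, returns the index of the largest lambda whose mean error is within
#' one standard error of the path minimum.
#'
#' @param cvm Mean CV errors along the (decreasing) path.
#' @param cvse Standard errors of `cvm`.
#' @return Integer index of the 1-SE lambda.
#' @examples
#' one_se_index(c(1.00, 0.90, 0.85, 0.88), c(0.06, 0.05, 0.05, 0.05))  # 2
#' @export
one_se_index <- function(cvm, cvse) {
  i_min <- which.min(cvm)
  which(cvm <= cvm[i_min] + cvse[i_min])[1]
}

#' @export
print.enet_cv <- function(x, ...) {
  best <- x$summary[which.min(x$summary$cvm_1se), ]
  cat(sprintf("<enet_cv> %d alphas x %d-fold CV (fold seed %d)\n",
              length(x$alpha_grid), max(x$fold_assignment), x$seed))
  cat(sprintf("  best: alpha = %.2f, lambda_1se = %.4g, CV MSE = %.4f, %d CpGs\n",
              best$alpha, best$lambda_1se, best$cvm_1se, best$nzero_1se))
  invisible(x)
}

#' @export
tidy.enet_cv <- function(x, ...) x$path

#' @export
glance.enet_cv <- function(x, ...) {
  best <- x$summary[which.min(x$summary$cvm_1se), ]
  tibble::tibble(alpha = best$alpha, lambda_1se = best$lambda_1se,
                 cv_mse = best$cvm_1se, n_nonzero = best$nzero_1se,
                 seed = x$seed)
}

#' @export
autoplot.enet_cv <- function(object, ...) {
  df <- object$path
  sel <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(log(.data$lambda), .data$cvm,
                                   colour = factor(.data$alpha))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::inner_join(
      df, dplyr::select(sel, "alpha", lambda = "lambda_1se"),
      by = c("alpha", "lambda")), size = 2) +
    ggplot2::labs(x = expression(log(lambda)), y = "CV mean squared error",
                  colour = expression(alpha),
                  title = "Cross-validation surface (points: per-alpha 1-SE choices)") +
    ggplot2::theme_minimal()
}

#' Select the tuning pair and refit the final score model
#'
#' Among the per-alpha `(alpha, lambda_1se)` candidates, picks the pair with
#' the smallest CV MSE (ties broken toward the smallest alpha), refits on the
#' full training design at that pair, and packages the scoring artifact:
#' nonzero CpG weights, intercept, covariate coefficients (stored but never
#' applied at scoring time), per-probe training standardization parameters,
#' and the training mean/SD of the CpG-only raw score.
#'
#' @param design The training `design_matrix`.
#' @param cv An `enet_cv` from [cross_validate()] on the same design.
#' @return An object of class `score_model`.
#' @export
select_and_fit <- function(design, cv) {
  s <- cv$summary
  best <- s[order(s$cvm_1se, s$alpha), ][1, ]
  full <- enet_path(design, alpha = best$alpha,
                    nlambda = cv$settings$nlambda,
                    lambda_min_ratio = cv$settings$lambda_min_ratio,
                    tol = cv$settings$tol, maxit = cv$settings$maxit)
  l_idx <- which.min(abs(full$lambda - best$lambda_1se))
  b <- full$beta[, l_idx]
  is_cpg <- design$info$kind == "cpg"
  cpg_w <- b[is_cpg]
  nz <- cpg_w != 0
  if (!any(nz)) {
    abort(paste0("the selected model keeps no CpGs; the candidate panel may ",
                 "carry no signal at this sample size - review effect sizes ",
                 "or configuration."))
  }
  weights <- tibble::tibble(probe_id = names(cpg_w)[nz],
                            weight = unname(cpg_w[nz]))
  raw <- as.numeric(design$x[, is_cpg, drop = FALSE][, nz, drop = FALSE] %*%
                      cpg_w[nz])
  structure(
    list(
      alpha = best$alpha,
      lambda = best$lambda_1se,
      intercept = full$intercept[l_idx],
      weights = weights,
      scaling = design$cpg_scaling,
      raw_score = list(mean = mean(raw), sd = sd(raw)),
      covariates = tibble::tibble(
        term = design$info$column[!is_cpg],
        estimate = unname(b[!is_cpg])
      ),
      cv_mse = best$cvm_1se,
      folds = list(seed = cv$seed,
                   assignment = as.integer(cv$fold_assignment)),
      meta = list(schema_version = "1.0",
                  package = as.character(packageVersion("methylcog")),
                  n_train = nrow(design$x),
                  alpha_grid = cv$alpha_grid,
                  n_folds = max(cv$fold_assignment))
    ),
    class = "score_model"
  )
}

#' Train a methylation proxy score for g in one call
#'
#' Convenience wrapper: [build_design()] then [cross_validate()] then
#' [select_and_fit()].
#'
#' @inheritParams build_design
#' @inheritParams cross_validate
#' @return A `score_model`.
#' @export
train_methylcog <- function(beta, pheno, candidate_probes, outcome = "g",
                            alpha_grid = seq(0, 1, by = 0.1), n_folds = 10,
                            seed = .default_fold_seed, ...) {
  design <- build_design(beta, pheno, candidate_probes, outcome = outcome)
  cv <- cross_validate(design, alpha_grid = alpha_grid, n_folds = n_folds,
                       seed = seed, ...)
  model <- select_and_fit(design, cv)
  attr(model, "cv") <- cv
  model
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model> %d CpG weights (alpha = %.2f, lambda = %.4g, CV MSE = %.3f)\n",
              nrow(x$weights), x$alpha, x$lambda, x$cv_mse))
  cat(sprintf("  trained on n = %d, fold seed %d, schema %s\n",
              x$meta$n_train, x$folds$seed, x$meta$schema_version))
  invisible(x)
}

#' @export
tidy.score_model <- function(x, ...) {
  dplyr::arrange(x$weights, dplyr::desc(abs(.data$weight)))
}

#' @export
glance.score_model <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, lambda = x$lambda,
                 n_cpgs = nrow(x$weights), cv_mse = x$cv_mse,
                 n_train = x$meta$n_train, fold_seed = x$folds$seed)
}
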