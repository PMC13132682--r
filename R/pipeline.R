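#' Serialize / deserialize a score model as versioned JSON
#'
#' The artifact stores the tuning pair, intercept, nonzero CpG weights,
#' per-probe training standardization parameters, raw-score scaling, covariate
#' coefficients, fold assignment and metadata. Numbers are written with 17
#' significant digits so a write/read round trip reproduces every field
#' bit-exactly. Unknown schema versions and malformed fields are explicit
#' errors, never silent coercions.
#'
#' @param model A `score_model`.
#' @param path Output JSON path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the `score_model`.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "score_model")) abort("`model` must be a score_model.")
  payload <- list(
    schema_version = model$meta$schema_version,
    alpha = model$alpha,
    lambda = model$lambda,
    intercept = model$intercept,
    weights = model$weights,
    scaling = model$scaling,
    raw_score = model$raw_score,
    covariates = model$covariates,
    cv_mse = model$cv_mse,
    folds = model$folds,
    meta = model$meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort(paste0("malformed model JSON: ", conditionMessage(e)))
  )
  ver <- obj$schema_version
  if (is.null(ver)) abort("model JSON lacks a schema_version field.")
  if (!identical(as.character(ver), "1.0")) {
    abort(sprintf("unsupported model schema version '%s' (supported: 1.0).", ver))
  }
  for (f in c("alpha", "lambda", "intercept", "cv_mse")) {
    if (!is.numeric(obj[[f]]) || length(obj[[f]]) != 1) {
      abort(sprintf("model field '%s' must be a single number.", f))
    }
  }
  if (!is.numeric(obj$weights$weight)) {
    abort("model field 'weights$weight' must be numeric.")
  }
  structure(
    list(
      alpha = obj$alpha, lambda = obj$lambda, intercept = obj$intercept,
      weights = tibble::as_tibble(obj$weights),
      scaling = tibble::as_tibble(obj$scaling),
      raw_score = obj$raw_score,
      covariates = tibble::as_tibble(obj$covariates),
      cv_mse = obj$cv_mse,
      folds = list(seed = obj$folds$seed,
                   assignment = as.integer(obj$folds$assignment)),
      meta = list(schema_version = as.character(ver),
                  package = obj$meta$package,
                  n_train = obj$meta$n_train,
                  alpha_grid = obj$meta$alpha_grid,
                  n_folds = obj$meta$n_folds)
    ),
    class = "score_model"
  )
}

#' Run the four-stage workflow end to end
#'
#' Simulate (or load) a cohort, QC the methylation matrix, derive g from the
#' battery, split train/test, train the elastic-net score, score the training,
#' test and (optionally) external-platform sets, and run the validation
#' battery. Every artifact is written under `out_dir` and listed in a manifest
#' with its MD5 content hash, the config seed, and a config snapshot; re-runs
#' with the same config reproduce identical hashes.
#'
#' @param config A list. For a synthetic run supply `cohort` (a
#'   [cohort_config()] or arguments for one). Optional entries: `out_dir`
#'   (default `tempfile("methylcog_run")`), `train_fraction` (0.7), `strata`,
#'   `alpha_grid`, `n_folds` (10), `fold_seed` (20251014), `external`
#'   (logical: score the second-platform variant, default `TRUE`),
#'   `p_threshold` (0.01), `z_cut` (3).
#' @return A list of class `methylcog_run`: paths of written artifacts, the
#'   manifest tibble, and the in-memory results (`model`, `metrics`,
#'   `validation`).
#' @export
run_pipeline <- function(config = list()) {
  cfg_cohort <- config$cohort %||% cohort_config()
  if (!inherits(cfg_cohort, "cohort_config")) {
    cfg_cohort <- do.call(cohort_config, cfg_cohort)
  }
  out_dir <- config$out_dir %||% tempfile("methylcog_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  train_fraction <- config$train_fraction %||% 0.7
  strata <- config$strata %||% c("mci", "race", "sex")
  alpha_grid <- config$alpha_grid %||% seq(0, 1, by = 0.1)
  n_folds <- config$n_folds %||% 10
  fold_seed <- config$fold_seed %||% .default_fold_seed
  external <- config$external %||% TRUE

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  ## simulate
  cohort <- stage("simulate", generate_cohort(cfg_cohort))
  battery <- stage("simulate", generate_test_battery(cohort$truth$g_true, cfg_cohort))

  ## qc
  qc <- stage("qc", qc_pipeline(cohort$beta, cohort$annotation,
                                allowlist = cohort$annotation$probe_id[cohort$annotation$candidate],
                                p_threshold = config$p_threshold %||% 0.01,
                                z_cut = config$z_cut %||% 3))

  ## derive g (battery-wide, before splitting)
  gfit <- stage("derive_g", derive_g(impute_tests(battery)))
  pheno <- dplyr::inner_join(cohort$pheno, gfit$scores, by = "sample_id")
  pheno <- pheno[pheno$sample_id %in% sample_ids(qc$beta), ]

  ## split
  idx <- stage("split", stratified_split(pheno, train_fraction, strata,
                                         seed = fold_seed))
  pheno_train <- pheno[idx$train, ]
  pheno_test <- pheno[idx$test, ]
  candidates <- cohort$annotation$probe_id[cohort$annotation$candidate]

  ## train
  sub_beta <- function(ids) {
    keep <- sample_ids(qc$beta) %in% ids
    beta_matrix(qc$beta$values[, keep, drop = FALSE],
                detection_p = subset_detp(qc$beta$detection_p, NULL, keep),
                platform = qc$beta$platform)
  }
  beta_train <- sub_beta(pheno_train$sample_id)
  model <- stage("train", train_methylcog(beta_train, pheno_train, candidates,
                                          alpha_grid = alpha_grid,
                                          n_folds = n_folds, seed = fold_seed))

  ## score train + test
  scores_train <- stage("score", compute_score(beta_train, model))
  beta_test <- sub_beta(pheno_test$sample_id)
  scores_test <- if (nrow(pheno_test) > 0) {
    stage("score", compute_score(beta_test, model))
  } else {
    NULL
  }

  ## external platform variant
  scores_ext <- NULL
  if (isTRUE(external)) {
    plat <- stage("score", split_platforms(cohort$beta, cfg_cohort,
                                           annotation = cohort$annotation))
    qc_ext <- stage("score", qc_pipeline(plat$platform_b, plat$annotation,
                                         allowlist = candidates,
                                         drop_outliers = FALSE))
    scores_ext <- stage("score", compute_score(qc_ext$beta, model))
  }

  ## validate (held-out test set)
  validation <- NULL
  metrics <- NULL
  if (!is.null(scores_test) && nrow(scores_test$scores) >= 3) {
    metrics <- stage("validate", evaluate_score(scores_test, pheno_test))
    vd <- dplyr::inner_join(pheno_test, scores_test$scores, by = "sample_id")
    validation <- stage("validate", list(
      incremental = incremental_r2(vd, "g", c("age", "sex", "education"), "z"),
      discrimination = discrimination_suite(vd, vd$z, screener = "screener"),
      clock = {
        mr <- residualize(vd$z, vd$age)
        cr <- residualize(vd$comparator_clock, vd$age)
        list(resid_cor = partial_correlation(mr, cr),
             methylcog_resid_g = partial_correlation(mr, vd$g))
      }
    ))
  }

  ## artifacts + manifest
  paths <- list(
    pheno = file.path(out_dir, "pheno.tsv"),
    beta = file.path(out_dir, "beta_qc.tsv"),
    model = file.path(out_dir, "model.json"),
    scores_train = file.path(out_dir, "scores_train.tsv"),
    config = file.path(out_dir, "config.json")
  )
  write.table(pheno, paths$pheno, sep = "\t", quote = FALSE, row.names = FALSE)
  write_beta_tsv(qc$beta, paths$beta)
  write_model(model, paths$model)
  write.table(scores_train$scores, paths$scores_train, sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(scores_test)) {
    paths$scores_test <- file.path(out_dir, "scores_test.tsv")
    write.table(scores_test$scores, paths$scores_test, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(scores_ext)) {
    paths$scores_external <- file.path(out_dir, "scores_external.tsv")
    write.table(scores_ext$scores, paths$scores_external, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(metrics)) {
    paths$report <- file.path(out_dir, "report.json")
    report <- list(
      metrics = metrics,
      incremental = glance(validation$incremental),
      discrimination = glance(validation$discrimination),
      clock = validation$clock
    )
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = I(10))
  }
  cfg_snapshot <- cfg_cohort
  class(cfg_snapshot) <- NULL
  jsonlite::write_json(
    list(cohort = cfg_snapshot, train_fraction = train_fraction,
         strata = strata, alpha_grid = alpha_grid, n_folds = n_folds,
         fold_seed = fold_seed),
    paths$config, auto_unbox = TRUE, digits = I(17))

  files <- unlist(paths)
  manifest <- tibble::tibble(
    artifact = names(files),
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    seed = cfg_cohort$seed
  )
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  structure(
    list(out_dir = out_dir, paths = paths, manifest = manifest,
         model = model, metrics = metrics, validation = validation,
         scores = list(train = scores_train, test = scores_test,
                       external = scores_ext),
         gfactor = gfit, qc_report = qc$report),
    class = "methylcog_run"
  )
}

#' @export
print.methylcog_run <- function(x, ...) {
  cat(sprintf("<methylcog_run> %d artifacts in %s\n", nrow(x$manifest), x$out_dir))
  if (!is.null(x$metrics)) {
    cat(sprintf("  held-out: R2 = %.3f, r = %.3f, rho = %.3f (n = %d)\n",
                x$metrics$r2, x$metrics$pearson_r, x$metrics$spearman_rho,
                x$metrics$n))
  }
  cat(sprintf("  model: %d CpGs at alpha = %.2f, lambda = %.4g\n",
              nrow(x$model$weights), x$model$alpha, x$model$lambda))
  invisible(x)
}
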