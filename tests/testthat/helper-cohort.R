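# small cohort configurations used across tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 300, n_probes = 120, n_causal = 10,
         battery_size = 8, n_replicate_loci = 4, seed = 42L,
         causal_effect_sd = 0.15),  # detectable at small test-cohort sizes
    list(...)
  )
  do.call(cohort_config, args)
}

# a bare design_matrix around a raw predictor matrix (all CpG columns)
raw_design <- function(x, y, penalty_factor = rep(1, ncol(x))) {
  structure(
    list(
      x = x, y = y,
      info = tibble::tibble(column = colnames(x),
                            kind = ifelse(penalty_factor > 0, "cpg", "covariate"),
                            penalty_factor = penalty_factor),
      cpg_scaling = tibble::tibble(probe_id = colnames(x)[penalty_factor > 0],
                                   mu = 0, sigma = 1, measured = TRUE),
      sample_ids = sprintf("S%04d", seq_len(nrow(x))),
      excluded = tibble::tibble(sample_id = character(), reason = character())
    ),
    class = "design_matrix"
  )
}

# hand-built one-CpG score model used by scorer tests
toy_score_model <- function(weight = 1, mu = 0.5, sigma = 0.1,
                            raw_mean = 0, raw_sd = 1, probe = "cg1") {
  structure(
    list(
      alpha = 0.5, lambda = 0.1, intercept = 0,
      weights = tibble::tibble(probe_id = probe, weight = weight),
      scaling = tibble::tibble(probe_id = probe, mu = mu, sigma = sigma,
                               measured = TRUE),
      raw_score = list(mean = raw_mean, sd = raw_sd),
      covariates = tibble::tibble(term = character(), estimate = numeric()),
      cv_mse = 1, folds = list(seed = 1L, assignment = 1L),
      meta = list(schema_version = "1.0", package = "test", n_train = 10,
                  alpha_grid = 0.5, n_folds = 2)
    ),
    class = "score_model"
  )
}

# objective value of the weighted elastic net (used to referee solvers)
enet_objective <- function(x, y, b0, b, w, alpha, lambda) {
  n <- nrow(x)
  r <- y - b0 - as.numeric(x %*% b)
  sum(r^2) / (2 * n) + lambda * sum(w * (alpha * abs(b) + (1 - alpha) / 2 * b^2))
}
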