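#' Compute methylation proxy scores from a fitted score model
#'
#' Aligns the cohort's probes to the model's candidate pool, standardizes each
#' probe with the model's training mean and SD (never the target cohort's),
#' zeroes non-finite standardized entries, forms the weighted sum over the
#' model's nonzero CpG weights, and z-scales the raw score by the training
#' raw-score mean/SD. Covariate coefficients are never applied outside the
#' training fit. Samples missing more than `max_missing` of the measured pool
#' are excluded with a reason. Probes in the pool that are absent from the
#' cohort altogether contribute zero (they are unmeasured on this platform and
#' do not count toward per-sample missingness).
#'
#' @param beta A QC'd `beta_matrix` (or TSV-shaped data frame).
#' @param model A `score_model` from [select_and_fit()] or [read_model()].
#' @param max_missing Maximum tolerated fraction of missing (NA) values per
#'   sample across the measured pool, default 0.10.
#' @return An object of class `score_set`: `scores` (tibble `sample_id`,
#'   `raw`, `z`, `n_missing`), `excluded` (tibble with reasons),
#'   `absent_probes` (pool probes not on this platform).
#' @export
compute_score <- function(beta, model, max_missing = 0.10) {
  beta <- as_beta_matrix(beta)
  if (!inherits(model, "score_model")) abort("`model` must be a score_model.")
  pool <- model$scaling$probe_id
  present <- intersect(pool, probe_ids(beta))
  if (length(intersect(model$weights$probe_id, probe_ids(beta))) == 0) {
    abort("none of the model's weighted probes are present in `beta`.")
  }
  xb <- t(beta$values[present, , drop = FALSE])          # samples x probes
  n_missing <- rowSums(is.na(xb))
  miss_frac <- n_missing / length(present)
  drop <- miss_frac > max_missing
  excluded <- tibble::tibble(
    sample_id = rownames(xb)[drop],
    reason = sprintf("missing %.1f%% of measured candidate pool",
                     100 * miss_frac[drop])
  )
  xb <- xb[!drop, , drop = FALSE]
  sc <- model$scaling[match(present, model$scaling$probe_id), ]
  xz <- sweep(sweep(xb, 2, sc$mu), 2, sc$sigma, "/")
  xz[!is.finite(xz)] <- 0
  w <- model$weights
  wvec <- setNames(numeric(ncol(xz)), colnames(xz))
  hit <- intersect(w$probe_id, names(wvec))
  wvec[hit] <- w$weight[match(hit, w$probe_id)]
  raw <- as.numeric(xz %*% wvec)
  z <- (raw - model$raw_score$mean) / model$raw_score$sd
  structure(
    list(
      scores = tibble::tibble(sample_id = rownames(xb), raw = raw, z = z,
                              n_missing = n_missing[!drop]),
      excluded = excluded,
      absent_probes = setdiff(pool, present)
    ),
    class = "score_set"
  )
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> %d samples scored, %d excluded, %d pool probes unmeasured\n",
              nrow(x$scores), nrow(x$excluded), length(x$absent_probes)))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.score_set <- function(x, ...) x$scores

#' Evaluate scores against measured g
#'
#' Primary R-squared is the squared Pearson correlation (the score is
#' z-scaled, not calibrated to the outcome scale); a calibration R-squared
#' (`1 - SS_res/SS_tot`) is reported alongside. RMSE and MAE are computed on
#' the standardized scales; Spearman's rho uses average ranks for ties.
#'
#' @param scores A `score_set`, or a numeric vector of scores.
#' @param g Standardized measured g: a numeric vector aligned with `scores`,
#'   or a data frame with `sample_id` and a `g` column to join on.
#' @return A one-row tibble: `n`, `r2`, `rmse`, `mae`, `pearson_r`,
#'   `spearman_rho`, `r2_calibration`.
#' @export
evaluate_score <- function(scores, g) {
  if (inherits(scores, "score_set")) {
    tab <- scores$scores
    if (is.data.frame(g)) {
      joined <- dplyr::inner_join(tab, g[, c("sample_id", "g")], by = "sample_id")
      s <- joined$z
      gv <- joined$g
    } else {
      s <- tab$z
      gv <- g
    }
  } else {
    s <- as.numeric(scores)
    gv <- if (is.data.frame(g)) g$g else as.numeric(g)
  }
  ok <- is.finite(s) & is.finite(gv)
  s <- s[ok]
  gv <- gv[ok]
  n <- length(s)
  if (n < 3) abort("at least 3 paired observations are required.")
  rmse <- sqrt(mean((s - gv)^2))
  mae <- mean(abs(s - gv))
  if (sd(s) == 0 || sd(gv) == 0) {
    warn("constant input: correlation-based metrics are undefined.")
    return(tibble::tibble(n = n, r2 = NA_real_, rmse = rmse, mae = mae,
                          pearson_r = NA_real_, spearman_rho = NA_real_,
                          r2_calibration = NA_real_))
  }
  r <- cor(s, gv)
  rho <- cor(rank(s), rank(gv))
  tibble::tibble(
    n = n, r2 = r^2, rmse = rmse, mae = mae,
    pearson_r = r, spearman_rho = rho,
    r2_calibration = 1 - sum((gv - s)^2) / sum((gv - mean(gv))^2)
  )
}
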