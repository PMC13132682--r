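#' Probe-level filtering
#'
#' Removes probes flagged as cross-reactive, SNP-proximal, or lacking the
#' standard `cg` identifier prefix; optionally restricts to a candidate
#' allowlist (e.g., an EWAS-derived CpG panel). Probe order is preserved.
#'
#' @param beta A `beta_matrix` (or TSV-shaped data frame).
#' @param annotation Probe annotation with columns `probe_id`,
#'   `is_cross_reactive`, `is_snp_proximal`, `has_cg_prefix`; must cover every
#'   probe in `beta`.
#' @param allowlist Optional character vector of candidate probe IDs; when
#'   supplied the retained set is the intersection of the allowlist and the
#'   QC-pass set.
#' @return A list with the filtered `beta` and a `report` (counts removed per
#'   rule; rule order: non-cg, cross-reactive, SNP-proximal, off-allowlist).
#' @export
filter_probes <- function(beta, annotation, allowlist = NULL) {
  beta <- as_beta_matrix(beta)
  ids <- probe_ids(beta)
  hit <- match(ids, annotation$probe_id)
  if (anyNA(hit)) {
    abort(paste0("unannotated probe(s): ",
                 paste(head(ids[is.na(hit)], 5), collapse = ", ")))
  }
  ann <- annotation[hit, ]
  drop_cg <- !ann$has_cg_prefix
  drop_xr <- !drop_cg & ann$is_cross_reactive
  drop_snp <- !drop_cg & !drop_xr & ann$is_snp_proximal
  keep <- !(drop_cg | drop_xr | drop_snp)
  drop_allow <- rep(FALSE, length(ids))
  if (!is.null(allowlist)) {
    drop_allow <- keep & !(ann$locus_id %in% allowlist | ids %in% allowlist)
    keep <- keep & !drop_allow
  }
  out <- beta_matrix(beta$values[keep, , drop = FALSE],
                     detection_p = subset_detp(beta$detection_p, keep, NULL),
                     platform = beta$platform)
  report <- list(
    probes_in = length(ids),
    probes_out = sum(keep),
    removed = c(non_cg = sum(drop_cg), cross_reactive = sum(drop_xr),
                snp_proximal = sum(drop_snp), off_allowlist = sum(drop_allow))
  )
  list(beta = out, report = report)
}

subset_detp <- function(detp, rows, cols) {
  if (is.null(detp)) return(NULL)
  if (!is.null(rows)) detp <- detp[rows, , drop = FALSE]
  if (!is.null(cols)) detp <- detp[, cols, drop = FALSE]
  detp
}

#' Mask failed detections and impute missing beta values
#'
#' Cells whose detection p-value exceeds `p_threshold` are set missing; all
#' missing cells are then imputed from inter-probe linear structure. Each
#' incomplete probe is regressed (ridge-stabilized) on the `k` other probes
#' most correlated with it, with predictor probes mean-completed first so the
#' scheme works under scattered per-cell missingness; the probe mean is the
#' fallback when too few probes or observed samples are available. Probes
#' missing in every sample are dropped. Imputed values are clipped to
#' `[0, 1]`; the output has no missing cells. Deterministic (single pass over
#' probes; predictors always use the mean-completed matrix).
#'
#' @param beta A `beta_matrix`.
#' @param p_threshold Detection p-value threshold, default 0.01.
#' @param k Number of predictor probes per imputation model.
#' @param ridge Ridge factor, as a fraction of the mean predictor
#'   sum-of-squares, stabilizing each small regression.
#' @return A list with the completed `beta` and a `report` (cells masked,
#'   cells imputed, probes dropped as all-missing).
#' @export
mask_and_impute <- function(beta, p_threshold = 0.01, k = 10, ridge = 1e-3) {
  beta <- as_beta_matrix(beta)
  vals <- beta$values
  masked <- 0L
  if (!is.null(beta$detection_p)) {
    bad <- beta$detection_p > p_threshold & !is.na(vals)
    masked <- sum(bad)
    vals[bad] <- NA_real_
  }
  all_missing <- rowSums(!is.na(vals)) == 0
  dropped <- rownames(vals)[all_missing]
  vals <- vals[!all_missing, , drop = FALSE]
  n_impute <- sum(is.na(vals))
  if (n_impute > 0) {
    mu <- rowMeans(vals, na.rm = TRUE)
    filled <- vals
    na_idx <- which(is.na(vals))
    filled[na_idx] <- mu[((na_idx - 1) %% nrow(vals)) + 1]
    x_all <- t(filled)                               # samples x probes
    cmat <- suppressWarnings(cor(x_all))
    cmat[!is.finite(cmat)] <- 0
    diag(cmat) <- 0
    k_use <- min(k, nrow(vals) - 1)
    for (i in which(rowSums(is.na(vals)) > 0)) {
      obs <- !is.na(vals[i, ])
      if (k_use < 1 || sum(obs) < k_use + 2) next    # probe-mean fallback
      top <- order(abs(cmat[, i]), decreasing = TRUE)[seq_len(k_use)]
      x_obs <- cbind(1, x_all[obs, top, drop = FALSE])
      xtx <- crossprod(x_obs)
      pen <- diag(c(0, rep(ridge * mean(diag(xtx)[-1]), k_use)))
      coefs <- solve(xtx + pen, crossprod(x_obs, vals[i, obs]))
      pred <- cbind(1, x_all[!obs, top, drop = FALSE]) %*% coefs
      filled[i, !obs] <- pmin(pmax(as.numeric(pred), 0), 1)
    }
    vals <- filled
  }
  detp <- beta$detection_p
  if (!is.null(detp)) detp <- detp[rownames(vals), , drop = FALSE]
  list(
    beta = beta_matrix(vals, detection_p = detp, platform = beta$platform),
    report = list(cells_masked = masked, cells_imputed = n_impute,
                  probes_dropped_all_missing = dropped)
  )
}

#' Collapse replicate probes to one row per locus
#'
#' Probes sharing a `locus_id` are replaced by their per-sample arithmetic
#' mean, named by the locus. Must run after imputation: replicate rows with
#' missing cells are a precondition error.
#'
#' @param beta A `beta_matrix` with no missing cells among replicated loci.
#' @param annotation Probe annotation with `probe_id` and `locus_id`.
#' @return A `beta_matrix` with one row per locus, original order of first
#'   occurrence preserved.
#' @export
collapse_replicates <- function(beta, annotation) {
  beta <- as_beta_matrix(beta)
  ids <- probe_ids(beta)
  locus <- annotation$locus_id[match(ids, annotation$probe_id)]
  if (anyNA(locus)) abort("every probe needs an annotation row with a locus_id.")
  dup_loci <- unique(locus[duplicated(locus)])
  if (length(dup_loci) == 0) return(beta)
  rep_rows <- locus %in% dup_loci
  if (anyNA(beta$values[rep_rows, ])) {
    abort("replicate rows contain missing cells; run mask_and_impute() first.")
  }
  sums <- rowsum(beta$values, group = locus, reorder = FALSE)
  counts <- as.vector(table(factor(locus, levels = rownames(sums))))
  vals <- sums / counts
  detp <- beta$detection_p
  if (!is.null(detp)) {
    detp <- rowsum(detp, group = locus, reorder = FALSE) / counts
  }
  beta_matrix(vals, detection_p = detp, platform = beta$platform)
}

#' Flag principal-component outlier samples
#'
#' Runs a sample-wise PCA of the sample-by-CpG M-value matrix (columns, i.e.
#' probes, centered; not scaled), z-scores the PC1 and PC2 scores, and flags
#' samples exceeding `z_cut` in absolute value on either component. Flags are
#' invariant to the arbitrary sign of each PC.
#'
#' @param m Numeric probes-by-samples M-value matrix (e.g. from
#'   [beta_to_m()]), or a `beta_matrix` whose values are transformed first.
#' @param z_cut Threshold in SD units, default 3.
#' @return A tibble with `sample_id`, `z_pc1`, `z_pc2`, `flagged`.
#' @export
flag_pc_outliers <- function(m, z_cut = 3) {
  if (inherits(m, "beta_matrix")) m <- beta_to_m(m)
  if (ncol(m) < 3) abort("at least 3 samples are required for PC outlier QC.")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE, rank. = 2)
  z <- scale(pc$x[, 1:2, drop = FALSE])
  tibble::tibble(
    sample_id = colnames(m),
    z_pc1 = as.numeric(z[, 1]),
    z_pc2 = as.numeric(if (ncol(z) > 1) z[, 2] else 0),
    flagged = abs(.data$z_pc1) > z_cut | abs(.data$z_pc2) > z_cut
  )
}

#' Full methylation QC pipeline
#'
#' Fixed order: optional metadata-based sample exclusion (bisulfite
#' conversion, sex concordance), probe filtering, detection-p masking +
#' imputation, replicate collapsing, then M-value PC outlier flagging (QC
#' only; scoring always stays on the beta scale).
#'
#' @inheritParams filter_probes
#' @inheritParams mask_and_impute
#' @inheritParams flag_pc_outliers
#' @param sample_qc Optional data frame with `sample_id` and a logical `pass`
#'   column; failing samples are dropped before probe QC.
#' @param drop_outliers Drop PC-flagged samples from the returned matrix.
#' @return A list: `beta` (analysis-ready), `report` (per-stage counts),
#'   `outliers` (the [flag_pc_outliers()] tibble).
#' @export
qc_pipeline <- function(beta, annotation, allowlist = NULL, sample_qc = NULL,
                        p_threshold = 0.01, z_cut = 3, drop_outliers = TRUE) {
  beta <- as_beta_matrix(beta)
  report <- list()
  if (!is.null(sample_qc)) {
    bad <- sample_qc$sample_id[!sample_qc$pass]
    keep <- !(sample_ids(beta) %in% bad)
    report$samples_failed_metadata_qc <- sum(!keep)
    beta <- beta_matrix(beta$values[, keep, drop = FALSE],
                        detection_p = subset_detp(beta$detection_p, NULL, keep),
                        platform = beta$platform)
  }
  f <- filter_probes(beta, annotation, allowlist = allowlist)
  report$probe_filter <- f$report
  mi <- mask_and_impute(f$beta, p_threshold = p_threshold)
  report$impute <- mi$report
  collapsed <- collapse_replicates(mi$beta, annotation)
  out <- flag_pc_outliers(beta_to_m(collapsed), z_cut = z_cut)
  report$pc_outliers <- out$sample_id[out$flagged]
  if (drop_outliers && any(out$flagged)) {
    keep <- !out$flagged
    collapsed <- beta_matrix(collapsed$values[, keep, drop = FALSE],
                             detection_p = subset_detp(collapsed$detection_p, NULL, keep),
                             platform = collapsed$platform)
  }
  list(beta = collapsed, report = report, outliers = out)
}
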