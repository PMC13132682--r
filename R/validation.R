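#' Group-difference tests for a score
#'
#' Dispatches on the grouping variable: Welch two-sample t-test for binary
#' groupings, Welch's ANOVA for three or more levels, Pearson correlation
#' (t-based p) for continuous variables. Two-tailed p values at alpha = 0.05.
#'
#' @param score Numeric vector.
#' @param grouping Factor/character/logical (categorical) or numeric
#'   (continuous) vector of the same length.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `significant`.
#' @export
group_tests <- function(score, grouping) {
  ok <- is.finite(score) & !is.na(grouping)
  score <- score[ok]
  grouping <- grouping[ok]
  if (is.numeric(grouping) && length(unique(grouping)) > 5) {
    ct <- stats::cor.test(score, grouping)
    out <- tibble::tibble(test = "pearson", statistic = unname(ct$statistic),
                          df = unname(ct$parameter), p_value = ct$p.value,
                          estimate = unname(ct$estimate))
  } else {
    grouping <- factor(grouping)
    grouping <- droplevels(grouping)
    sizes <- table(grouping)
    if (any(sizes < 2)) {
      abort(sprintf("group '%s' has fewer than 2 members.",
                    names(sizes)[sizes < 2][1]))
    }
    if (nlevels(grouping) == 2) {
      tt <- stats::t.test(score ~ grouping)        # Welch by default
      out <- tibble::tibble(test = "welch_t", statistic = unname(tt$statistic),
                            df = unname(tt$parameter), p_value = tt$p.value,
                            estimate = unname(diff(rev(tt$estimate))))
    } else {
      ft <- stats::oneway.test(score ~ grouping, var.equal = FALSE)
      out <- tibble::tibble(test = "welch_anova", statistic = unname(ft$statistic),
                            df = unname(ft$parameter[2]), p_value = ft$p.value,
                            estimate = NA_real_)
    }
  }
  dplyr::mutate(out, significant = .data$p_value < 0.05)
}

#' Incremental validity of an added predictor
#'
#' Fits OLS models of `outcome` on the base covariates and on base + added;
#' reports both R-squareds, their difference, the semi-partial R-squared of
#' each added predictor (full R-squared minus the R-squared of the full model
#' without that predictor), the F-test of the increment, and full-model
#' coefficients with t-based 95% CIs.
#'
#' @param data Data frame holding all columns.
#' @param outcome Name of the outcome column.
#' @param base Character vector of base covariate columns.
#' @param added Character vector (usually length 1) of added predictors.
#' @return An object of class `incremental_fit`.
#' @export
incremental_r2 <- function(data, outcome, base, added) {
  cols <- c(outcome, base, added)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  df <- data[stats::complete.cases(data[cols]), cols]
  n <- nrow(df)
  if (n <= length(base) + length(added) + 2) abort("too few complete observations.")
  form <- function(rhs) stats::reformulate(rhs, response = outcome)
  mm <- model.matrix(form(c(base, added)), df)
  if (qr(mm)$rank < ncol(mm)) {
    abort("exact collinearity among predictors; check base and added columns.")
  }
  fit_base <- lm(form(base), data = df)
  fit_full <- lm(form(c(base, added)), data = df)
  r2_base <- summary(fit_base)$r.squared
  r2_full <- summary(fit_full)$r.squared
  sr2 <- vapply(added, function(a) {
    others <- setdiff(c(base, added), a)
    r2_full - summary(lm(form(others), data = df))$r.squared
  }, numeric(1))
  an <- stats::anova(fit_base, fit_full)
  cf <- summary(fit_full)$coefficients
  ci <- stats::confint(fit_full)
  coefs <- tibble::tibble(
    term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
    statistic = cf[, 3], p_value = cf[, 4],
    conf_low = ci[, 1], conf_high = ci[, 2]
  )
  structure(
    list(r2_base = r2_base, r2_full = r2_full, delta_r2 = r2_full - r2_base,
         sr2 = sr2, f_statistic = an$F[2], p_delta = an$`Pr(>F)`[2],
         coefficients = coefs, n = n, outcome = outcome,
         base = base, added = added),
    class = "incremental_fit"
  )
}

#' @export
print.incremental_fit <- function(x, ...) {
  cat(sprintf("<incremental_fit> %s ~ base (R2 = %.3f) + %s (R2 = %.3f)\n",
              x$outcome, x$r2_base, paste(x$added, collapse = " + "), x$r2_full))
  cat(sprintf("  delta R2 = %.4f (F = %.2f, p = %.3g); sr2: %s\n",
              x$delta_r2, x$f_statistic, x$p_delta,
              paste(sprintf("%s = %.4f", names(x$sr2), x$sr2), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.incremental_fit <- function(x, ...) x$coefficients

#' @export
glance.incremental_fit <- function(x, ...) {
  tibble::tibble(r2_base = x$r2_base, r2_full = x$r2_full,
                 delta_r2 = x$delta_r2, sr2 = sum(x$sr2),
                 f_statistic = x$f_statistic, p_value = x$p_delta, n = x$n)
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance: the probability that a random positive outranks a
#' random negative, with half credit for ties, computed from average ranks.
#'
#' @param labels Binary vector (0/1, logical, or two-level factor).
#' @param scores Numeric classifier scores.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) abort("both classes must be present.")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) abort("labels must be binary (0/1).")
  as.integer(labels)
}

# placement values ("structural components"): for each positive, the fraction
# of negatives it beats (V10); for each negative, the fraction of positives it
# is beaten by (V01); ties get half credit.
delong_placements <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  m <- length(pos)
  n <- length(neg)
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n,
                numeric(1))
  v01 <- vapply(neg, function(x) (sum(pos > x) + 0.5 * sum(pos == x)) / m,
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two scores measured on the same samples,
#' using the placement-value covariance estimate and a two-sided z test on the
#' AUC difference. When the variance of the difference is zero (e.g. identical
#' score vectors) the difference is reported as 0 with p = 1.
#'
#' @param labels Binary outcome vector.
#' @param scores_a,scores_b Paired numeric score vectors.
#' @return A one-row tibble: `auc_a`, `auc_b`, `delta_auc`, `z`, `p_value`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) abort("both classes must be present.")
  pa <- delong_placements(y, scores_a)
  pb <- delong_placements(y, scores_b)
  m <- sum(y == 1)
  n <- sum(y == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  s <- s10 / m + s01 / n
  v <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  d <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    inform("zero variance of the AUC difference; reporting p = 1 by convention.")
    return(tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta_auc = 0,
                          z = 0, p_value = 1))
  }
  z <- d / sqrt(v)
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta_auc = d, z = z,
                 p_value = 2 * pnorm(-abs(z)))
}

#' Likelihood-ratio test for nested models
#'
#' `Delta chi-squared = 2 (LL_full - LL_reduced)` with degrees of freedom equal
#' to the parameter difference. Fits must be on the same observations with the
#' reduced model nested in the full one.
#'
#' @param fit_reduced,fit_full Fitted models with `logLik` methods (e.g.
#'   `glm`).
#' @return A one-row tibble: `chisq`, `df`, `p_value`.
#' @export
nested_lr_test <- function(fit_reduced, fit_full) {
  ll_r <- logLik(fit_reduced)
  ll_f <- logLik(fit_full)
  if (stats::nobs(fit_reduced) != stats::nobs(fit_full)) {
    abort("models were fit on different numbers of observations.")
  }
  chisq <- 2 * (as.numeric(ll_f) - as.numeric(ll_r))
  if (chisq < -1e-6) {
    abort("full model has lower likelihood than the reduced model; check convergence and nesting.")
  }
  chisq <- max(chisq, 0)
  df <- attr(ll_f, "df") - attr(ll_r, "df")
  p <- if (df <= 0) 1 else pchisq(chisq, df, lower.tail = FALSE)
  tibble::tibble(chisq = chisq, df = df, p_value = p)
}

#' MCI discrimination suite
#'
#' Fits the nested logistic-regression ladder used to judge the clinical value
#' of a score: a demographics-only base model (age, sex, education), base +
#' score, and -- when a screener or extra predictor sets are supplied -- base +
#' screener (+ score) and base + extras (+ score). The score is standardized
#' before fitting so its odds ratio is per SD. Each nested pair is compared by
#' AUC difference (DeLong, on fitted probabilities) and a likelihood-ratio
#' test.
#'
#' @param pheno Data frame with the diagnosis and covariate columns.
#' @param score Numeric vector aligned with `pheno` rows, or the name of a
#'   column in `pheno`.
#' @param diagnosis Name of the binary diagnosis column, default `"mci"`.
#' @param covariates Base covariates, default age, sex, education.
#' @param screener Optional name of a cognitive screener column.
#' @param extra Optional named list of character vectors: extra predictor sets
#'   (e.g. biomarker or MRI columns), each fit as base + set and base + set +
#'   score.
#' @return An object of class `discrimination_fit`: `models` (per-model AUC,
#'   log-likelihood, df), `score_effects` (per-SD OR with 95% CI per model
#'   containing the score), `comparisons` (DeLong delta AUC and LR chi-squared
#'   per nested pair), and the fitted probabilities.
#' @export
discrimination_suite <- function(pheno, score, diagnosis = "mci",
                                 covariates = c("age", "sex", "education"),
                                 screener = NULL, extra = NULL) {
  if (is.character(score) && length(score) == 1) score <- pheno[[score]]
  df <- as.data.frame(pheno)
  df$.score <- as.numeric(scale(score))
  keep <- stats::complete.cases(df[c(diagnosis, covariates, ".score", screener)])
  df <- df[keep, , drop = FALSE]
  y <- as_binary_labels(df[[diagnosis]])
  df$.y <- y

  specs <- list(base = covariates, base_score = c(covariates, ".score"))
  if (!is.null(screener)) {
    specs$base_screener <- c(covariates, screener)
    specs$base_screener_score <- c(covariates, screener, ".score")
  }
  for (nm in names(extra)) {
    specs[[paste0("base_", nm)]] <- c(covariates, extra[[nm]])
    specs[[paste0("base_", nm, "_score")]] <- c(covariates, extra[[nm]], ".score")
  }

  fits <- lapply(specs, function(rhs) {
    f <- glm(stats::reformulate(rhs, response = ".y"), data = df,
             family = binomial())
    if (!f$converged) abort("logistic fit did not converge (possible separation).")
    f
  })
  probs <- lapply(fits, function(f) unname(stats::fitted(f)))

  models <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(model = nm, auc = auc(y, probs[[nm]]),
                   loglik = as.numeric(logLik(f)),
                   df = attr(logLik(f), "df"), n = length(y))
  })
  score_effects <- purrr::imap_dfr(fits, function(f, nm) {
    cf <- summary(f)$coefficients
    if (!".score" %in% rownames(cf)) return(NULL)
    est <- cf[".score", ]
    tibble::tibble(
      model = nm, log_odds = est[1], std_error = est[2], p_value = est[4],
      or = exp(est[1]),
      or_low = exp(est[1] - qnorm(0.975) * est[2]),
      or_high = exp(est[1] + qnorm(0.975) * est[2]),
      pct_odds_change = odds_percent_reduction(exp(est[1]))
    )
  })
  pairs <- Filter(function(p) all(p %in% names(fits)),
                  lapply(names(specs)[endsWith(names(specs), "_score")],
                         function(full) c(sub("_score$", "", full), full)))
  comparisons <- purrr::map_dfr(pairs, function(p) {
    dl <- delong_test(y, probs[[p[2]]], probs[[p[1]]])
    lr <- nested_lr_test(fits[[p[1]]], fits[[p[2]]])
    tibble::tibble(reduced = p[1], full = p[2],
                   auc_reduced = dl$auc_b, auc_full = dl$auc_a,
                   delta_auc = dl$delta_auc, delong_p = dl$p_value,
                   lr_chisq = lr$chisq, lr_df = lr$df, lr_p = lr$p_value)
  })
  structure(
    list(models = models, score_effects = score_effects,
         comparisons = comparisons, fitted_probs = probs, labels = y,
         diagnosis = diagnosis),
    class = "discrimination_fit"
  )
}

#' Express a per-SD odds ratio as a percent change in odds
#'
#' An OR of 0.74 per SD is a 26% reduction in odds; an OR of 1.20 is a 20%
#' increase (returned as -20).
#'
#' @param or Odds ratio(s).
#' @return Percent reduction in odds, `100 * (1 - or)`.
#' @export
odds_percent_reduction <- function(or) 100 * (1 - or)

#' @export
print.discrimination_fit <- function(x, ...) {
  cat(sprintf("<discrimination_fit> %d models on n = %d (%d cases)\n",
              nrow(x$models), length(x$labels), sum(x$labels)))
  print(x$models, n = Inf)
  invisible(x)
}

#' @export
tidy.discrimination_fit <- function(x, ...) x$comparisons

#' @export
glance.discrimination_fit <- function(x, ...) {
  cmp <- x$comparisons[x$comparisons$reduced == "base", ]
  eff <- x$score_effects[x$score_effects$model == "base_score", ]
  tibble::tibble(
    auc_base = cmp$auc_reduced[1], auc_score = cmp$auc_full[1],
    delta_auc = cmp$delta_auc[1], delong_p = cmp$delong_p[1],
    or_per_sd = eff$or[1], or_p = eff$p_value[1], n = length(x$labels)
  )
}

#' @export
autoplot.discrimination_fit <- function(object, models = NULL, ...) {
  nms <- models %||% c("base", "base_score")
  roc_df <- purrr::map_dfr(nms, function(nm) {
    p <- object$fitted_probs[[nm]]
    thr <- c(Inf, sort(unique(p), decreasing = TRUE))
    y <- object$labels
    tibble::tibble(
      model = nm,
      tpr = vapply(thr, function(t) mean(p[y == 1] >= t), numeric(1)),
      fpr = vapply(thr, function(t) mean(p[y == 0] >= t), numeric(1))
    )
  })
  ggplot2::ggplot(roc_df, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "ROC curves for MCI discrimination") +
    ggplot2::theme_minimal()
}

#' Residualize a score on chronological age
#'
#' OLS residuals of `score` on `age` (intercept included): the
#' age-acceleration-style quantity used to compare a cognition proxy with an
#' aging clock on an age-free footing. Residuals are exactly uncorrelated with
#' age.
#'
#' @param score Numeric vector.
#' @param age Numeric vector of ages (non-constant).
#' @return Numeric vector of residuals.
#' @export
residualize <- function(score, age) {
  if (length(score) < 3) abort("at least 3 observations are required.")
  if (sd(age) == 0) abort("age is constant; residualization is undefined.")
  unname(resid(lm(score ~ age)))
}

#' Partial correlation with pairwise-complete handling
#'
#' Correlation of the OLS residuals of `x` and `y` on the covariates, computed
#' on observations complete for the pair and covariates; p from a t
#' distribution with `n - k - 2` df, CI by Fisher z.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame or matrix of adjustment variables (may be
#'   empty/NULL, in which case the plain Pearson correlation is returned).
#' @return A one-row tibble: `r`, `conf_low`, `conf_high`, `p_value`, `n`,
#'   `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    cv <- NULL
    ok <- is.finite(x) & is.finite(y)
  } else {
    cv <- as.matrix(as.data.frame(covariates))
    ok <- is.finite(x) & is.finite(y) & stats::complete.cases(cv)
  }
  k <- if (is.null(cv)) 0L else ncol(cv)
  n <- sum(ok)
  if (n < k + 3) abort(sprintf("insufficient complete pairs (n = %d).", n))
  xs <- x[ok]
  ys <- y[ok]
  if (k > 0) {
    mm <- cbind(1, cv[ok, , drop = FALSE])
    xs <- resid(lm.fit(mm, xs))
    ys <- resid(lm.fit(mm, ys))
  }
  r <- cor(xs, ys)
  df <- n - k - 2
  tstat <- r * sqrt(df / (1 - r^2))
  zr <- atanh(r)
  se <- 1 / sqrt(n - k - 3)
  tibble::tibble(
    r = r, conf_low = tanh(zr - qnorm(0.975) * se),
    conf_high = tanh(zr + qnorm(0.975) * se),
    p_value = 2 * pt(-abs(tstat), df), n = n, df = df
  )
}

#' Moderation (interaction) model
#'
#' Fits `outcome ~ focal * moderator + covariates` by OLS and reports the
#' coefficient table with the interaction term flagged.
#'
#' @param data Data frame.
#' @param outcome,focal,moderator Column names.
#' @param covariates Character vector of adjustment columns.
#' @return An object of class `moderation_fit` with a tidy coefficient table;
#'   the interaction row carries `term_type = "interaction"`.
#' @export
moderation_fit <- function(data, outcome, focal, moderator,
                           covariates = c("age", "sex", "education")) {
  cols <- c(outcome, focal, moderator, covariates)
  df <- data[stats::complete.cases(data[cols]), cols]
  if (length(unique(df[[moderator]])) < 2) abort("moderator is constant.")
  form <- stats::as.formula(paste(
    outcome, "~", focal, "*", moderator,
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  ))
  mm <- model.matrix(form, df)
  if (qr(mm)$rank < ncol(mm)) abort("collinear design in moderation model.")
  fit <- lm(form, data = df)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  tab <- tibble::tibble(
    term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
    statistic = cf[, 3], p_value = cf[, 4],
    conf_low = ci[, 1], conf_high = ci[, 2],
    term_type = ifelse(grepl(":", rownames(cf)), "interaction", "main")
  )
  structure(list(coefficients = tab, n = nrow(df), formula = form, fit = fit),
            class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  int <- x$coefficients[x$coefficients$term_type == "interaction", ]
  cat(sprintf("<moderation_fit> n = %d; interaction %s: b = %.3f (p = %.3g)\n",
              x$n, int$term[1], int$estimate[1], int$p_value[1]))
  invisible(x)
}

#' @export
tidy.moderation_fit <- function(x, ...) x$coefficients

#' Bootstrap mediation analysis (product of coefficients)
#'
#' Linear mediator and outcome models: `a` from
#' `mediator ~ treatment + covariates`, `b` from
#' `outcome ~ mediator + treatment + covariates`. ACME = a*b, ADE = the
#' treatment coefficient of the outcome model, total effect = ACME + ADE
#' (which equals the treatment coefficient of
#' `outcome ~ treatment + covariates` exactly for OLS with identical samples).
#' Case-resampling bootstrap percentile CIs and a two-sided bootstrap p for
#' the ACME; proportion mediated = ACME / total effect.
#'
#' @param data Data frame.
#' @param treatment,mediator,outcome Column names (treatment typically a 0/1
#'   group indicator).
#' @param covariates Character vector of adjustment columns (may be empty).
#' @param B Bootstrap iterations (>= 100), default 1000.
#' @param seed Integer seed.
#' @return An object of class `mediation_result`.
#' @export
mediation_bootstrap <- function(data, treatment, mediator, outcome,
                                covariates = character(), B = 1000,
                                seed = 1L) {
  if (B < 100) abort("B must be at least 100.")
  cols <- c(treatment, mediator, outcome, covariates)
  df <- data[stats::complete.cases(data[cols]), cols]
  n <- nrow(df)
  tr <- as.numeric(df[[treatment]])
  md <- as.numeric(df[[mediator]])
  y <- as.numeric(df[[outcome]])
  cv <- if (length(covariates)) {
    model.matrix(stats::reformulate(covariates), df)[, -1, drop = FALSE]
  } else {
    NULL
  }
  est <- function(idx) {
    t_i <- tr[idx]; m_i <- md[idx]; y_i <- y[idx]
    c_i <- if (is.null(cv)) NULL else cv[idx, , drop = FALSE]
    xm <- cbind(1, t_i, c_i)
    a <- lm.fit(xm, m_i)$coefficients[2]
    xo <- cbind(1, m_i, t_i, c_i)
    cf <- lm.fit(xo, y_i)$coefficients
    b <- cf[2]; ade <- cf[3]
    c(acme = unname(a * b), ade = unname(ade),
      total = unname(a * b + ade), a = unname(a), b = unname(b))
  }
  point <- est(seq_len(n))
  # the product-of-coefficients identity: verify total against a direct fit
  total_direct <- lm.fit(cbind(1, tr, cv), y)$coefficients[2]
  set.seed(seed)
  boots <- t(vapply(seq_len(B), function(i) est(sample.int(n, replace = TRUE)),
                    numeric(5)))
  ci <- apply(boots[, c("acme", "ade", "total")], 2, quantile,
              probs = c(0.025, 0.975))
  p_acme <- 2 * min(mean(boots[, "acme"] <= 0), mean(boots[, "acme"] >= 0))
  p_acme <- min(p_acme, 1)
  prop <- if (abs(point["total"]) < 1e-10) {
    warn("total effect is ~0; proportion mediated is undefined.")
    NA_real_
  } else {
    unname(point["acme"] / point["total"])
  }
  structure(
    list(acme = unname(point["acme"]), ade = unname(point["ade"]),
         total = unname(point["total"]),
         total_direct = unname(total_direct),
         prop_mediated = prop,
         ci = list(acme = unname(ci[, "acme"]), ade = unname(ci[, "ade"]),
                   total = unname(ci[, "total"])),
         p_acme = p_acme, paths = point[c("a", "b")],
         boots = boots, B = B, seed = seed, n = n),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> n = %d, B = %d (seed %d)\n", x$n, x$B, x$seed))
  cat(sprintf("  ACME = %.4f [%.4f, %.4f], p = %.3g\n",
              x$acme, x$ci$acme[1], x$ci$acme[2], x$p_acme))
  cat(sprintf("  ADE = %.4f, total = %.4f, proportion mediated = %.3f\n",
              x$ade, x$total, x$prop_mediated))
  invisible(x)
}

#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    term = c("acme", "ade", "total"),
    estimate = c(x$acme, x$ade, x$total),
    conf_low = c(x$ci$acme[1], x$ci$ade[1], x$ci$total[1]),
    conf_high = c(x$ci$acme[2], x$ci$ade[2], x$ci$total[2])
  )
}

#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(acme = x$acme, ade = x$ade, total = x$total,
                 prop_mediated = x$prop_mediated, p_acme = x$p_acme,
                 B = x$B, n = x$n)
}

#' Dual-criterion outlier mask
#'
#' Flags observations with `|z| >= z_cut` (classical z-score) or
#' `|MAD-Z| >= madz_cut`, where `MAD-Z = 0.6745 (x - median) / MAD`. When the
#' MAD is zero that criterion is skipped with a warning and the z criterion
#' alone applies.
#'
#' @param score Numeric vector (n >= 3).
#' @param z_cut Classical z threshold, default 3.
#' @param madz_cut Robust threshold, default 3.5.
#' @return Logical vector, `TRUE` = outlier.
#' @export
outlier_mask <- function(score, z_cut = 3, madz_cut = 3.5) {
  if (length(score) < 3) abort("at least 3 observations are required.")
  z <- abs(score - mean(score)) / sd(score)
  m <- median(score)
  madv <- median(abs(score - m))
  flag <- z >= z_cut
  if (madv == 0) {
    warn("MAD is zero; MAD-Z criterion skipped.")
  } else {
    madz <- abs(0.6745 * (score - m) / madv)
    flag <- flag | madz >= madz_cut
  }
  flag
}
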