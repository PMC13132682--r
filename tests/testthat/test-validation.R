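test_that("group tests dispatch correctly with hand-checked Welch anchors", {
  same <- group_tests(c(1, 2, 3, 1, 2, 3), factor(rep(c("a", "b"), each = 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  tt <- group_tests(c(1, 2, 3, 4, 5, 6), factor(rep(c("a", "b"), each = 3)))
  expect_equal(tt$test, "welch_t")
  expect_equal(tt$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$df, 4, tolerance = 1e-12)

  av <- group_tests(rnorm(30), factor(rep(letters[1:3], 10)))
  expect_equal(av$test, "welch_anova")

  ct <- group_tests(rnorm(30), rnorm(30))
  expect_equal(ct$test, "pearson")

  expect_error(group_tests(1:5, factor(c("a", "a", "a", "a", "b"))), "'b'")
})

test_that("incremental R2: orthogonal limit, identity, and collinearity error", {
  set.seed(1)
  n <- 20000
  base <- rnorm(n)
  added <- rnorm(n)                       # orthogonal to base
  r_target <- 0.3
  y <- 0.5 * base + r_target * scale(added)[, 1] + rnorm(n, 0, sqrt(1 - r_target^2))
  d <- tibble::tibble(y = as.numeric(y), base = base, added = added)
  fit <- incremental_r2(d, "y", "base", "added")
  expect_lt(abs(fit$delta_r2 - r_target^2 / (0.25 + 1)), 0.006)
  expect_equal(unname(fit$sr2["added"]), fit$delta_r2, tolerance = 1e-12)
  expect_gte(fit$delta_r2, 0)
  d$dup <- d$base
  expect_error(incremental_r2(d, "y", c("base", "dup"), "added"), "collinearity")
})

test_that("a pure-noise predictor adds R2 of about 1/(n - k) under the null", {
  set.seed(2)
  n <- 100
  reps <- 1500
  incr <- replicate(reps, {
    d <- tibble::tibble(y = rnorm(n), base = rnorm(n), added = rnorm(n))
    incremental_r2(d, "y", "base", "added")$delta_r2
  })
  # one added predictor after base+intercept: E[increment] ~ 1/(n - 2)
  expect_equal(mean(incr), 1 / (n - 2), tolerance = 0.15)
})

test_that("AUC equals brute-force pair enumeration, with tie handling", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  set.seed(3)
  y <- rbinom(200, 1, 0.35)
  s <- sample(seq(0, 1, 0.05), 200, TRUE)     # many ties
  brute <- {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  }
  expect_equal(auc(y, s), brute, tolerance = 1e-12)
  expect_error(auc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("DeLong: conventions, rank invariance, and bootstrap-consistent variance", {
  set.seed(4)
  y <- rbinom(300, 1, 0.4)
  s <- rnorm(300) + y
  same <- suppressMessages(delong_test(y, s, s))
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_value, 1)

  mono <- suppressMessages(delong_test(y, s, exp(2 * s) + 5))
  expect_equal(mono$delta_auc, 0, tolerance = 1e-12)

  s2 <- rnorm(300) + 0.5 * y
  dl <- delong_test(y, s, s2)
  boots <- replicate(2000, {
    i <- sample.int(300, replace = TRUE)
    if (length(unique(y[i])) < 2) return(NA_real_)
    auc(y[i], s[i]) - auc(y[i], s2[i])
  })
  v_boot <- var(boots, na.rm = TRUE)
  v_delong <- (dl$delta_auc / dl$z)^2
  expect_lt(abs(v_delong - v_boot) / v_boot, 0.15)
  # independent implementation cross-check
  pr <- suppressMessages(pROC::roc.test(
    pROC::roc(y, s, quiet = TRUE, levels = c(0, 1), direction = "<"),
    pROC::roc(y, s2, quiet = TRUE, levels = c(0, 1), direction = "<"),
    method = "delong", paired = TRUE))
  expect_equal(dl$p_value, pr$p.value, tolerance = 1e-9)
})

test_that("likelihood-ratio test: identity, power, and convergence guard", {
  set.seed(5)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + x1))
  f0 <- glm(y ~ x1, family = binomial())
  f1 <- glm(y ~ x1 + x2, family = binomial())
  self <- nested_lr_test(f0, f0)
  expect_equal(self$chisq, 0)
  expect_equal(self$p_value, 1)
  out <- nested_lr_test(f0, f1)
  expect_gte(out$chisq, 0)
  expect_equal(out$df, 1)
  # power: the true linear predictor is detected nearly always
  hits <- replicate(200, {
    x <- rnorm(150)
    yy <- rbinom(150, 1, plogis(1.2 * x))
    r <- glm(yy ~ 1, family = binomial())
    f <- glm(yy ~ x, family = binomial())
    nested_lr_test(r, f)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the discrimination suite reports per-SD ORs and nested comparisons", {
  cfg <- cohort_config(n_subjects = 700, n_probes = 40, n_causal = 4, seed = 23L)
  co <- generate_cohort(cfg)
  ph <- co$pheno
  ph$g <- co$truth$g_true
  score <- co$truth$g_true + rnorm(nrow(ph), 0, 0.8)  # strong g proxy
  fit <- discrimination_suite(ph, score, screener = "screener")
  expect_setequal(fit$models$model,
                  c("base", "base_score", "base_screener", "base_screener_score"))
  expect_true(all(fit$models$auc >= 0 & fit$models$auc <= 1))
  eff <- fit$score_effects[fit$score_effects$model == "base_score", ]
  expect_equal(eff$or, exp(eff$log_odds), tolerance = 1e-12)
  expect_lt(eff$or, 1)                      # protective, as constructed
  cmp <- fit$comparisons[fit$comparisons$reduced == "base", ]
  expect_gt(cmp$auc_full, cmp$auc_reduced)  # the score adds discrimination
  expect_gte(cmp$lr_chisq, 0)

  # a null score leaves the AUC essentially unchanged
  null_fit <- discrimination_suite(ph, rnorm(nrow(ph)))
  ncmp <- null_fit$comparisons
  expect_lt(abs(ncmp$delta_auc), 0.02)

  # OR-to-percent reporting convention
  expect_equal(odds_percent_reduction(0.74), 26, tolerance = 1e-9)
  expect_equal(odds_percent_reduction(0.67), 33, tolerance = 1e-9)
})

test_that("age residualization is exactly age-orthogonal", {
  set.seed(6)
  age <- runif(200, 65, 90)
  r1 <- residualize(2 * age, age)
  expect_lt(max(abs(r1)), 1e-10)
  s <- rnorm(200)
  r2 <- residualize(s, age)
  expect_lt(abs(cor(r2, age)), 1e-10)
  s_orth <- unname(resid(lm(s ~ age))) + mean(s)  # age-orthogonal score
  expect_equal(residualize(s_orth, age), s_orth - mean(s_orth), tolerance = 1e-10)
  expect_error(residualize(s, rep(70, 200)), "constant")
})

test_that("partial correlation removes common causes and degenerates to Pearson", {
  set.seed(7)
  n <- 100000
  z <- rnorm(n)
  x <- z + rnorm(n)
  y <- z + rnorm(n)
  pc <- partial_correlation(x, y, data.frame(z = z))
  expect_lt(abs(pc$r), 0.02)
  expect_equal(pc$df, n - 3)

  plain <- partial_correlation(x[1:500], y[1:500])
  expect_equal(plain$r, cor(x[1:500], y[1:500]), tolerance = 1e-12)

  w <- rnorm(n)                              # independent covariate
  pc2 <- partial_correlation(x, y, data.frame(w = w))
  expect_equal(pc2$r, cor(x, y), tolerance = 0.02)

  expect_error(partial_correlation(rnorm(4), rnorm(4),
                                   data.frame(a = rnorm(4), b = rnorm(4))),
               "insufficient")
})

test_that("moderation models recover a simulated interaction and hold size", {
  set.seed(8)
  est <- replicate(150, {
    n <- 600
    mod <- rbinom(n, 1, 0.4)
    x <- rnorm(n)
    y <- 0.3 * x + 0.2 * mod + 0.16 * x * mod + rnorm(n)
    d <- tibble::tibble(y = y, x = x, mod = mod,
                        age = rnorm(n), sex = rbinom(n, 1, 0.5),
                        education = rnorm(n))
    f <- moderation_fit(d, "y", "x", "mod")
    f$coefficients$estimate[f$coefficients$term_type == "interaction"]
  })
  expect_equal(mean(est), 0.16, tolerance = 0.02)

  p_null <- replicate(400, {
    n <- 300
    d <- tibble::tibble(y = rnorm(n), x = rnorm(n), mod = rbinom(n, 1, 0.5),
                        age = rnorm(n), sex = rbinom(n, 1, 0.5),
                        education = rnorm(n))
    f <- moderation_fit(d, "y", "x", "mod")
    f$coefficients$p_value[f$coefficients$term_type == "interaction"]
  })
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.03)

  d_const <- tibble::tibble(y = rnorm(50), x = rnorm(50), mod = 1,
                            age = rnorm(50), sex = rbinom(50, 1, 0.5),
                            education = rnorm(50))
  expect_error(moderation_fit(d_const, "y", "x", "mod"), "constant")
})

test_that("mediation: effect decomposition identity and null coverage", {
  set.seed(9)
  n <- 500
  tr <- rbinom(n, 1, 0.4)
  med <- 0.5 * tr + rnorm(n)
  y <- 0.6 * med + 0.3 * tr + rnorm(n)
  d <- tibble::tibble(tr = tr, med = med, y = y, c1 = rnorm(n))
  mb <- mediation_bootstrap(d, "tr", "med", "y", "c1", B = 300, seed = 1)
  expect_equal(mb$acme + mb$ade, mb$total, tolerance = 1e-12)
  expect_equal(mb$total, mb$total_direct, tolerance = 1e-10)
  expect_gt(mb$acme, 0)
  mb2 <- mediation_bootstrap(d, "tr", "med", "y", "c1", B = 300, seed = 1)
  expect_identical(mb$boots, mb2$boots)     # seeded determinism

  # b = 0: the ACME interval covers 0 at ~95%
  cover <- replicate(150, {
    tr <- rbinom(250, 1, 0.5)
    med <- 0.5 * tr + rnorm(250)
    y <- 0.4 * tr + rnorm(250)              # outcome ignores the mediator
    d0 <- tibble::tibble(tr = tr, med = med, y = y)
    m <- mediation_bootstrap(d0, "tr", "med", "y", B = 200,
                             seed = sample.int(1e6, 1))
    m$ci$acme[1] <= 0 && m$ci$acme[2] >= 0
  })
  expect_gte(mean(cover), 0.88)
  expect_lte(mean(cover), 0.99)
})

test_that("education adjustment attenuates the mediated share when it carries the path", {
  cfg <- cohort_config(n_subjects = 4000, n_probes = 60, n_causal = 10,
                       seed = 33L)
  co <- generate_cohort(cfg)
  comp <- causal_composite(co$beta, co$truth)
  g <- derive_g(generate_test_battery(co$truth$g_true, cfg))$scores$g
  d <- tibble::tibble(minority = co$pheno$minority, med = comp, g = g,
                      age = co$pheno$age,
                      sex = as.integer(co$pheno$sex == "male"),
                      education = co$pheno$education,
                      gran = co$pheno$cell_gran, batch = co$pheno$batch)
  base_cov <- c("age", "sex", "gran", "batch")
  m1 <- mediation_bootstrap(d, "minority", "med", "g", base_cov, B = 150, seed = 2)
  m2 <- mediation_bootstrap(d, "minority", "med", "g", c(base_cov, "education"),
                            B = 150, seed = 2)
  expect_lt(m2$prop_mediated, m1$prop_mediated)
})

test_that("dual-criterion outlier mask matches hand computation and null rates", {
  x <- 1:9
  madz_9 <- 0.6745 * (9 - 5) / 2
  expect_equal(madz_9, 1.349)
  expect_false(outlier_mask(x)[9])

  x2 <- c(rep(5, 20), 50)
  expect_warning(flags <- outlier_mask(x2), "MAD")   # MAD = 0 path
  expect_true(flags[21])

  x3 <- c(seq(-2, 2, length.out = 20), 50)
  flags3 <- outlier_mask(x3)
  expect_true(flags3[21])
  expect_false(any(flags3[1:20]))

  set.seed(10)
  z <- rnorm(10000)
  expect_lt(mean(outlier_mask(z)), 0.005)
})
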