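test_that("generation is bitwise deterministic given the seed", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$beta$values, b$beta$values)
  expect_identical(a$truth$causal_weights, b$truth$causal_weights)
  expect_identical(generate_test_battery(a$truth$g_true, cfg),
                   generate_test_battery(b$truth$g_true, cfg))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_causal = 50, n_probes = 40), "n_causal")
  expect_error(cohort_config(age_range = c(90, 65)), "age_range")
  expect_error(cohort_config(mci_prevalence = 1.4), "probabilities")
  expect_error(cohort_config(platform_overlap = 0), "platform_overlap")
  expect_error(cohort_config(battery_size = 1), "battery_size")
})

test_that("observed MCI fraction matches the configured prevalence", {
  cfg <- cohort_config(n_subjects = 2000, n_probes = 60, n_causal = 5,
                       mci_prevalence = 0.24, seed = 7L)
  co <- generate_cohort(cfg)
  n <- nrow(co$pheno)
  half_width <- qnorm(0.995) * sqrt(0.24 * 0.76 / n)
  expect_lt(abs(mean(co$pheno$mci) - 0.24), half_width)
})

test_that("null effect size leaves every probe uncorrelated with g", {
  cfg <- cohort_config(n_subjects = 800, n_probes = 150, n_causal = 10,
                       causal_effect_sd = 0, probe_age_sd = 0, seed = 11L)
  co <- generate_cohort(cfg)
  r <- as.numeric(cor(t(beta_to_m(co$beta)), co$truth$g_true))
  bonf <- qnorm(1 - 0.025 / length(r)) / sqrt(nrow(co$pheno))
  expect_lt(max(abs(r)), bonf)
})

test_that("phenotypes carry the documented structure", {
  co <- generate_cohort(small_config())
  ph <- co$pheno
  cells <- as.matrix(ph[grep("^cell_", names(ph))])
  expect_equal(ncol(cells), 6)
  expect_lt(max(abs(rowSums(cells) - 1)), 1e-12)
  expect_true(all(ph$age >= 65 & ph$age <= 95))
  expect_s3_class(ph$sex, "factor")
  expect_true(all(levels(ph$race) == c("White", "Black", "Other")))
  expect_true(all(co$beta$values > 0 & co$beta$values < 1))
  expect_equal(mean(co$truth$g_true), 0, tolerance = 1e-10)
  expect_equal(sd(co$truth$g_true), 1, tolerance = 1e-10)
  w <- co$truth$causal_weights
  expect_true(all(w != 0) && all(names(w) %in% co$truth$causal_probe_ids))
})

test_that("battery has the requested width and the noiseless limit is exact", {
  cfg14 <- cohort_config(n_subjects = 100, n_probes = 40, n_causal = 4,
                         battery_size = 14, seed = 3L)
  co <- generate_cohort(cfg14)
  bat <- generate_test_battery(co$truth$g_true, cfg14)
  expect_equal(sum(startsWith(names(bat), "test_")), 14)

  cfg_pure <- cohort_config(n_subjects = 100, n_probes = 40, n_causal = 4,
                            battery_size = 3, loading_range = c(1, 1), seed = 3L)
  bat_pure <- generate_test_battery(co$truth$g_true, cfg_pure)
  for (j in paste0("test_0", 1:3)) {
    expect_equal(unname(bat_pure[[j]]), unname(co$truth$g_true), tolerance = 1e-12)
  }
})

test_that("off-diagonal battery correlations match the loading product", {
  cfg <- cohort_config(n_subjects = 5000, n_probes = 40, n_causal = 4,
                       battery_size = 6, seed = 21L)
  co <- generate_cohort(cfg)
  bat <- generate_test_battery(co$truth$g_true, cfg)
  lam <- attr(bat, "loadings")
  r <- cor(as.matrix(bat[paste0("test_0", 1:6)]))
  # unit-variance tests: corr(test_j, test_k) = lambda_j * lambda_k
  expected <- outer(lam, lam)
  off <- upper.tri(r)
  expect_lt(abs(mean(r[off]) - mean(expected[off])), 0.02)
  expect_lt(max(abs(r[off] - expected[off])), 0.08)
})

test_that("platform split: identity, panel size, and missingness rate", {
  cfg_id <- cohort_config(n_subjects = 120, n_probes = 80, n_causal = 5,
                          platform_overlap = 1, missing_rate = 0,
                          n_replicate_loci = 0, seed = 5L)
  co <- generate_cohort(cfg_id)
  pl <- split_platforms(co$beta, cfg_id)
  expect_identical(pl$platform_a$values, pl$platform_b$values)

  cfg_sub <- cohort_config(n_subjects = 120, n_probes = 600, n_causal = 5,
                           platform_overlap = 558 / 600, missing_rate = 0,
                           n_replicate_loci = 0, seed = 5L)
  co2 <- generate_cohort(cfg_sub)
  pl2 <- split_platforms(co2$beta, cfg_sub)
  expect_equal(nrow(pl2$platform_b$values), 558)

  cfg_miss <- cohort_config(n_subjects = 250, n_probes = 400, n_causal = 5,
                            platform_overlap = 1, missing_rate = 0.05,
                            n_replicate_loci = 0, seed = 9L)
  co3 <- generate_cohort(cfg_miss)
  pl3 <- split_platforms(co3$beta, cfg_miss)
  n_cells <- length(pl3$platform_b$values)
  expect_gte(n_cells, 1e5)
  half_width <- qnorm(0.995) * sqrt(0.05 * 0.95 / n_cells)
  expect_lt(abs(mean(is.na(pl3$platform_b$values)) - 0.05), half_width)
})

test_that("replicate probes share a locus and extend the annotation", {
  cfg <- small_config()
  co <- generate_cohort(cfg)
  pl <- split_platforms(co$beta, cfg, annotation = co$annotation)
  reps <- grep("_r2$", probe_ids(pl$platform_b), value = TRUE)
  expect_equal(length(reps), 4)
  ann <- pl$annotation
  expect_true(all(probe_ids(pl$platform_b) %in% ann$probe_id))
  expect_identical(ann$locus_id[match(reps, ann$probe_id)], sub("_r2$", "", reps))
})

test_that("stratified split preserves within-cell proportions and boundaries", {
  cfg <- cohort_config(seed = 20251014L)     # default n = 2069
  co <- generate_cohort(cfg)
  idx <- stratified_split(co$pheno, 0.7, c("mci", "race", "sex"), seed = 1L)
  expect_equal(sort(c(idx$train, idx$test)), seq_len(nrow(co$pheno)))
  n_cells <- nrow(unique(co$pheno[c("mci", "race", "sex")]))
  expect_lt(abs(length(idx$train) - round(0.7 * 2069)), n_cells + 1)
  # per-cell balance within one subject
  cell <- interaction(co$pheno[c("mci", "race", "sex")], drop = TRUE)
  in_train <- seq_len(nrow(co$pheno)) %in% idx$train
  for (lev in levels(cell)) {
    i <- cell == lev
    expect_lte(abs(sum(in_train[i]) - 0.7 * sum(i)), 1)
  }

  all_train <- stratified_split(co$pheno, 1, c("mci", "sex"), seed = 1L)
  expect_length(all_train$test, 0)

  ph <- co$pheno[1:11, ]
  ph$odd <- c(rep("a", 10), "b")              # singleton cell
  expect_warning(s <- stratified_split(ph, 0.7, "odd", seed = 2L), "singleton")
  expect_true(11 %in% s$train)
})

test_that("the causal signal is recoverable exactly on the causal set", {
  cfg <- cohort_config(n_subjects = 3000, n_probes = 200, n_causal = 12,
                       seed = 31L)
  co <- generate_cohort(cfg)
  m <- beta_to_m(co$beta)
  age <- co$pheno$age
  g_adj <- resid(lm(co$truth$g_true ~ age))
  r <- apply(m, 1, function(row) cor(resid(lm(row ~ age)), g_adj))
  bonf <- qnorm(1 - 0.025 / length(r)) / sqrt(nrow(co$pheno))
  causal <- names(r) %in% co$truth$causal_probe_ids
  expect_true(all(abs(r[causal]) > bonf))     # power at configured effects
  expect_lt(mean(abs(r[!causal]) > bonf), 0.01)
})
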