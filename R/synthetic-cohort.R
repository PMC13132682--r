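#' Configuration for a synthetic methylation--cognition cohort
#'
#' Defines the study conditions the generator emulates: two array platforms
#' with partially overlapping probe panels, a latent general cognitive ability
#' (g) driving a multi-test battery and MCI status, a sparse causal CpG subset
#' whose methylation depends on g, age, cell composition and batch, an
#' age-dominated comparator clock, and demographic structure typical of a
#' population-based cohort of adults aged 65+.
#'
#' Default demographics are calibrated to a large US aging cohort: age mean
#' 75.22 (SD 7.01) truncated to `age_range`, 57% female, race distribution
#' 78% White / 16.5% Black / 5.5% other, MCI prevalence 23.8%, education mean
#' 12.8 years. Probe effects are specified on the M-value scale and mapped to
#' beta values through the inverse logit2, which keeps betas in (0, 1).
#'
#' `race_probe_shift` (the minority-group baseline shift applied to half of
#' the causal probes, aligned against each probe's causal sign) defaults to
#' the value that makes the population product-of-coefficients proportion
#' mediated equal `target_prop_mediated` for the causal-composite mediator;
#' see [implied_mediation()].
#'
#' @param n_subjects,n_probes,n_causal Cohort and panel sizes.
#' @param causal_effect_sd Magnitude of each causal probe's g effect on the
#'   M-value scale (signs random).
#' @param age_range,age_mean,age_sd Age distribution (years; truncated normal).
#' @param mci_prevalence Target MCI prevalence; the diagnostic threshold is
#'   solved so the expected prevalence matches.
#' @param battery_size Number of cognitive tests in the battery.
#' @param loading_range Interval from which each test's g loading is drawn;
#'   unique noise SD is `sqrt(1 - loading^2)` so tests have unit variance.
#' @param platform_overlap Fraction of probes retained on the second platform.
#' @param missing_rate Per-cell detection-failure probability.
#' @param n_replicate_loci Loci duplicated as replicate probes on the second
#'   platform (exercises replicate collapsing).
#' @param seed Integer seed; all draws flow from this single stream.
#' @param female_prop,race_probs,hispanic_prop,edu_mean,edu_sd,edu_race_shift
#'   Demographic parameters (`edu_race_shift` = mean education shift, in
#'   years, for minority-group participants).
#' @param n_batches,batch_sd Number of plates and SD of per-probe additive
#'   M-value plate shifts (first plate is reference).
#' @param probe_noise_sd,probe_age_sd,probe_cell_sd Per-probe residual SD and
#'   SDs of per-probe age / cell-composition coefficients (M-value scale).
#' @param g_age_beta,g_edu_beta,g_race_shift Structural coefficients of the
#'   latent g equation (on z-scored age and education; named race shifts).
#' @param mci_g_beta Log-odds slope of MCI on g.
#' @param target_prop_mediated Population proportion of the minority-group
#'   cognition gap mediated by the causal-probe composite.
#' @param edu_probe_weight Education loading (M units per education SD,
#'   sign-aligned) of the race-shifted causal probes, so part of the mediated
#'   path runs through education and adjusting for education attenuates the
#'   mediated share.
#' @param race_probe_shift Optional override of the calibrated probe shift.
#' @param frac_cross_reactive,frac_snp,frac_non_cg Fractions of the panel
#'   flagged for QC removal (these probes are never causal).
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 2069,
                          n_probes = 600,
                          n_causal = 30,
                          causal_effect_sd = 0.045,
                          age_range = c(65, 95),
                          age_mean = 75.22,
                          age_sd = 7.01,
                          mci_prevalence = 0.238,
                          battery_size = 19,
                          loading_range = c(0.4, 0.8),
                          platform_overlap = 558 / 600,
                          missing_rate = 0.02,
                          n_replicate_loci = 10,
                          seed = 20251014L,
                          female_prop = 0.57,
                          race_probs = c(White = 0.78, Black = 0.165, Other = 0.055),
                          hispanic_prop = 0.11,
                          edu_mean = 12.8,
                          edu_sd = 3.0,
                          edu_race_shift = -1.2,
                          n_batches = 3,
                          batch_sd = 0.08,
                          probe_noise_sd = 0.35,
                          probe_age_sd = 0.02,
                          probe_cell_sd = 0.06,
                          g_age_beta = -0.25,
                          g_edu_beta = 0.25,
                          g_race_shift = c(Black = -0.40, Other = -0.30),
                          mci_g_beta = -1.2,
                          target_prop_mediated = 0.35,
                          edu_probe_weight = 0.03,
                          race_probe_shift = NULL,
                          frac_cross_reactive = 0.02,
                          frac_snp = 0.02,
                          frac_non_cg = 0.01) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  if (is.null(cfg$race_probe_shift)) {
    cfg$race_probe_shift <- implied_mediation(cfg)$race_probe_shift
  }
  cfg
}

validate_cohort_config <- function(cfg) {
  stop_cfg <- function(msg) abort(msg, class = "methylcog_config_error")
  if (cfg$n_causal > cfg$n_probes) stop_cfg("n_causal must not exceed n_probes.")
  if (cfg$age_range[1] >= cfg$age_range[2]) stop_cfg("degenerate age_range (low >= high).")
  probs <- c(cfg$mci_prevalence, cfg$missing_rate, cfg$female_prop,
             cfg$hispanic_prop, cfg$frac_cross_reactive, cfg$frac_snp,
             cfg$frac_non_cg)
  if (any(probs < 0 | probs > 1)) stop_cfg("all probabilities must lie in [0, 1].")
  if (cfg$platform_overlap <= 0 || cfg$platform_overlap > 1) {
    stop_cfg("platform_overlap must lie in (0, 1].")
  }
  if (cfg$loading_range[1] <= 0 || cfg$loading_range[2] > 1 ||
      cfg$loading_range[1] > cfg$loading_range[2]) {
    stop_cfg("loading_range must be an interval within (0, 1].")
  }
  if (abs(sum(cfg$race_probs) - 1) > 1e-8) stop_cfg("race_probs must sum to 1.")
  if (cfg$battery_size < 2) stop_cfg("battery_size must be at least 2.")
  invisible(cfg)
}

# reference blood cell-type mixture (granulocyte-dominated), Dirichlet base
.cell_types <- c(gran = 0.54, cd4t = 0.15, cd8t = 0.10, b = 0.07,
                 nk = 0.06, mono = 0.08)

#' Population mediation structure implied by a cohort configuration
#'
#' Computes, from the generative equations alone (no simulation), the
#' population paths of the mediation structure: minority-group status ->
#' causal-probe composite -> cognition, with age and sex as covariates. The
#' mediator is the sign-aligned mean of the race-shifted causal probes. Also
#' returns the probe baseline shift that makes the proportion mediated equal
#' `target_prop_mediated`. The paths assume the mediator and outcome models
#' adjust for age, sex, cell composition and batch (which absorb the
#' composite's technical terms); analyses with fewer covariates will see a
#' somewhat smaller mediated share.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `total_effect`, `a_path`, `b_path`, `acme`,
#'   `prop_mediated`, and `race_probe_shift`.
#' @export
implied_mediation <- function(config) {
  cfg <- config
  p_min <- 1 - unname(cfg$race_probs["White"])              # P(minority)
  # education: edu = mu + shift*T + N(0, edu_sd^2); z-scored downstream
  var_edu <- cfg$edu_sd^2 + p_min * (1 - p_min) * cfg$edu_race_shift^2
  t_edu <- cfg$edu_race_shift / sqrt(var_edu)               # T effect on edu_z
  # direct race shift on g averaged over minority groups
  pr <- cfg$race_probs
  dg <- cfg$g_race_shift
  dg_avg <- (pr["Black"] * dg["Black"] + pr["Other"] * dg["Other"]) / p_min
  dg_avg <- unname(dg_avg)
  # latent g scale: var of raw g equation
  e_dg <- p_min * dg_avg                                    # E[race shift], approx.
  var_dg <- pr["Black"] * dg["Black"]^2 + pr["Other"] * dg["Other"]^2 - e_dg^2
  cov_eduz_dg <- (cfg$edu_race_shift / sqrt(var_edu)) *
    (pr["Black"] * dg["Black"] + pr["Other"] * dg["Other"] - p_min * e_dg)
  resid_g_sd <- 0.92                                        # fixed residual scale
  var_graw <- cfg$g_age_beta^2 + cfg$g_edu_beta^2 + unname(var_dg) +
    2 * cfg$g_edu_beta * unname(cov_eduz_dg) + resid_g_sd^2
  sd_graw <- sqrt(var_graw)
  # total effect of minority status on standardized g, given age & sex
  c_tot <- (cfg$g_edu_beta * t_edu + dg_avg) / sd_graw
  # residual variance of g given minority status and age
  var_edu_given_T <- cfg$edu_sd^2 / var_edu                 # on edu_z scale
  var_dg_given_T <- p_min *
    ((pr["Black"] * dg["Black"]^2 + pr["Other"] * dg["Other"]^2) / p_min - dg_avg^2)
  v_g <- (cfg$g_edu_beta^2 * var_edu_given_T + unname(var_dg_given_T) +
            resid_g_sd^2) / var_graw
  # composite of k2 race-shifted causal probes (sign-aligned mean, M scale);
  # the per-probe age, cell and batch terms are absorbed by the mediation
  # covariates (age, sex, cell composition, batch), leaving probe noise plus
  # the education loading of the shifted probes
  k2 <- floor(cfg$n_causal / 2)
  sigma_c2 <- cfg$probe_noise_sd^2 / k2
  a_mag <- cfg$causal_effect_sd
  e_w <- cfg$edu_probe_weight
  cov_eduz_g <- cfg$g_edu_beta * var_edu_given_T / sd_graw   # given T, age
  cov_cg <- a_mag * v_g + e_w * cov_eduz_g
  var_c <- a_mag^2 * v_g + e_w^2 * var_edu_given_T +
    2 * a_mag * e_w * cov_eduz_g + sigma_c2
  b_path <- cov_cg / var_c
  # solve a_path * b_path / c_tot = target for the probe shift s (shift enters
  # the aligned composite as -s per unit T; education carries e_w * t_edu)
  s <- unname(a_mag * c_tot + e_w * t_edu - cfg$target_prop_mediated * c_tot / b_path)
  a_path <- a_mag * c_tot + e_w * t_edu - s
  acme <- a_path * b_path
  list(total_effect = unname(c_tot), a_path = unname(a_path),
       b_path = unname(b_path), acme = unname(acme),
       prop_mediated = unname(acme / c_tot), race_probe_shift = s)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws phenotypes, a probes-by-samples beta matrix with detection p-values,
#' probe annotation, and the generating ground truth, all from the single
#' seeded stream in `config`. Causal probes carry a `g` term on the M-value
#' scale; every probe carries age, cell-composition and batch terms; a
#' comparator clock column is age-dominated with a small negative g loading;
#' biomarker-like columns are log-normal and age-correlated.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `pheno` (tibble), `beta` (`beta_matrix`),
#'   `annotation` (tibble), and `truth` (list: `g_true`, `causal_probe_ids`,
#'   `causal_weights`, `mediator_paths`, `shifted_probe_ids`, `config`).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  if (is.null(cfg$race_probe_shift)) {
    cfg$race_probe_shift <- implied_mediation(cfg)$race_probe_shift
  }
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  sample_id <- sprintf("S%05d", seq_len(n))

  ## ---- demographics -------------------------------------------------------
  age <- rtruncnorm1(n, cfg$age_mean, cfg$age_sd, cfg$age_range[1], cfg$age_range[2])
  sex <- factor(ifelse(runif(n) < cfg$female_prop, "female", "male"),
                levels = c("female", "male"))
  race <- factor(sample(names(cfg$race_probs), n, TRUE, prob = cfg$race_probs),
                 levels = names(cfg$race_probs))
  hispanic <- rbinom(n, 1, cfg$hispanic_prop)
  minority <- as.integer(race != "White")
  edu <- cfg$edu_mean + cfg$edu_race_shift * minority + rnorm(n, 0, cfg$edu_sd)
  edu <- pmin(pmax(edu, 0), 20)
  cells <- matrix(rgamma(n * 6, shape = rep(35 * .cell_types, each = n)), nrow = n)
  cells <- cells / rowSums(cells)
  colnames(cells) <- paste0("cell_", names(.cell_types))
  batch <- factor(sample(paste0("plate", seq_len(cfg$n_batches)), n, TRUE))
  apoe4 <- rbinom(n, 1, 0.233)

  ## ---- latent cognitive ability ------------------------------------------
  age_z <- as.numeric(scale(age))
  edu_z <- as.numeric(scale(edu))
  race_shift_g <- rep(0, n)
  for (grp in names(cfg$g_race_shift)) {
    race_shift_g[race == grp] <- cfg$g_race_shift[[grp]]
  }
  g_raw <- cfg$g_age_beta * age_z + cfg$g_edu_beta * edu_z + race_shift_g +
    rnorm(n, 0, 0.92)
  g_true <- as.numeric(scale(g_raw))

  ## ---- diagnosis, comparator clock, screener, biomarkers ------------------
  thr <- uniroot(function(q) mean(stats::plogis(q + cfg$mci_g_beta * g_true)) -
                   cfg$mci_prevalence, c(-20, 20))$root
  mci <- rbinom(n, 1, stats::plogis(thr + cfg$mci_g_beta * g_true))
  comparator_clock <- 0.9 * age_z - 0.15 * g_true + rnorm(n, 0, 0.4)
  screener <- round(pmin(pmax(27 + 1.5 * g_true - 0.5 * age_z + rnorm(n, 0, 1.2), 0), 30))
  biomarker_nfl <- exp(0.3 * age_z + rnorm(n, 0, 0.5))
  biomarker_gfap <- exp(0.25 * age_z + rnorm(n, 0, 0.5))

  ## ---- probe panel and annotation ----------------------------------------
  p <- cfg$n_probes
  n_xr <- round(cfg$frac_cross_reactive * p)
  n_snp <- round(cfg$frac_snp * p)
  n_ch <- round(cfg$frac_non_cg * p)
  probe_id <- sprintf("cg%08d", seq_len(p))
  if (n_ch > 0) probe_id[seq_len(n_ch)] <- sprintf("ch.%d.%07d", 1:n_ch, seq_len(n_ch))
  flagged <- logical(p)
  flagged[seq_len(n_ch)] <- TRUE
  is_xr <- logical(p); is_snp <- logical(p)
  pool_left <- which(!flagged)
  idx_xr <- sample(pool_left, n_xr); is_xr[idx_xr] <- TRUE
  pool_left <- setdiff(pool_left, idx_xr)
  idx_snp <- sample(pool_left, n_snp); is_snp[idx_snp] <- TRUE
  clean <- !flagged & !is_xr & !is_snp
  causal_idx <- sort(sample(which(clean), cfg$n_causal))
  annotation <- tibble::tibble(
    probe_id = probe_id,
    locus_id = probe_id,
    is_cross_reactive = is_xr,
    is_snp_proximal = is_snp,
    has_cg_prefix = startsWith(probe_id, "cg"),
    on_450k = TRUE,
    candidate = clean
  )

  ## ---- methylation on the M scale ----------------------------------------
  mu <- rnorm(p, 0, 1.5)
  age_coef <- rnorm(p, 0, cfg$probe_age_sd)
  cell_coef <- rnorm(p, 0, cfg$probe_cell_sd)
  batch_shift <- cbind(0, matrix(rnorm(p * (cfg$n_batches - 1), 0, cfg$batch_sd), p))
  causal_sign <- sample(c(-1, 1), cfg$n_causal, TRUE)
  a <- numeric(p)
  a[causal_idx] <- causal_sign * cfg$causal_effect_sd
  shifted_idx <- causal_idx[seq_len(floor(cfg$n_causal / 2))]
  shift <- numeric(p)
  # baseline shift aligned against the causal sign: minority participants get
  # methylation moved in the direction associated with lower predicted g
  signs_all <- sign(a)
  shift[shifted_idx] <- -cfg$race_probe_shift * signs_all[shifted_idx]
  # sign-aligned education loading on the same probes (education-borne path)
  edu_load <- numeric(p)
  edu_load[shifted_idx] <- cfg$edu_probe_weight * signs_all[shifted_idx]
  cell_z <- as.numeric(scale(cells[, "cell_gran"]))
  noise <- matrix(rnorm(p * n, 0, cfg$probe_noise_sd), p, n)
  m_vals <- mu +
    outer(a, g_true) +
    outer(age_coef, age_z) +
    outer(cell_coef, cell_z) +
    batch_shift[, as.integer(batch)] +
    outer(shift, minority) +
    outer(edu_load, edu_z) +
    noise
  beta_vals <- m_to_beta(m_vals)
  dimnames(beta_vals) <- list(probe_id, sample_id)

  det_p <- matrix(runif(p * n, 0, 0.005), p, n, dimnames = dimnames(beta_vals))
  fail <- matrix(runif(p * n) < cfg$missing_rate, p, n)
  det_p[fail] <- runif(sum(fail), 0.02, 1)

  pheno <- tibble::tibble(
    sample_id = sample_id, age = age, sex = sex, education = edu,
    race = race, hispanic = hispanic, minority = minority,
    tibble::as_tibble(cells), batch = batch, mci = mci, apoe4 = apoe4,
    screener = screener, comparator_clock = comparator_clock,
    biomarker_nfl = biomarker_nfl, biomarker_gfap = biomarker_gfap
  )

  truth <- list(
    g_true = setNames(g_true, sample_id),
    causal_probe_ids = probe_id[causal_idx],
    causal_weights = setNames(a[causal_idx], probe_id[causal_idx]),
    shifted_probe_ids = probe_id[shifted_idx],
    mediator_paths = implied_mediation(cfg),
    config = cfg
  )

  list(
    pheno = pheno,
    beta = beta_matrix(beta_vals, detection_p = det_p, platform = "platform_a"),
    annotation = annotation,
    truth = truth
  )
}

#' Generate a cognitive test battery from latent ability
#'
#' Each test is `loading * g + sqrt(1 - loading^2) * noise`, with loadings
#' drawn uniformly from `config$loading_range`, so tests have unit variance
#' and the battery has a single common factor.
#'
#' @param g_true Named standardized vector of latent ability (names = sample
#'   IDs).
#' @param config A [cohort_config()]; `battery_size`, `loading_range` and
#'   `seed` are used.
#' @return A tibble with `sample_id` and `battery_size` test columns. The
#'   drawn loadings are attached as attribute `"loadings"`.
#' @export
generate_test_battery <- function(g_true, config) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed + 7L)
  k <- cfg$battery_size
  n <- length(g_true)
  lambda <- runif(k, cfg$loading_range[1], cfg$loading_range[2])
  noise_sd <- sqrt(1 - lambda^2)
  scores <- vapply(seq_len(k),
                   function(j) lambda[j] * g_true + rnorm(n, 0, noise_sd[j]),
                   numeric(n))
  colnames(scores) <- sprintf("test_%02d", seq_len(k))
  out <- tibble::tibble(sample_id = names(g_true) %||% sprintf("S%05d", seq_len(n)))
  out <- dplyr::bind_cols(out, tibble::as_tibble(scores))
  attr(out, "loadings") <- setNames(lambda, colnames(scores))
  out
}

#' Split a beta matrix into two platform variants
#'
#' The first platform is the input unchanged. The second keeps a seeded random
#' fraction `platform_overlap` of probes, masks cells at `missing_rate` (value
#' set `NA`, detection p raised above any sensible threshold), and duplicates
#' `n_replicate_loci` of the retained loci as replicate probes (suffix `_r2`,
#' sharing `locus_id`) with small independent measurement noise.
#'
#' @param beta A `beta_matrix`.
#' @param config A [cohort_config()].
#' @param annotation Optional probe annotation to extend with replicate rows.
#' @return A list with `platform_a`, `platform_b` (`beta_matrix`es) and, when
#'   `annotation` is supplied, an extended `annotation` tibble.
#' @export
split_platforms <- function(beta, config, annotation = NULL) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed + 101L)
  p <- nrow(beta$values)
  keep_n <- round(cfg$platform_overlap * p)
  keep <- sort(sample.int(p, keep_n))
  vals <- beta$values[keep, , drop = FALSE]
  detp <- if (is.null(beta$detection_p)) {
    matrix(0, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  } else {
    beta$detection_p[keep, , drop = FALSE]
  }
  if (cfg$missing_rate > 0) {
    fail <- matrix(runif(length(vals)) < cfg$missing_rate, nrow(vals))
    vals[fail] <- NA_real_
    detp[fail] <- runif(sum(fail), 0.5, 1)
  }
  locus <- rownames(vals)
  n_rep <- min(cfg$n_replicate_loci, nrow(vals))
  if (n_rep > 0) {
    rep_idx <- sort(sample.int(nrow(vals), n_rep))
    rep_vals <- m_to_beta(beta_to_m(vals[rep_idx, , drop = FALSE]) +
                            matrix(rnorm(n_rep * ncol(vals), 0, 0.02), n_rep))
    rownames(rep_vals) <- paste0(rownames(vals)[rep_idx], "_r2")
    rep_detp <- detp[rep_idx, , drop = FALSE]
    rownames(rep_detp) <- rownames(rep_vals)
    locus <- c(locus, rownames(vals)[rep_idx])
    vals <- rbind(vals, rep_vals)
    detp <- rbind(detp, rep_detp)
  }
  platform_b <- beta_matrix(vals, detection_p = detp, platform = "platform_b")
  out <- list(platform_a = beta, platform_b = platform_b)
  if (!is.null(annotation)) {
    extra_id <- setdiff(rownames(vals), annotation$probe_id)
    if (length(extra_id)) {
      base <- annotation[match(sub("_r2$", "", extra_id), annotation$probe_id), ]
      base$probe_id <- extra_id
      annotation <- dplyr::bind_rows(annotation, base)
    }
    out$annotation <- annotation
  }
  out
}

#' Sign-aligned causal-probe composite
#'
#' The mediator variable of the generator's mediation structure: the mean,
#' over the race-shifted causal probes, of each probe's M-value multiplied by
#' the sign of its causal weight (so probes whose methylation rises with g and
#' probes whose methylation falls with g contribute coherently).
#'
#' @param beta A `beta_matrix` containing the shifted probes.
#' @param truth The `truth` element returned by [generate_cohort()].
#' @return Named numeric vector, one value per sample.
#' @export
causal_composite <- function(beta, truth) {
  ids <- truth$shifted_probe_ids
  miss <- setdiff(ids, probe_ids(beta))
  if (length(miss)) abort(paste0("shifted probes absent from beta: ",
                                 paste(miss, collapse = ", ")))
  m <- beta_to_m(beta$values[ids, , drop = FALSE])
  signs <- sign(truth$causal_weights[ids])
  colMeans(m * signs)
}

#' Stratified train/test split
#'
#' Partitions subjects into train and test sets, preserving `train_fraction`
#' within every cell of the crossed strata (to within one subject per cell).
#' Singleton cells are assigned to the training set with a warning.
#'
#' @param pheno Phenotype data frame.
#' @param train_fraction Proportion assigned to training.
#' @param strata Character vector of stratification column names (categorical).
#' @param seed Integer seed for the within-cell shuffles.
#' @return A list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(pheno, train_fraction = 0.7,
                             strata = c("mci", "race", "sex"),
                             seed = .default_fold_seed) {
  stopifnot(train_fraction >= 0, train_fraction <= 1)
  missing_cols <- setdiff(strata, names(pheno))
  if (length(missing_cols)) {
    abort(paste0("strata columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  cell <- interaction(pheno[strata], drop = TRUE)
  set.seed(seed)
  train <- integer(0)
  singletons <- 0L
  for (lev in levels(cell)) {
    idx <- which(cell == lev)
    if (length(idx) == 1) {
      train <- c(train, idx)
      singletons <- singletons + 1L
      next
    }
    n_tr <- round(train_fraction * length(idx))
    train <- c(train, sample(idx, n_tr))
  }
  if (singletons > 0) {
    warn(sprintf("%d singleton stratum cell(s) assigned to the training set.",
                 singletons))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(pheno)), train))
}
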