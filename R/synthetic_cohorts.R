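# Multi-site synthetic cohort generator. The generative model is the minimal
# structure under which the per-site covariate model is correctly specified:
#   value = roi_mean + site_shift
#           + scale * [ trend(age, sex) + moderator links
#                       + dx * (true_d + site_dev + sex shift) * sigma_pool
#                       + eps ]
# with eps Gaussian, compound-symmetric across ROIs, and its variance solved
# per ROI and group so the within-site marginal s.d. matches the configured
# targets (0.0194 controls / 0.0176 patients for whole-skeleton FA).

.METRICS <- c("FA", "MD", "AD", "RD")

# plausible synthetic per-tract FA means (not estimates of any real template)
.default_fa_means <- function() {
  c(AverageFA = 0.455, ACR = 0.50, CC = 0.70, BCC = 0.66, GCC = 0.70,
    ALIC = 0.58, CR = 0.52, FXST = 0.52, FX = 0.45, PTR = 0.62, SS = 0.58,
    SFO = 0.52, CGC = 0.56, PCR = 0.54, SCC = 0.74, SLF = 0.52, EC = 0.48,
    IC = 0.62, UNC = 0.50, SCR = 0.52, RLIC = 0.60, IFO = 0.52, CGH = 0.50,
    CST = 0.60, PLIC = 0.68)
}

# evaluate an expression under a private RNG stream, restoring global state
.with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration of the multi-site cohort generator
#'
#' Defaults emulate the reference 29-cohort study design: heterogeneous site
#' sizes (20-250 subjects per group), a standardized diagnosis effect per ROI
#' equal to the registry's reference FA effect sizes, between-site effect
#' heterogeneity on the d scale, site intercept shifts, nonlinear age and sex
#' trends, and clinical moderators with the study's printed means (age at
#' onset 23 y, illness duration ~14 y, CPZ-equivalent dose 371.23 mg, PANSS
#' total 55.90, SANS 16.72, SAPS 13.70, 71/6/10/13% atypical/typical/both/
#' unmedicated, ~51% smokers). Whole-skeleton FA is calibrated so its
#' marginal s.d. is 0.0194 in controls and 0.0176 in patients.
#'
#' @param n_sites Number of sites (cohorts).
#' @param n_controls,n_patients Per-site group size: a single count, or a
#'   length-2 range sampled uniformly per site.
#' @param metrics Metrics to simulate, subset of `c("FA","MD","AD","RD")`.
#' @param true_d Standardized diagnosis effect (patients minus controls) per
#'   ROI: a named numeric vector (applied to FA), or a named list of such
#'   vectors keyed by metric. Unnamed entries fall back to defaults.
#' @param d_sex_shift Additional diagnosis effect (d units) in female
#'   patients; 0 disables sex-dependent disease effects.
#' @param smoker_d Effect (d units) of smoking within the patient group,
#'   added on top of the calibrated variance (default 0).
#' @param tau_between_site S.d. of site-level deviations of the true effect,
#'   on the d scale.
#' @param site_location_sd S.d. of additive site intercept shifts (FA units;
#'   scaled to each metric's dispersion).
#' @param site_scale_sd S.d. of log multiplicative site scale jitter. The
#'   default 0 keeps the per-site marginal-s.d. calibration exact; Cohen's d
#'   is invariant to this scale either way.
#' @param rho_roi Compound-symmetry correlation of ROI residuals.
#' @param tract_sd Marginal s.d. of tract-ROI FA in controls.
#' @param marginal_sd_control,marginal_sd_patient Target marginal s.d. of
#'   whole-skeleton average FA per group.
#' @param age_range Control age sampling range (uniform), years.
#' @param pct_male_controls,pct_male_patients Male fractions per group.
#' @param age_effect Age/sex trend coefficients in s.d. units: `center`
#'   (years), `linear` (/y), `quad` (/y^2), `sex` (male offset), `linear_sex`,
#'   `quad_sex` (interactions).
#' @param clinical_params Means/shapes of the clinical moderator
#'   distributions (see Details in the package vignette).
#' @param coverage Number of sites recording each clinical field, emulating
#'   partial availability of scales across cohorts.
#' @param moderator_slopes Named vector of true within-patient slopes of FA
#'   on each moderator (FA units per moderator unit).
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(n_sites = 29L,
                             n_controls = c(20L, 250L),
                             n_patients = c(20L, 250L),
                             metrics = "FA",
                             true_d = NULL,
                             d_sex_shift = 0,
                             smoker_d = 0,
                             tau_between_site = 0.05,
                             site_location_sd = 0.005,
                             site_scale_sd = 0,
                             rho_roi = 0.5,
                             tract_sd = 0.030,
                             marginal_sd_control = 0.0194,
                             marginal_sd_patient = 0.0176,
                             age_range = c(18, 54),
                             pct_male_controls = 0.534,
                             pct_male_patients = 0.67,
                             age_effect = list(center = 36, linear = -0.02,
                                               quad = -1.5e-4, sex = 0.15,
                                               linear_sex = -2e-3,
                                               quad_sex = -5e-5),
                             clinical_params = list(),
                             coverage = list(),
                             moderator_slopes = NULL,
                             seed = 1L) {
  metrics <- match.arg(metrics, .METRICS, several.ok = TRUE)
  stopifnot(n_sites >= 1L, length(age_range) == 2L, age_range[1] < age_range[2],
            tau_between_site >= 0, site_location_sd >= 0, site_scale_sd >= 0,
            rho_roi >= 0, rho_roi < 1, tract_sd > 0,
            marginal_sd_control > 0, marginal_sd_patient > 0)
  .check_n <- function(n, what) {
    if (!length(n) %in% 1:2 || any(n < 1) || any(n != round(n)))
      stop(what, " must be a positive count or range")
    as.integer(n)
  }
  n_controls <- .check_n(n_controls, "n_controls")
  n_patients <- .check_n(n_patients, "n_patients")
  for (p in c(pct_male_controls, pct_male_patients))
    if (p < 0 || p > 1) stop("male fractions must lie in [0, 1]")

  clin <- utils::modifyList(list(
    onset_mean = 23, onset_sd = 4, onset_min = 13,
    duration_mean = 13.2, duration_shape = 4,
    cpz_mean = 371.23, cpz_shape = 4,
    panss_mean = 55.90, panss_sd = 15,
    panss_pos_mean = 14.4, panss_pos_sd = 4.5,
    panss_neg_mean = 15.4, panss_neg_sd = 5.5,
    sans_mean = 16.72, sans_sd = 8, saps_mean = 13.70, saps_sd = 8,
    smoking_frac = 0.51,
    med_fracs = c(atypical = 0.71, typical = 0.06, both = 0.10, none = 0.13)),
    clinical_params)
  if (clin$smoking_frac < 0 || clin$smoking_frac > 1)
    stop("smoking_frac must lie in [0, 1]")
  if (abs(sum(clin$med_fracs) - 1) > 1e-6)
    stop("medication-class fractions must sum to 1")
  if (any(clin$med_fracs < 0)) stop("medication-class fractions must be >= 0")

  cov_def <- list(onset = 20L, duration = 20L, cpz = 10L, panss = 10L,
                  sans = 9L, saps = 9L, smoking = 6L, med = 10L)
  coverage <- utils::modifyList(cov_def, coverage)
  coverage <- lapply(coverage, function(k) min(as.integer(k), n_sites))

  slopes_def <- c(age_at_onset = 0, duration_years = 0, cpz = 0,
                  panss_total = 0, panss_pos = 0, panss_neg = 0,
                  sans_total = 0, saps_total = 0)
  if (!is.null(moderator_slopes)) {
    bad <- setdiff(names(moderator_slopes), names(slopes_def))
    if (length(bad)) stop("unknown moderators: ", paste(bad, collapse = ", "))
    slopes_def[names(moderator_slopes)] <- moderator_slopes
  }

  reg <- roi_registry()
  cfg <- structure(list(
    n_sites = n_sites, n_controls = n_controls, n_patients = n_patients,
    metrics = metrics, d_sex_shift = d_sex_shift, smoker_d = smoker_d,
    tau_between_site = tau_between_site,
    site_location_sd = site_location_sd, site_scale_sd = site_scale_sd,
    rho_roi = rho_roi, tract_sd = tract_sd,
    marginal_sd_control = marginal_sd_control,
    marginal_sd_patient = marginal_sd_patient,
    age_range = age_range, pct_male_controls = pct_male_controls,
    pct_male_patients = pct_male_patients, age_effect = age_effect,
    clinical_params = clin, coverage = coverage,
    moderator_slopes = slopes_def, seed = as.integer(seed),
    rois = reg$roi), class = "generator_config")
  cfg$metric_params <- .resolve_metric_params(cfg, true_d)
  cfg$calibration <- .calibrate_generator(cfg)
  cfg
}

# per-metric ROI means, marginal s.d.s and true effects
.resolve_metric_params <- function(cfg, true_d) {
  rois <- cfg$rois
  reg <- roi_registry()
  if (is.numeric(true_d)) true_d <- list(FA = true_d)
  if (!is.null(true_d) && !is.list(true_d))
    stop("true_d must be a named vector or a list keyed by metric")
  base_d <- list(
    FA = stats::setNames(reg$d_fa, rois),
    MD = stats::setNames(rep(0.20, 25), rois),
    RD = stats::setNames(rep(0.25, 25), rois),
    AD = stats::setNames(ifelse(rois == "FX", 0.10, 0), rois))
  base_mean <- list(FA = .default_fa_means(),
                    MD = stats::setNames(rep(7.5e-4, 25), rois),
                    AD = stats::setNames(rep(1.15e-3, 25), rois),
                    RD = stats::setNames(rep(5.8e-4, 25), rois))
  base_sd <- list(FA = NULL, MD = 3.5e-5, AD = 5.0e-5, RD = 4.5e-5)
  ratio <- cfg$marginal_sd_patient / cfg$marginal_sd_control
  out <- list()
  for (m in cfg$metrics) {
    d <- base_d[[m]]
    if (!is.null(true_d[[m]])) {
      bad <- setdiff(names(true_d[[m]]), rois)
      if (length(bad)) stop("true_d names not in ROI registry: ",
                            paste(bad, collapse = ", "))
      d[names(true_d[[m]])] <- true_d[[m]]
    }
    if (any(!is.finite(d))) stop("true_d must be finite for every ROI")
    if (m == "FA") {
      sd_c <- stats::setNames(rep(cfg$tract_sd, 25), rois)
      sd_c["AverageFA"] <- cfg$marginal_sd_control
      sd_p <- sd_c * ratio
    } else {
      sd_c <- stats::setNames(rep(base_sd[[m]], 25), rois)
      sd_c["AverageFA"] <- 0.8 * base_sd[[m]]
      sd_p <- sd_c
    }
    out[[m]] <- list(true_d = d, roi_means = base_mean[[m]][rois],
                     marg_sd_control = sd_c, marg_sd_patient = sd_p,
                     sign = if (m == "FA") 1 else -1,
                     site_loc_sd = cfg$site_location_sd *
                       unname(sd_c[2]) / cfg$tract_sd)
  }
  out
}

# draw the systematic covariate component for one group (controls/patients)
.draw_systematic <- function(cfg, n, group) {
  ae <- cfg$age_effect
  cp <- cfg$clinical_params
  if (group == "control") {
    age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
    male <- stats::rbinom(n, 1L, cfg$pct_male_controls)
    clin <- NULL
  } else {
    lo <- stats::pnorm((cp$onset_min - cp$onset_mean) / cp$onset_sd)
    onset <- stats::qnorm(stats::runif(n, lo, 1)) * cp$onset_sd + cp$onset_mean
    duration <- stats::rgamma(n, shape = cp$duration_shape,
                              rate = cp$duration_shape / cp$duration_mean)
    age <- onset + duration
    male <- stats::rbinom(n, 1L, cfg$pct_male_patients)
    clin <- data.frame(
      age_at_onset = onset, duration_years = duration,
      cpz = stats::rgamma(n, shape = cp$cpz_shape,
                          rate = cp$cpz_shape / cp$cpz_mean),
      panss_total = stats::rnorm(n, cp$panss_mean, cp$panss_sd),
      panss_pos = stats::rnorm(n, cp$panss_pos_mean, cp$panss_pos_sd),
      panss_neg = stats::rnorm(n, cp$panss_neg_mean, cp$panss_neg_sd),
      sans_total = stats::rnorm(n, cp$sans_mean, cp$sans_sd),
      saps_total = stats::rnorm(n, cp$saps_mean, cp$saps_sd))
  }
  a <- age - ae$center
  fstd <- ae$linear * a + ae$quad * a^2 +
    male * (ae$sex + ae$linear_sex * a + ae$quad_sex * a^2)
  list(age = age, male = male, fstd = fstd, clin = clin)
}

# latent moderator link (FA units), centered at the moderator means
.moderator_link <- function(cfg, clin, centers) {
  sl <- cfg$moderator_slopes
  active <- names(sl)[sl != 0]
  if (!length(active)) return(numeric(nrow(clin)))
  out <- numeric(nrow(clin))
  for (m in active)
    out <- out + sl[[m]] * (clin[[m]] - centers[[m]])
  out
}

# Moments of the systematic component per group, by fixed-seed Monte-Carlo
# quadrature (independent of the user's seed), plus the residual s.d. solve.
.calibrate_generator <- function(cfg, n_mc = 200000L) {
  mom <- .with_local_seed(914207L, {
    ctl <- .draw_systematic(cfg, n_mc, "control")
    pat <- .draw_systematic(cfg, n_mc, "patient")
    centers <- lapply(pat$clin, mean)
    mod <- .moderator_link(cfg, pat$clin, centers)
    list(var_fstd_control = stats::var(ctl$fstd),
         var_fstd_patient = stats::var(pat$fstd),
         var_mod_patient = stats::var(mod),
         cov_fstd_mod = stats::cov(pat$fstd, mod),
         centers = centers)
  })
  sig <- list()
  for (m in cfg$metrics) {
    p <- cfg$metric_params[[m]]
    v_c <- p$marg_sd_control^2 * (1 - mom$var_fstd_control)
    v_p <- p$marg_sd_patient^2 * (1 - mom$var_fstd_patient)
    if (m == "FA")
      v_p <- v_p - mom$var_mod_patient -
        2 * p$marg_sd_patient * p$sign * mom$cov_fstd_mod
    if (any(v_c <= 0) || any(v_p <= 0))
      stop("covariate/moderator effect variance exceeds the target marginal ",
           "variance; residual variance would be negative")
    sig[[m]] <- list(control = sqrt(v_c), patient = sqrt(v_p),
                     pooled = sqrt((v_c + v_p) / 2))
  }
  c(mom, list(sigma_eps = sig))
}

.draw_group_size <- function(n) {
  if (length(n) == 1L) n else sample(seq(n[1], n[2]), 1L)
}

#' Generate a multi-site subject-level dataset
#'
#' Simulates every site of the configured study: demographics, clinical
#' moderators (patients only; controls have these fields missing), and one
#' column per metric x ROI measure named `<metric>_<ROI>` (e.g.
#' `FA_AverageFA`). Output is deterministic for a fixed config seed.
#' Clinical fields are masked to `NA` at sites not covered for that scale,
#' mirroring partial availability of clinical instruments across cohorts.
#'
#' @param config A `generator_config`.
#' @return data.frame with one row per subject; the config is attached as
#'   attribute `"config"`.
#' @export
generate_multisite <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  rois <- cfg$rois
  R <- length(rois)
  covered <- lapply(cfg$coverage, function(k) sort(sample.int(cfg$n_sites, k)))
  centers <- cfg$calibration$centers
  sites <- vector("list", cfg$n_sites)
  for (s in seq_len(cfg$n_sites)) {
    n1 <- .draw_group_size(cfg$n_controls)   # controls
    n2 <- .draw_group_size(cfg$n_patients)   # patients
    n <- n1 + n2
    site_loc <- lapply(cfg$metrics, function(m)
      stats::rnorm(1, 0, cfg$metric_params[[m]]$site_loc_sd))
    names(site_loc) <- cfg$metrics
    site_scale <- exp(stats::rnorm(1, 0, cfg$site_scale_sd))
    site_dev <- lapply(cfg$metrics, function(m)
      stats::rnorm(R, 0, cfg$tau_between_site))
    names(site_dev) <- cfg$metrics

    ctl <- .draw_systematic(cfg, n1, "control")
    pat <- .draw_systematic(cfg, n2, "patient")
    cp <- cfg$clinical_params
    smoker <- stats::rbinom(n2, 1L, cp$smoking_frac)
    med <- sample(names(cp$med_fracs), n2, replace = TRUE,
                  prob = cp$med_fracs)
    modsum <- .moderator_link(cfg, pat$clin, centers)

    dx <- c(rep(0L, n1), rep(1L, n2))
    female <- 1L - c(ctl$male, pat$male)
    fstd <- c(ctl$fstd, pat$fstd)
    smk <- c(rep(0L, n1), smoker)
    modv <- c(rep(0, n1), modsum)

    z0 <- stats::rnorm(n)
    vals <- list()
    for (m in cfg$metrics) {
      p <- cfg$metric_params[[m]]
      sg <- cfg$calibration$sigma_eps[[m]]
      sd_mat <- rbind(matrix(sg$control, n1, R, byrow = TRUE),
                      matrix(sg$patient, n2, R, byrow = TRUE))
      eps <- (sqrt(cfg$rho_roi) * z0 +
                sqrt(1 - cfg$rho_roi) * matrix(stats::rnorm(n * R), n, R)) *
        sd_mat
      d_tot <- outer(dx, p$true_d + site_dev[[m]]) +
        outer(dx * female, rep(cfg$d_sex_shift, R)) +
        outer(dx * smk, rep(cfg$smoker_d, R))
      sys <- p$sign * outer(fstd, rep(1, R)) *
        rbind(matrix(p$marg_sd_control, n1, R, byrow = TRUE),
              matrix(p$marg_sd_patient, n2, R, byrow = TRUE))
      if (m == "FA") sys <- sys + modv
      v <- matrix(p$roi_means, n, R, byrow = TRUE) + site_loc[[m]] +
        site_scale * (sys + d_tot * matrix(sg$pooled, n, R, byrow = TRUE) +
                        eps)
      if (m == "FA") v <- pmin(pmax(v, 1e-6), 1 - 1e-6)
      colnames(v) <- paste0(m, "_", rois)
      vals[[m]] <- v
    }

    site_id <- sprintf("site%02d", s)
    clin_rec <- pat$clin
    mask <- function(field, key) {
      if (s %in% covered[[key]]) field
      else field[rep(NA_integer_, length(field))]
    }
    df <- data.frame(
      site_id = site_id,
      subject_id = sprintf("%s_%04d", site_id, seq_len(n)),
      diagnosis = c(rep("control", n1), rep("patient", n2)),
      sex = ifelse(c(ctl$male, pat$male) == 1L, "M", "F"),
      age = c(ctl$age, pat$age),
      age_at_onset = c(rep(NA_real_, n1), mask(clin_rec$age_at_onset, "onset")),
      duration_years = c(rep(NA_real_, n1),
                         mask(clin_rec$duration_years, "duration")),
      cpz = c(rep(NA_real_, n1),
              mask(ifelse(med == "none", NA_real_, clin_rec$cpz), "cpz")),
      panss_total = c(rep(NA_real_, n1), mask(clin_rec$panss_total, "panss")),
      panss_pos = c(rep(NA_real_, n1), mask(clin_rec$panss_pos, "panss")),
      panss_neg = c(rep(NA_real_, n1), mask(clin_rec$panss_neg, "panss")),
      sans_total = c(rep(NA_real_, n1), mask(clin_rec$sans_total, "sans")),
      saps_total = c(rep(NA_real_, n1), mask(clin_rec$saps_total, "saps")),
      smoker = c(rep(NA, n1), as.logical(mask(smoker, "smoking"))),
      med_class = c(rep(NA_character_, n1), mask(med, "med")),
      stringsAsFactors = FALSE)
    sites[[s]] <- cbind(df, do.call(cbind, unname(lapply(vals, as.data.frame))))
  }
  out <- do.call(rbind, sites)
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  out
}

#' Derive whole-skeleton global covariates per subject
#'
#' Adds `average_fa` (the simulated/observed whole-skeleton measure),
#' `core_fa` (voxel-count-weighted mean of the leaf tract ROI values, i.e.
#' the atlas-labeled core) and `periphery_fa` (recovered from the exact
#' decomposition identity `n_total*average = n_core*core + n_peri*periphery`)
#' for use as the global adjustment covariates in regional models.
#'
#' @param data Subject-level data.frame with `FA_*` measure columns.
#' @return `data` with columns `average_fa`, `core_fa`, `periphery_fa` added.
#' @export
add_global_covariates <- function(data) {
  reg <- roi_registry()
  leaves <- reg[reg$type == "leaf", ]
  cols <- paste0("FA_", leaves$roi)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing FA columns: ", paste(miss, collapse = ", "))
  n_core <- sum(leaves$n_voxels)
  n_tot <- reg$n_voxels[reg$roi == "AverageFA"]
  n_per <- n_tot - n_core
  core <- as.matrix(data[cols]) %*% (leaves$n_voxels / n_core)
  data$average_fa <- data$FA_AverageFA
  data$core_fa <- as.numeric(core)
  data$periphery_fa <- (n_tot * data$average_fa - n_core * data$core_fa) / n_per
  data
}

#' Write a generated cohort as per-site CSV tables with a config sidecar
#'
#' One `subjects_<site>.csv` per site (UTF-8, header row, missing values as
#' empty fields) plus `generator_config.yaml` recording every generator
#' parameter and the seed.
#'
#' @param data Output of [generate_multisite()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort_csv <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in unique(data$site_id)) {
    p <- file.path(dir, paste0("subjects_", s, ".csv"))
    utils::write.csv(data[data$site_id == s, , drop = FALSE], p,
                     row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  cfg <- attr(data, "config")
  if (!is.null(cfg)) {
    cp <- file.path(dir, "generator_config.yaml")
    keep <- setdiff(names(cfg), c("metric_params", "calibration", "rois"))
    yaml::write_yaml(lapply(unclass(cfg)[keep], function(x)
      if (is.numeric(x) || is.character(x) || is.logical(x)) unname(x) else x),
      cp)
    paths <- c(paths, cp)
  }
  invisible(paths)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "generator_config: %d site(s), controls %s, patients %s, metrics %s, tau=%g, seed=%d\n",
    x$n_sites, paste(x$n_controls, collapse = "-"),
    paste(x$n_patients, collapse = "-"),
    paste(x$metrics, collapse = "/"), x$tau_between_site, x$seed))
  invisible(x)
}
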