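test_that("d-from-t conversion matches its closed form", {
  # zero effect
  z <- cohens_d_from_t(0, 30, 40, 63)
  expect_equal(z$d, 0)
  expect_equal(z$se_d, sqrt((30 + 40) / (30 * 40)))
  # worked case: t=2, n1=n2=50, df=96
  w <- cohens_d_from_t(2, 50, 50, 96)
  expect_equal(w$d, 4 / sqrt(96), tolerance = 1e-12)        # 0.408248
  expect_equal(w$se_d, sqrt(0.04 + (4 / sqrt(96))^2 / 196),
               tolerance = 1e-12)                            # 0.202115
  # doubling both groups at fixed t shrinks |d| by about sqrt(2)
  big <- cohens_d_from_t(2, 100, 100, 196)
  expect_equal(w$d / big$d, sqrt(2), tolerance = 0.02)
  expect_error(cohens_d_from_t(NaN, 50, 50, 96), "non-finite")
})

test_that("conversion agrees with the classical pooled-s.d. d up to the df factor", {
  # brute-force oracle on random two-group samples with no covariates
  set.seed(1)
  for (i in 1:20) {
    n1 <- sample(10:40, 1); n2 <- sample(10:40, 1)
    x <- rnorm(n1, 0, 1.3); y <- rnorm(n2, 0.5, 1.3)
    sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
    d_classic <- (mean(y) - mean(x)) / sp
    tt <- summary(lm(c(x, y) ~ rep(0:1, c(n1, n2))))$coefficients[2, "t value"]
    d_conv <- cohens_d_from_t(tt, n1, n2, n1 + n2 - 2)$d
    expect_equal(d_conv, d_classic * sqrt((n1 + n2) / (n1 + n2 - 2)),
                 tolerance = 1e-10)
  }
})

test_that("group model recovers an injected adjusted shift and honors the cutoff", {
  truth <- stats::setNames(rep(0, 25), roi_registry()$roi)
  truth["AverageFA"] <- -0.4
  cfg <- generator_config(n_sites = 1L, n_controls = 2000L,
                          n_patients = 2000L, true_d = truth,
                          tau_between_site = 0, seed = 2L)
  d <- generate_multisite(cfg)
  fit <- fit_group_model(d, "AverageFA")
  expect_lt(abs(fit$d + 0.4), 0.08)
  expect_equal(fit$df, 4000L - 7L)
  expect_equal(fit$n_controls, 2000L)
  # null ROI in the same data stays near zero
  expect_lt(abs(fit_group_model(d, "PLIC")$d), 0.06)
  # a site with 9 patients is excluded with a logged reason
  d9 <- d[c(which(d$diagnosis == "control")[1:30],
            which(d$diagnosis == "patient")[1:9]), ]
  expect_message(out <- fit_group_model(d9, "AverageFA"), "below min_n")
  expect_null(out)
  rec <- site_effect_sizes(d9, rois = "AverageFA")
  expect_equal(nrow(rec), 0L)
  expect_match(attr(rec, "exclusions"), "below min_n")
})

test_that("multi-ROI fast path reproduces the per-ROI lm fit exactly", {
  cfg <- generator_config(n_sites = 2L, n_controls = c(30L, 80L),
                          n_patients = c(30L, 80L), seed = 6L)
  d <- generate_multisite(cfg)
  rec <- site_effect_sizes(d, rois = c("AverageFA", "FX", "PLIC"))
  for (i in seq_len(nrow(rec))) {
    ref <- fit_group_model(d, rec$roi[i], site = rec$site_id[i])
    expect_equal(rec$estimate[i], ref$d, tolerance = 1e-10)
    expect_equal(rec$se[i], ref$se_d, tolerance = 1e-10)
    expect_equal(rec$stat[i], ref$t_diag, tolerance = 1e-10)
    expect_equal(rec$df[i], ref$df)
  }
})

test_that("rank-deficient designs fail loudly naming the collinear term", {
  d <- generate_multisite(null_config(n = 60L, seed = 8L))
  d$average_fa <- d$age          # exactly collinear with the age covariate
  expect_error(site_effect_sizes(d, rois = "CC",
                                 spec = covariate_spec(adjust = "average_fa")),
               "collinear.*average_fa")
  # adjusting the whole-skeleton measure for itself is refused
  expect_error(site_effect_sizes(d, rois = "AverageFA",
                                 spec = covariate_spec(adjust = "average_fa")),
               "no ROIs left")
})

test_that("adding rows with missing covariates never changes estimates", {
  d <- generate_multisite(null_config(n = 80L, seed = 10L))
  base <- site_effect_sizes(d, rois = "AverageFA")
  extra <- d[1:15, ]
  extra$age <- NA_real_
  aug <- site_effect_sizes(rbind(d, extra), rois = "AverageFA")
  expect_equal(base$estimate, aug$estimate, tolerance = 1e-12)
  expect_equal(base$se, aug$se, tolerance = 1e-12)
})

test_that("moderator regressions compute duration_pct and require variation", {
  d <- generate_multisite(generator_config(
    n_sites = 1L, n_controls = 10L, n_patients = 200L, seed = 12L,
    coverage = list(duration = 1L)))
  pat <- d$diagnosis == "patient"
  # duration as percent of lifetime: spot-check the arithmetic on one row
  expect_equal((d$duration_years / d$age)[pat][1],
               d$duration_years[pat][1] / d$age[pat][1])
  rec <- moderator_regression(d, "duration_pct", rois = "AverageFA")
  expect_equal(rec$model_id, "mod_duration_pct")
  expect_equal(rec$n2, 200L)
  d$duration_years[pat] <- 10
  expect_error(moderator_regression(d, "duration_years", rois = "AverageFA"),
               "constant moderator")
})

test_that("moderator z-statistics are standard normal under the null", {
  # many small sites, no true moderator effect: z over sites ~ N(0, 1)
  zs <- c()
  for (s in 1:5) {
    cfg <- generator_config(n_sites = 25L, n_controls = 10L,
                            n_patients = c(30L, 60L), seed = 100L + s,
                            coverage = list(cpz = 25L))
    rec <- moderator_regression(generate_multisite(cfg), "cpz",
                                rois = "AverageFA")
    zs <- c(zs, rec$stat)
  }
  expect_gte(length(zs), 100L)
  expect_gt(stats::ks.test(zs, "pnorm")$p.value, 0.01)
})

test_that("subgroup contrasts recover injected effects and honor the cutoff", {
  cfg <- generator_config(n_sites = 1L, n_controls = 10L, n_patients = 3000L,
                          smoker_d = -0.2, seed = 13L,
                          coverage = list(smoking = 1L, med = 1L))
  d <- generate_multisite(cfg)
  rec <- subgroup_effect(d, "smoker", rois = "AverageFA")
  expect_lt(abs(rec$estimate + 0.2), 0.1)
  # identical subgroup distributions: no effect
  d0 <- generate_multisite(generator_config(
    n_sites = 1L, n_controls = 10L, n_patients = 3000L, seed = 14L,
    coverage = list(smoking = 1L)))
  rec0 <- subgroup_effect(d0, "smoker", rois = "AverageFA")
  expect_lt(abs(rec0$estimate), 0.1)
  # a rare medication class never reaches the 10-per-group cutoff
  small <- generate_multisite(generator_config(
    n_sites = 2L, n_controls = 10L, n_patients = 60L, seed = 15L,
    clinical_params = list(med_fracs = c(atypical = 0.85, typical = 0.05,
                                         both = 0.05, none = 0.05)),
    coverage = list(med = 2L)))
  recm <- subgroup_effect(small, "medication", contrast = c("both", "typical"),
                          rois = "AverageFA")
  expect_equal(nrow(recm), 0L)
  expect_match(attr(recm, "exclusions"), "below min_n")
})

test_that("dispersion comparison reports both s.d.s and detects ratio 2", {
  set.seed(21)
  x <- rnorm(500, 0, 2); y <- rnorm(500, 0, 1)
  vc <- variance_comparison(x, y)
  expect_equal(vc$sd1, sd(x))
  expect_equal(vc$sd2, sd(y))
  expect_lt(vc$p, 0.05)
  lv <- variance_comparison(x, y, method = "levene")
  expect_lt(lv$p, 0.05)
  # equal dispersion: F statistic 1, p 1 for identical samples
  same <- variance_comparison(x, x)
  expect_equal(same$statistic, 1)
  expect_equal(same$p, 1)
  expect_error(variance_comparison(rep(1, 5), y), "zero variance")
})
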