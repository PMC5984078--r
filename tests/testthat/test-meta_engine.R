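test_that("single-study pooling is the identity", {
  m <- random_effects_meta(-0.3, 0.08)
  expect_equal(m$pooled, -0.3)
  expect_equal(m$se_pooled, 0.08)
  expect_equal(m$Q, 0)
  expect_equal(m$I2, 0)
  expect_equal(m$tau2, 0)
  expect_equal(m$k, 1L)
})

test_that("two-study DerSimonian-Laird case matches the closed form", {
  m <- random_effects_meta(c(0.3, 0.5), c(0.1, 0.1), method = "DL")
  expect_equal(m$Q, 2, tolerance = 1e-12)
  expect_equal(m$tau2, 0.01, tolerance = 1e-12)
  expect_equal(m$pooled, 0.4, tolerance = 1e-12)
  expect_equal(m$se_pooled, 0.1, tolerance = 1e-12)
  expect_equal(m$I2, 50, tolerance = 1e-12)
})

test_that("homogeneous studies collapse to the fixed-effect answer", {
  m <- random_effects_meta(rep(0.25, 6), rep(0.1, 6), method = "DL")
  expect_equal(m$tau2, 0)
  expect_equal(m$pooled, 0.25)
  expect_equal(m$se_pooled, 0.1 / sqrt(6))
  r <- random_effects_meta(rep(0.25, 6), rep(0.1, 6), method = "REML")
  expect_equal(r$tau2, 0)
  expect_equal(r$pooled, m$pooled)
})

test_that("DL matches a brute-force formula evaluation on random inputs", {
  set.seed(3)
  for (i in 1:10) {
    k <- sample(3:10, 1)
    yi <- rnorm(k, -0.3, 0.15)
    sei <- runif(k, 0.05, 0.3)
    m <- random_effects_meta(yi, sei, method = "DL")
    # independent direct evaluation
    w <- 1 / sei^2
    q <- sum(w * (yi - sum(w * yi) / sum(w))^2)
    t2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (sei^2 + t2)
    expect_equal(m$tau2, t2, tolerance = 1e-12)
    expect_equal(m$pooled, sum(ws * yi) / sum(ws), tolerance = 1e-12)
    expect_equal(m$se_pooled, 1 / sqrt(sum(ws)), tolerance = 1e-12)
    expect_equal(m$I2, max(0, 100 * (q - (k - 1)) / q), tolerance = 1e-12)
  }
})

test_that("DL and REML agree with metafor on random problems", {
  skip_if_not_installed("metafor")
  set.seed(8)
  for (i in 1:5) {
    k <- sample(4:12, 1)
    yi <- rnorm(k, -0.35, 0.2)
    sei <- runif(k, 0.05, 0.25)
    dl <- random_effects_meta(yi, sei, method = "DL")
    ref <- metafor::rma(yi = yi, sei = sei, method = "DL")
    expect_equal(dl$pooled, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(dl$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(dl$se_pooled, ref$se, tolerance = 1e-10)
    expect_equal(dl$Q, ref$QE, tolerance = 1e-10)
    rm_ <- random_effects_meta(yi, sei, method = "REML")
    refr <- metafor::rma(yi = yi, sei = sei, method = "REML",
                         control = list(threshold = 1e-12))
    expect_equal(rm_$tau2, refr$tau2, tolerance = 1e-8)
    expect_equal(rm_$pooled, as.numeric(refr$beta), tolerance = 1e-8)
    expect_equal(rm_$se_pooled, refr$se, tolerance = 1e-8)
  }
})

test_that("pooled estimates are convex combinations; more studies never hurt precision", {
  set.seed(5)
  yi <- rnorm(8, -0.3, 0.2); sei <- runif(8, 0.05, 0.4)
  m <- random_effects_meta(yi, sei, method = "DL")
  expect_gte(m$pooled, min(yi))
  expect_lte(m$pooled, max(yi))
  # at fixed tau2, dropping the noisiest study can only lose precision
  tau2 <- m$tau2
  sub <- which(sei < max(sei))
  se_full <- 1 / sqrt(sum(1 / (sei^2 + tau2)))
  se_sub <- 1 / sqrt(sum(1 / (sei[sub]^2 + tau2)))
  expect_gte(se_sub, se_full)
})

test_that("pooling rejects empty and malformed inputs", {
  expect_error(random_effects_meta(numeric(0), numeric(0)), "no records")
  expect_error(random_effects_meta(c(0.1, 0.2), c(0.1, 0)), "record.*2")
})

test_that("Bonferroni threshold divides the family rate", {
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(1.2, 5))
})

test_that("paired effect-vector comparison matches hand arithmetic", {
  b <- c(0.0, 0.0, 0.0); a <- b + c(0.1, 0.2, 0.3)
  cmp <- compare_effect_vectors(a, b)
  expect_equal(cmp$statistic, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-6) # 3.4641
  expect_equal(cmp$df, 2)
  # antisymmetry
  rev_ <- compare_effect_vectors(b, a)
  expect_equal(rev_$statistic, -cmp$statistic)
  # identical vectors give zero-variance differences: undefined statistic
  expect_error(compare_effect_vectors(a, a), "zero-variance")
})

test_that("effect-size vs sqrt(voxel) correlation behaves at the extremes", {
  n_vox <- c(100, 400, 900, 1600, 2500)
  d <- -0.01 * sqrt(n_vox)
  res <- effectsize_voxelcount_correlation(d, n_vox)
  expect_equal(res$r_abs, 1, tolerance = 1e-12)
  expect_equal(res$r_signed, -1, tolerance = 1e-12)
  # permutation oracle: correlation centred at zero under shuffling
  set.seed(4)
  d2 <- rnorm(10); nv <- runif(10, 100, 3000)
  rs <- replicate(200,
    effectsize_voxelcount_correlation(sample(d2), nv)$r_signed)
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(effectsize_voxelcount_correlation(rep(1, 5), nv[1:5]),
               "constant")
})

test_that("site-attribute subgroup pooling reduces correctly and detects shifts", {
  rec <- make_records(10, mu = -0.4, tau = 0.03, se = 0.08, seed = 2)
  one <- group_meta_compare(rec, setNames(rep("all", 10), rec$site_id))
  ref <- random_effects_meta(rec$estimate, rec$se)
  expect_equal(one$groups$all$pooled, ref$pooled)
  expect_null(one$diff_z)
  # injected 0.2 between-group difference is detected
  rec2 <- rec
  grp <- rep(c("high", "low"), each = 5)
  names(grp) <- rec2$site_id
  rec2$estimate[grp[rec2$site_id] == "low"] <-
    rec2$estimate[grp[rec2$site_id] == "low"] - 0.2
  cmpr <- group_meta_compare(rec2, grp)
  expect_lt(cmpr$diff_p, 0.05)
  expect_gt(cmpr$diff, 0)    # high minus low
  # groups with a single site are skipped with a warning
  expect_warning(group_meta_compare(rec2, setNames(c("a", rep("b", 9)),
                                                   rec2$site_id)),
                 "k < 2")
})

test_that("group-difference z is standard normal when the attribute is inert", {
  set.seed(6)
  zs <- replicate(300, {
    rec <- data.frame(site_id = sprintf("s%02d", 1:12), roi = "AverageFA",
                      metric = "FA", model_id = "casecontrol_FA",
                      estimate = rnorm(12, -0.4, 0.1), se = 0.1,
                      stat = NA, df = 100, n1 = 50, n2 = 50)
    grp <- setNames(rep(c("a", "b"), 6), rec$site_id)
    suppressWarnings(group_meta_compare(rec, grp, method = "DL")$diff_z)
  })
  expect_gt(stats::ks.test(zs, "pnorm")$p.value, 0.01)
})

test_that("meta_pool flags cells at the family threshold and sorts by magnitude", {
  rec <- rbind(make_records(8, mu = -0.5, se = 0.05, seed = 3),
               make_records(8, mu = 0.0, se = 0.05, seed = 4, roi = "CST"))
  rep_ <- meta_pool(rec, method = "DL")
  expect_equal(attr(rep_, "threshold"), 0.002)
  expect_equal(rep_$roi, c("AverageFA", "CST"))  # sorted by |pooled|
  expect_true(rep_$significant[rep_$roi == "AverageFA"])
  expect_false(rep_$significant[rep_$roi == "CST"])
  expect_equal(rep_$significant, rep_$p < 0.002)
  # single-site moderator records pass through
  single <- make_records(1, mu = -0.001, se = 2e-4,
                         model_id = "mod_duration_years")
  mm <- meta_moderators(single)
  expect_equal(mm$pooled, single$estimate)
  expect_equal(mm$se, single$se)
})

test_that("forest data reproduces per-site CIs and the pooled summary", {
  rec <- make_records(6, mu = -0.4, se = 0.1, seed = 9)
  fd <- forest_data(rec, method = "DL")
  expect_equal(nrow(fd), 7L)
  expect_equal(fd$estimate[1:6], rec$estimate)
  expect_equal(fd$ci_high[1:6] - fd$estimate[1:6],
               rep(qnorm(0.975) * 0.1, 6))
  expect_equal(sum(fd$weight[1:6]), 1, tolerance = 1e-12)
  mr <- random_effects_meta(rec$estimate, rec$se, method = "DL")
  expect_equal(fd$estimate[7], mr$pooled)
})
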