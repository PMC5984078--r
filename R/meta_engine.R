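# Random-effects inverse-variance pooling with DerSimonian-Laird or REML
# between-site variance, Cochran's Q / I2 heterogeneity, Bonferroni control,
# and the cross-ROI secondary comparisons.

#' Random-effects inverse-variance meta-analysis of one set of estimates
#'
#' Pools per-site estimates `y_i` with standard errors `se_i`. Fixed-effect
#' weights `w_i = 1/se_i^2` give Cochran's
#' `Q = sum w_i (y_i - y_FE)^2`; the DerSimonian-Laird estimator is
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, and REML
#' maximizes the profiled restricted log-likelihood over `tau2 >= 0` to
#' tolerance `tol`. Random-effects
#' weights `w*_i = 1/(se_i^2 + tau2)` give the pooled estimate, its standard
#' error `(sum w*)^(-1/2)`, a two-sided normal p-value on `z = pooled/se`,
#' and `I2 = max(0, 100 (Q - (k-1))/Q)` (0 when `k = 1`).
#'
#' @param yi Numeric vector of estimates (Cohen's d or regression slopes).
#' @param sei Positive standard errors, same length.
#' @param method `"REML"` (default) or `"DL"`.
#' @param tol REML convergence tolerance.
#' @return Object of class `meta_result`: list with `k`, `pooled`,
#'   `se_pooled`, `z`, `p`, `tau2`, `Q`, `I2`, `ci_low`, `ci_high`,
#'   `method`, `weights` (random-effects weights, normalized).
#' @examples
#' random_effects_meta(c(0.3, 0.5), c(0.1, 0.1), method = "DL")
#' @export
random_effects_meta <- function(yi, sei, method = c("REML", "DL"),
                                tol = 1e-10) {
  method <- match.arg(method)
  k <- length(yi)
  if (k == 0L) stop("no records to pool")
  if (length(sei) != k) stop("yi and sei lengths differ")
  bad <- which(!is.finite(sei) | sei <= 0)
  if (length(bad))
    stop("non-positive standard error in record(s): ",
         paste(bad, collapse = ", "))
  w <- 1 / sei^2
  y_fe <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - y_fe)^2)
  if (k == 1L) {
    tau2 <- 0
  } else if (method == "DL") {
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  } else {
    # REML score in tau2; its root maximizes the restricted likelihood
    score <- function(tau2) {
      wi <- 1 / (sei^2 + tau2)
      mu <- sum(wi * yi) / sum(wi)
      sum(wi^2 * (yi - mu)^2) - sum(wi) + sum(wi^2) / sum(wi)
    }
    if (score(0) <= 0) {
      tau2 <- 0           # boundary solution: no between-site variance
    } else {
      upper <- max(stats::var(yi) * 10, max(sei)^2, 1e-6)
      while (score(upper) > 0) upper <- upper * 4
      tau2 <- stats::uniroot(score, c(0, upper), tol = tol)$root
    }
  }
  wr <- 1 / (sei^2 + tau2)
  pooled <- sum(wr * yi) / sum(wr)
  se_pooled <- sqrt(1 / sum(wr))
  z <- pooled / se_pooled
  i2 <- if (k == 1L || Q <= 0) 0 else max(0, 100 * (Q - (k - 1)) / Q)
  structure(list(k = k, pooled = pooled, se_pooled = se_pooled, z = z,
                 p = 2 * stats::pnorm(-abs(z)), tau2 = tau2, Q = Q, I2 = i2,
                 ci_low = pooled - stats::qnorm(0.975) * se_pooled,
                 ci_high = pooled + stats::qnorm(0.975) * se_pooled,
                 method = method, weights = wr / sum(wr)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "meta (%s, k=%d): pooled %.4f (se %.4f), 95%% CI [%.4f, %.4f], z=%.2f, p=%.3g, tau2=%.5f, Q=%.2f, I2=%.1f%%\n",
    x$method, x$k, x$pooled, x$se_pooled, x$ci_low, x$ci_high, x$z, x$p,
    x$tau2, x$Q, x$I2))
  invisible(x)
}

#' Bonferroni family-wise significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests in the family (>= 1). The primary ROI family has
#'   m = 25, giving 0.05/25 = 0.002.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 25) # 0.002
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Pool a site interchange table across sites
#'
#' Runs [random_effects_meta()] for every ROI x metric x model cell of a
#' site-level record table (case-control d values or moderator slopes) and
#' flags significance at the Bonferroni threshold. Report rows are sorted by
#' decreasing `|pooled|` within model, ties broken by ROI name.
#'
#' @param records data.frame in the site interchange schema (columns
#'   `site_id`, `roi`, `metric`, `model_id`, `estimate`, `se`, ...).
#' @param method Between-site variance estimator, `"REML"` or `"DL"`.
#' @param alpha,m Bonferroni family parameters (defaults 0.05 and 25).
#' @return data.frame with one row per pooled cell: `roi`, `metric`,
#'   `model_id`, `k`, `pooled`, `se`, `z`, `p`, `tau2`, `Q`, `I2`,
#'   `ci_low`, `ci_high`, `significant`.
#' @export
meta_pool <- function(records, method = c("REML", "DL"), alpha = 0.05,
                      m = 25L) {
  method <- match.arg(method)
  thr <- bonferroni_threshold(alpha, m)
  key <- interaction(records$roi, records$metric, records$model_id,
                     drop = TRUE)
  rows <- lapply(split(records, key), function(r) {
    mr <- random_effects_meta(r$estimate, r$se, method = method)
    data.frame(roi = r$roi[1], metric = r$metric[1], model_id = r$model_id[1],
               k = mr$k, pooled = mr$pooled, se = mr$se_pooled, z = mr$z,
               p = mr$p, tau2 = mr$tau2, Q = mr$Q, I2 = mr$I2,
               ci_low = mr$ci_low, ci_high = mr$ci_high,
               significant = mr$p < thr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$model_id, out$metric, -abs(out$pooled), out$roi), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Pool clinical moderator regressions across sites
#'
#' [meta_pool()] applied to moderator regression records: pooled slope,
#' standard error, Z and p per ROI, flagged at the applicable threshold.
#'
#' @inheritParams meta_pool
#' @export
meta_moderators <- function(records, method = c("REML", "DL"), alpha = 0.05,
                            m = 25L) {
  meta_pool(records, method = method, alpha = alpha, m = m)
}

#' Paired comparison of two per-ROI effect-size vectors
#'
#' Paired t test on per-ROI differences (e.g. female-only vs male-only
#' pooled effects across the 25 measures), df = number of ROIs - 1.
#'
#' @param d_a,d_b Numeric vectors paired by ROI, equal length >= 2.
#' @param labels Optional ROI labels for the summary.
#' @return List of class `comparison_result` with `description`,
#'   `statistic`, `df`, `p`, `mean_diff`.
#' @export
compare_effect_vectors <- function(d_a, d_b, labels = NULL) {
  stopifnot(length(d_a) == length(d_b), length(d_a) >= 2L)
  diffs <- d_a - d_b
  if (stats::sd(diffs) == 0)
    stop("zero-variance differences; paired statistic undefined")
  tt <- stats::t.test(d_a, d_b, paired = TRUE)
  structure(list(description = "paired t test on per-ROI effect differences",
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 mean_diff = mean(diffs), labels = labels),
            class = "comparison_result")
}

#' Correlation between effect sizes and the square root of ROI voxel counts
#'
#' Pearson correlation of per-ROI effect sizes with `sqrt(n_voxels)`,
#' reported both for the signed d and for its magnitude `|d|` (larger ROIs
#' tend to show larger case-control effects, a sampling-support artifact to
#' keep in mind when ranking regions).
#'
#' @param d Per-ROI effect sizes (length >= 3).
#' @param n_voxels Matching voxel counts.
#' @return List of class `comparison_result` with `r_abs`, `p_abs`,
#'   `r_signed`, `p_signed`, `df`.
#' @export
effectsize_voxelcount_correlation <- function(d, n_voxels) {
  stopifnot(length(d) == length(n_voxels), length(d) >= 3L)
  if (stats::sd(d) == 0 || stats::sd(n_voxels) == 0)
    stop("constant input; correlation undefined")
  sq <- sqrt(n_voxels)
  ca <- stats::cor.test(abs(d), sq)
  cs <- stats::cor.test(d, sq)
  structure(list(description = "effect size vs sqrt(voxel count) correlation",
                 r_abs = unname(ca$estimate), p_abs = ca$p.value,
                 r_signed = unname(cs$estimate), p_signed = cs$p.value,
                 df = unname(ca$parameter)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$description, "\n")
  if (!is.null(x$statistic))
    cat(sprintf("  t = %.4f, df = %d, p = %.4g\n", x$statistic, x$df, x$p))
  if (!is.null(x$r_abs))
    cat(sprintf("  r(|d|, sqrt N) = %.3f (p = %.3g); signed r = %.3f (p = %.3g)\n",
                x$r_abs, x$p_abs, x$r_signed, x$p_signed))
  invisible(x)
}

#' Meta-analysis within site subgroups plus a difference test
#'
#' Partitions sites by an attribute (e.g. high vs low gradient-direction
#' scanners), pools each group independently, and tests the difference of
#' pooled estimates with a normal z test
#' `z = (mu_1 - mu_2) / sqrt(se_1^2 + se_2^2)`. Groups with fewer than 2
#' sites are skipped with a warning.
#'
#' @param records Site interchange records for a single ROI x metric x model
#'   cell (one row per site).
#' @param site_groups Named character/factor vector mapping `site_id` to a
#'   group label, or a column name in `records`.
#' @param method Between-site variance estimator.
#' @return List with `groups` (named list of `meta_result`) and, when
#'   exactly two groups survive, `diff_z`, `diff_p`, `diff` (group 1 minus
#'   group 2).
#' @export
group_meta_compare <- function(records, site_groups,
                               method = c("REML", "DL")) {
  method <- match.arg(method)
  if (is.character(site_groups) && length(site_groups) == 1L &&
      site_groups %in% names(records)) {
    grp <- records[[site_groups]]
  } else {
    grp <- site_groups[records$site_id]
  }
  if (anyNA(grp)) stop("every site needs a group label")
  parts <- split(records, grp)
  keep <- vapply(parts, nrow, 1L) >= 2L
  if (any(!keep))
    warning("skipping group(s) with k < 2: ",
            paste(names(parts)[!keep], collapse = ", "))
  parts <- parts[keep]
  metas <- lapply(parts, function(r)
    random_effects_meta(r$estimate, r$se, method = method))
  out <- list(groups = metas)
  if (length(metas) == 2L) {
    m1 <- metas[[1]]; m2 <- metas[[2]]
    dz <- (m1$pooled - m2$pooled) / sqrt(m1$se_pooled^2 + m2$se_pooled^2)
    out$diff <- m1$pooled - m2$pooled
    out$diff_z <- dz
    out$diff_p <- 2 * stats::pnorm(-abs(dz))
  }
  out
}

#' Forest-plot data for one pooled cell
#'
#' Per-site estimate, 95% CI and normalized random-effects weight, plus a
#' summary row, in plotting-ready long form.
#'
#' @param records Site interchange records for one ROI x metric x model cell.
#' @param method Between-site variance estimator.
#' @return data.frame with columns `site_id`, `estimate`, `ci_low`,
#'   `ci_high`, `weight`; the last row (`site_id == "POOLED"`) is the summary.
#' @export
forest_data <- function(records, method = c("REML", "DL")) {
  method <- match.arg(method)
  mr <- random_effects_meta(records$estimate, records$se, method = method)
  zc <- stats::qnorm(0.975)
  out <- data.frame(site_id = records$site_id, estimate = records$estimate,
                    ci_low = records$estimate - zc * records$se,
                    ci_high = records$estimate + zc * records$se,
                    weight = mr$weights, stringsAsFactors = FALSE)
  rbind(out, data.frame(site_id = "POOLED", estimate = mr$pooled,
                        ci_low = mr$ci_low, ci_high = mr$ci_high,
                        weight = 1))
}
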