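# Per-site stage: covariate-adjusted group models per ROI x metric, Cohen's d
# with standard errors, moderator regressions, subgroup contrasts and
# dispersion comparisons. Sign convention throughout: patients lower => d < 0.

MIN_GROUP_N <- 10L

#' Covariate specification for the per-site group model
#'
#' The base covariate set is age, sex, age-by-sex, age squared and age
#' squared-by-sex (age is mean-centered within site before squaring, which
#' tames the collinearity between age and its square). Optionally one global
#' FA covariate and/or one diagnosis interaction term is added.
#'
#' @param adjust Additional global covariate: `"none"`, `"average_fa"`,
#'   `"core_fa"` or `"periphery_fa"`.
#' @param interaction Diagnosis interaction term: `"none"`, `"dx_age"` or
#'   `"dx_sex"`.
#' @param use_sex Include the sex terms (disabled for sex-stratified models).
#' @param model_id Optional explicit model id; derived from the terms
#'   otherwise.
#' @return Object of class `covariate_spec`.
#' @export
covariate_spec <- function(adjust = c("none", "average_fa", "core_fa",
                                      "periphery_fa"),
                           interaction = c("none", "dx_age", "dx_sex"),
                           use_sex = TRUE, model_id = NULL) {
  adjust <- match.arg(adjust)
  interaction <- match.arg(interaction)
  if (is.null(model_id)) {
    model_id <- "casecontrol"
    if (adjust != "none") model_id <- paste0(model_id, "_adj_",
                                             sub("_fa$", "", adjust))
    if (interaction != "none") model_id <- paste0(model_id, "_", interaction)
    if (!use_sex) model_id <- paste0(model_id, "_stratified")
  }
  structure(list(adjust = adjust, interaction = interaction,
                 use_sex = use_sex, model_id = model_id),
            class = "covariate_spec")
}

# design matrix for one site's rows; age centered within site
.design_matrix <- function(df, spec, group_col = "dx") {
  a <- df$age - mean(df$age)
  X <- cbind(`(Intercept)` = 1, dx = df[[group_col]], age = a, age2 = a^2)
  if (spec$use_sex) {
    m <- as.integer(df$sex == "M")
    X <- cbind(X, sexM = m, age_sex = a * m, age2_sex = a^2 * m)
  }
  if (spec$adjust != "none") {
    if (is.null(df[[spec$adjust]]))
      stop("adjustment covariate '", spec$adjust,
           "' not present; run add_global_covariates() first")
    X <- cbind(X, adj = df[[spec$adjust]])
    colnames(X)[ncol(X)] <- spec$adjust
  }
  if (spec$interaction == "dx_age") X <- cbind(X, dx_age = X[, "dx"] * a)
  if (spec$interaction == "dx_sex")
    X <- cbind(X, dx_sex = X[, "dx"] * as.integer(df$sex == "M"))
  X
}

# multi-response OLS via one QR shared by all outcome columns; returns the
# requested coefficient's estimate, se and t per outcome
.ols_multi <- function(X, Y, coef_name) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  df_res <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df_res
  xtx_inv <- chol2inv(qr.R(qrX))
  j <- match(coef_name, colnames(X))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  list(beta = B[j, ], se = se, t = B[j, ] / se, df = df_res,
       coef = B, sigma2 = sigma2)
}

#' Convert a diagnosis t statistic to Cohen's d with its standard error
#'
#' Large-sample conversion used for covariate-adjusted group contrasts:
#' `d = t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))` and
#' `se_d = sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))`.
#' In the plain two-group model this equals the classical pooled-s.d. Cohen's
#' d times `sqrt((n1 + n2) / df)`.
#'
#' @param t t statistic of the group coefficient (vectorized).
#' @param n1,n2 Group sizes (>= 2).
#' @param df Residual degrees of freedom of the fitted model (> 0).
#' @return data.frame with columns `d` and `se_d`.
#' @examples
#' cohens_d_from_t(2, 50, 50, 96) # d = 0.40825, se = 0.20211
#' @export
cohens_d_from_t <- function(t, n1, n2, df) {
  if (any(!is.finite(t))) stop("non-finite t statistic")
  stopifnot(all(n1 >= 2), all(n2 >= 2), all(df > 0))
  d <- t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  data.frame(d = d, se_d = se)
}

#' Fit the covariate-adjusted group model for one site, ROI and metric
#'
#' Ordinary least squares of the ROI measure on diagnosis plus the covariate
#' set, after listwise deletion of rows with missing outcome or covariates.
#' Requires at least `min_n` subjects per group after deletion. This is the
#' single-ROI reference interface; [site_effect_sizes()] runs the same fit
#' for many ROIs at once.
#'
#' @param data Subject-level data.frame (one site; a `site` argument selects
#'   one site from a multi-site table).
#' @param roi ROI name from the registry.
#' @param metric Metric tag (column prefix), default `"FA"`.
#' @param spec A [covariate_spec()].
#' @param site Optional site id to subset.
#' @param min_n Minimum subjects per group (default 10).
#' @return List with `t_diag`, `df`, `n_controls`, `n_patients`,
#'   `coefficients` (full table), `d` and `se_d`; or `NULL`, with a message
#'   stating the triggering rule, when a group falls below the cutoff.
#' @export
fit_group_model <- function(data, roi, metric = "FA",
                            spec = covariate_spec(), site = NULL,
                            min_n = MIN_GROUP_N) {
  if (!is.null(site)) data <- data[data$site_id == site, , drop = FALSE]
  ycol <- paste0(metric, "_", roi)
  if (is.null(data[[ycol]])) stop("no column ", ycol, " in data")
  need <- c(ycol, "age", "sex", "diagnosis",
            if (spec$adjust != "none") spec$adjust)
  keep <- stats::complete.cases(data[need])
  df1 <- data[keep, , drop = FALSE]
  df1$dx <- as.integer(df1$diagnosis == "patient")
  n1 <- sum(df1$dx == 0L); n2 <- sum(df1$dx == 1L)
  if (n1 < min_n || n2 < min_n) {
    message(sprintf("excluded: %d controls / %d patients below min_n=%d",
                    n1, n2, min_n))
    return(NULL)
  }
  X <- .design_matrix(df1, spec)
  fit <- stats::lm(df1[[ycol]] ~ X - 1)
  ct <- summary(fit)$coefficients
  rownames(ct) <- colnames(X)
  tgt <- switch(spec$interaction, none = "dx", dx_age = "dx_age",
                dx_sex = "dx_sex")
  t_diag <- ct["dx", "t value"]
  dd <- cohens_d_from_t(t_diag, n1, n2, fit$df.residual)
  list(t_diag = t_diag, t_target = ct[tgt, "t value"],
       beta_target = ct[tgt, "Estimate"], se_target = ct[tgt, "Std. Error"],
       target = tgt, df = fit$df.residual,
       n_controls = n1, n_patients = n2, coefficients = ct,
       d = dd$d, se_d = dd$se_d)
}

#' Per-site covariate-adjusted Cohen's d for every ROI
#'
#' Runs the group model of [fit_group_model()] in every site for a set of
#' ROIs, sharing one design factorization per site across ROI outcomes
#' (listwise deletion depends only on the covariates, so the design is
#' identical), and converts the diagnosis t statistics to Cohen's d.
#' Site-by-ROI cells where either group has fewer than `min_n` subjects
#' after deletion are excluded; exclusions are recorded in the
#' `"exclusions"` attribute with the triggering rule.
#'
#' @param data Multi-site subject-level data.frame.
#' @param metric Metric tag.
#' @param rois ROI names (default: full registry).
#' @param spec A [covariate_spec()].
#' @param subset_sex Optional `"M"` or `"F"` for sex-stratified models (sex
#'   terms are dropped from the design automatically).
#' @param min_n Minimum subjects per group.
#' @return data.frame in the site interchange schema: `site_id`, `roi`,
#'   `metric`, `model_id`, `estimate` (d), `se`, `stat` (t), `df`, `n1`
#'   (controls), `n2` (patients).
#' @export
site_effect_sizes <- function(data, metric = "FA", rois = NULL,
                              spec = covariate_spec(), subset_sex = NULL,
                              min_n = MIN_GROUP_N) {
  if (is.null(rois)) rois <- roi_registry()$roi
  if (!is.null(subset_sex)) {
    data <- data[data$sex == subset_sex, , drop = FALSE]
    spec <- covariate_spec(adjust = spec$adjust,
                           interaction = spec$interaction, use_sex = FALSE,
                           model_id = paste0(spec$model_id, "_",
                                             tolower(subset_sex)))
  }
  if (spec$adjust == "average_fa" && metric == "FA")
    rois <- setdiff(rois, "AverageFA")  # adjusting a measure for itself is void
  if (!length(rois)) stop("no ROIs left to fit under this specification")
  ycols <- paste0(metric, "_", rois)
  miss <- setdiff(ycols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  need <- c("age", "sex", "diagnosis", if (spec$adjust != "none") spec$adjust)
  rows <- list(); excl <- character(0)
  for (s in unique(data$site_id)) {
    df1 <- data[data$site_id == s, , drop = FALSE]
    df1 <- df1[stats::complete.cases(df1[need]), , drop = FALSE]
    df1$dx <- as.integer(df1$diagnosis == "patient")
    n1 <- sum(df1$dx == 0L); n2 <- sum(df1$dx == 1L)
    if (n1 < min_n || n2 < min_n) {
      excl <- c(excl, sprintf(
        "%s [%s]: %d controls / %d patients below min_n=%d",
        s, spec$model_id, n1, n2, min_n))
      next
    }
    Y <- as.matrix(df1[ycols])
    ok <- colSums(is.na(Y)) == 0L
    X <- .design_matrix(df1, spec)
    fit <- .ols_multi(X, Y[, ok, drop = FALSE],
                      switch(spec$interaction, none = "dx",
                             dx_age = "dx_age", dx_sex = "dx_sex"))
    if (spec$interaction == "none") {
      dd <- cohens_d_from_t(fit$t, n1, n2, fit$df)
      est <- dd$d; se <- dd$se_d
    } else {
      est <- fit$beta; se <- fit$se   # interaction slope, meta-analyzed as beta
    }
    rows[[s]] <- data.frame(site_id = s, roi = rois[ok], metric = metric,
                            model_id = spec$model_id, estimate = unname(est),
                            se = unname(se), stat = unname(fit$t),
                            df = fit$df, n1 = n1, n2 = n2,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site_id = character(), roi = character(),
                      metric = character(), model_id = character(),
                      estimate = numeric(), se = numeric(), stat = numeric(),
                      df = integer(), n1 = integer(), n2 = integer())
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Per-site clinical moderator regressions within the patient group
#'
#' OLS of the ROI measure on one clinical moderator plus sex (plus the full
#' centered age, age-squared and age-by-sex covariate set when
#' `include_age`), within patients only. `duration_pct` is illness duration expressed as the fraction of the
#' subject's lifetime, `duration_years / age`. The with-age and without-age
#' duration models carry distinct model ids so the pooled stage can contrast
#' them. Sites with fewer than `min_n` patients with a non-missing moderator
#' are excluded.
#'
#' @param data Multi-site subject-level data.frame.
#' @param moderator One of `age_at_onset`, `duration_years`, `duration_pct`,
#'   `cpz`, `panss_total`, `panss_pos`, `panss_neg`, `sans_total`,
#'   `saps_total`.
#' @param metric Metric tag.
#' @param rois ROI names (default: full registry).
#' @param include_age Add age terms to the model.
#' @param min_n Minimum patients per site.
#' @return data.frame in the site interchange schema (`estimate` = slope,
#'   `stat` = z = beta/se, `n1` = 0, `n2` = patients used), with exclusions
#'   in the `"exclusions"` attribute.
#' @export
moderator_regression <- function(data, moderator, metric = "FA", rois = NULL,
                                 include_age = FALSE, min_n = MIN_GROUP_N) {
  mods <- c("age_at_onset", "duration_years", "duration_pct", "cpz",
            "panss_total", "panss_pos", "panss_neg", "sans_total",
            "saps_total")
  moderator <- match.arg(moderator, mods)
  if (is.null(rois)) rois <- roi_registry()$roi
  ycols <- paste0(metric, "_", rois)
  data <- data[data$diagnosis == "patient", , drop = FALSE]
  if (moderator == "duration_pct")
    data$duration_pct <- data$duration_years / data$age
  model_id <- paste0("mod_", moderator, if (include_age) "_agecov" else "")
  rows <- list(); excl <- character(0)
  for (s in unique(data$site_id)) {
    df1 <- data[data$site_id == s, , drop = FALSE]
    df1 <- df1[stats::complete.cases(df1[c(moderator, "age", "sex")]), ,
               drop = FALSE]
    if (nrow(df1) < min_n) {
      excl <- c(excl, sprintf("%s [%s]: %d patients below min_n=%d",
                              s, model_id, nrow(df1), min_n))
      next
    }
    if (stats::sd(df1[[moderator]]) == 0)
      stop("constant moderator '", moderator, "' at ", s)
    a <- df1$age - mean(df1$age)
    m_ <- as.integer(df1$sex == "M")
    X <- cbind(`(Intercept)` = 1, mod = df1[[moderator]], sexM = m_)
    if (include_age)  # full nonlinear age/sex covariate set
      X <- cbind(X, age = a, age2 = a^2, age_sex = a * m_, age2_sex = a^2 * m_)
    Y <- as.matrix(df1[ycols])
    ok <- colSums(is.na(Y)) == 0L
    fit <- .ols_multi(X, Y[, ok, drop = FALSE], "mod")
    rows[[s]] <- data.frame(site_id = s, roi = rois[ok], metric = metric,
                            model_id = model_id, estimate = unname(fit$beta),
                            se = unname(fit$se), stat = unname(fit$t),
                            df = fit$df, n1 = 0L, n2 = nrow(df1),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site_id = character(), roi = character(),
                      metric = character(), model_id = character(),
                      estimate = numeric(), se = numeric(), stat = numeric(),
                      df = integer(), n1 = integer(), n2 = integer())
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Per-site subgroup contrasts within the patient group
#'
#' Cohen's d between patient subgroups (smokers vs nonsmokers, or a pair of
#' medication classes), via the same covariate-adjusted machinery as the
#' case-control model with diagnosis replaced by the subgroup indicator.
#' Contrasts where either subgroup has fewer than `min_n` members at a site
#' are skipped (recorded in the `"exclusions"` attribute) — small typical-
#' antipsychotic subgroups drop out naturally under this rule.
#'
#' @param data Multi-site subject-level data.frame.
#' @param grouping `"smoker"` or `"medication"`.
#' @param contrast For `grouping = "medication"`, the two classes compared,
#'   first minus second (default atypical vs unmedicated).
#' @param metric Metric tag.
#' @param rois ROI names.
#' @param min_n Minimum per subgroup.
#' @return data.frame in the site interchange schema (`n1` = reference
#'   subgroup, `n2` = indicator subgroup; d > 0 means the indicator subgroup
#'   is higher).
#' @export
subgroup_effect <- function(data, grouping = c("smoker", "medication"),
                            contrast = c("atypical", "none"), metric = "FA",
                            rois = NULL, min_n = MIN_GROUP_N) {
  grouping <- match.arg(grouping)
  if (is.null(rois)) rois <- roi_registry()$roi
  ycols <- paste0(metric, "_", rois)
  pat <- data[data$diagnosis == "patient", , drop = FALSE]
  if (grouping == "smoker") {
    pat <- pat[!is.na(pat$smoker), , drop = FALSE]
    pat$grp <- as.integer(pat$smoker)                 # smokers minus nonsmokers
    model_id <- "subgroup_smoker"
  } else {
    stopifnot(length(contrast) == 2L)
    pat <- pat[!is.na(pat$med_class) & pat$med_class %in% contrast, ,
               drop = FALSE]
    pat$grp <- as.integer(pat$med_class == contrast[1])  # first minus second
    model_id <- paste0("subgroup_med_", contrast[1], "_vs_", contrast[2])
  }
  rows <- list(); excl <- character(0)
  spec <- covariate_spec()
  for (s in unique(pat$site_id)) {
    df1 <- pat[pat$site_id == s, , drop = FALSE]
    df1 <- df1[stats::complete.cases(df1[c("age", "sex")]), , drop = FALSE]
    n0 <- sum(df1$grp == 0L); n1g <- sum(df1$grp == 1L)
    if (n0 < min_n || n1g < min_n) {
      excl <- c(excl, sprintf("%s [%s]: subgroup sizes %d/%d below min_n=%d",
                              s, model_id, n0, n1g, min_n))
      next
    }
    X <- .design_matrix(df1, spec, group_col = "grp")
    Y <- as.matrix(df1[ycols])
    ok <- colSums(is.na(Y)) == 0L
    fit <- .ols_multi(X, Y[, ok, drop = FALSE], "dx")
    dd <- cohens_d_from_t(fit$t, n0, n1g, fit$df)
    rows[[s]] <- data.frame(site_id = s, roi = rois[ok], metric = metric,
                            model_id = model_id, estimate = unname(dd$d),
                            se = unname(dd$se_d), stat = unname(fit$t),
                            df = fit$df, n1 = n0, n2 = n1g,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site_id = character(), roi = character(),
                      metric = character(), model_id = character(),
                      estimate = numeric(), se = numeric(), stat = numeric(),
                      df = integer(), n1 = integer(), n2 = integer())
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Compare dispersion of a measure between two groups
#'
#' Reports both sample standard deviations together with a two-sample
#' dispersion test: the variance-ratio F test (default) or a Brown-Forsythe
#' style test (two-sample t test on absolute deviations from the group
#' medians), robust to non-normality.
#'
#' @param x,y Numeric samples (patients and controls, say), length >= 2.
#' @param method `"F"` or `"levene"`.
#' @return List with `sd1`, `sd2`, `statistic`, `df`, `p`, `method`.
#' @export
variance_comparison <- function(x, y, method = c("F", "levene")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the samples")
  if (method == "F") {
    ft <- stats::var.test(x, y)
    list(sd1 = stats::sd(x), sd2 = stats::sd(y),
         statistic = unname(ft$statistic), df = unname(ft$parameter),
         p = ft$p.value, method = "F")
  } else {
    tt <- stats::t.test(abs(x - stats::median(x)), abs(y - stats::median(y)))
    list(sd1 = stats::sd(x), sd2 = stats::sd(y),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, method = "levene")
  }
}
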