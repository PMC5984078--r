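# Manifest-driven pipeline: simulate -> per-site stage -> meta stage ->
# report bundle, with a CSV interchange dialect for site summary tables and
# provenance recording. Floats are serialized with 17 significant digits so
# every schema round-trips to full double precision.

.fmt17 <- function(x) {
  if (!is.numeric(x)) return(x)
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- NA_character_
  out
}

.site_schema <- c("site_id", "roi", "metric", "model_id", "estimate", "se",
                  "stat", "df", "n1", "n2")

#' Write / read a site interchange table
#'
#' Fixed column order (`site_id, roi, metric, model_id, estimate, se, stat,
#' df, n1, n2`), UTF-8 CSV, floats at 17 significant digits (lossless
#' round-trip). This is the format the per-site stage exports and the meta
#' stage consumes, so real site summaries prepared elsewhere can be pooled
#' directly.
#'
#' @param records data.frame in the site interchange schema.
#' @param path CSV path.
#' @return `read_site_table` returns the records data.frame; the writer
#'   returns `path` invisibly.
#' @export
write_site_table <- function(records, path) {
  miss <- setdiff(.site_schema, names(records))
  if (length(miss)) stop("records missing columns: ",
                         paste(miss, collapse = ", "))
  out <- records[.site_schema]
  for (col in c("estimate", "se", "stat")) out[[col]] <- .fmt17(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(site_id = "character"))
  miss <- setdiff(.site_schema, names(d))
  if (length(miss)) stop(path, ": missing columns ",
                         paste(miss, collapse = ", "))
  for (col in c("estimate", "se", "stat")) d[[col]] <- as.numeric(d[[col]])
  d
}

#' Read all site interchange tables in a directory
#'
#' @param dir Directory containing `records_*.csv` files.
#' @return Combined records data.frame.
#' @export
read_site_tables <- function(dir) {
  files <- list.files(dir, pattern = "^records_.*\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no records_*.csv files in ", dir)
  do.call(rbind, lapply(files, read_site_table))
}

#' Validate a site interchange CSV without mutating it
#'
#' Checks the schema, positive standard errors, finite estimates and the
#' minimum-10-per-group inclusion rule, returning one message per violation
#' naming the file, row and column.
#'
#' @param path CSV path.
#' @return Character vector of violations (length 0 when well formed).
#' @export
validate_site_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- character(0)
  miss <- setdiff(.site_schema, names(d))
  if (length(miss))
    return(sprintf("%s: missing column '%s'", path, miss))
  for (col in c("estimate", "se")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(!is.finite(v))
    out <- c(out, sprintf("%s: row %d column '%s' is not a finite number",
                          path, bad, col))
    if (col == "se") {
      nonpos <- which(is.finite(v) & v <= 0)
      out <- c(out, sprintf("%s: row %d has se <= 0", path, nonpos))
    }
  }
  cc <- grepl("^casecontrol", d$model_id) | grepl("^subgroup", d$model_id)
  small <- which(cc & (d$n1 < MIN_GROUP_N | d$n2 < MIN_GROUP_N))
  out <- c(out, sprintf(
    "%s: row %d group size below the minimum of %d per group",
    path, small, MIN_GROUP_N))
  out
}

#' Study manifest
#'
#' Configuration of one full pipeline run: generator settings (or a
#' directory of existing subject tables), the model families to run, the
#' significance family (`alpha`, `m`), the between-site variance estimator
#' and the seed. `read_manifest()` loads a YAML file with the same fields.
#'
#' @param name Run label.
#' @param seed Integer seed for the whole run.
#' @param alpha,m Bonferroni family parameters.
#' @param tau2_method `"REML"` or `"DL"`.
#' @param generator List of [generator_config()] arguments.
#' @param models List with entries `case_control` (metrics), `global_adjust`
#'   (subset of average/core/periphery), `interactions` (subset of
#'   `dx_age`, `dx_sex`), `sex_stratified` (flag), `moderators` (moderator
#'   names, suffix `_agecov` adds age terms), `subgroups` (subset of
#'   `smoker`, `medication`).
#' @param site_attributes Optional named list mapping site ids to attribute
#'   lists (e.g. gradient-direction class) for subgroup meta-comparisons.
#' @param out_dir Output directory of [run_pipeline()].
#' @return Object of class `study_manifest`.
#' @export
study_manifest <- function(name = "study", seed = 1L, alpha = 0.05, m = 25L,
                           tau2_method = "REML",
                           generator = list(),
                           models = list(),
                           site_attributes = NULL,
                           out_dir = tempfile("dtimeta_run_")) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  tau2_method <- match.arg(tau2_method, c("REML", "DL"))
  models <- utils::modifyList(list(
    case_control = "FA",
    global_adjust = character(0),
    interactions = character(0),
    sex_stratified = FALSE,
    moderators = character(0),
    subgroups = character(0)), models)
  ids <- .manifest_model_ids(models)
  if (anyDuplicated(ids)) stop("duplicate model ids in manifest: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  structure(list(name = name, seed = as.integer(seed), alpha = alpha,
                 m = as.integer(m), tau2_method = tau2_method,
                 generator = generator, models = models,
                 site_attributes = site_attributes, out_dir = out_dir),
            class = "study_manifest")
}

.manifest_model_ids <- function(models) {
  c(paste0("casecontrol_", models$case_control),
    if (length(models$global_adjust))
      paste0("casecontrol_adj_", sub("_fa$", "", models$global_adjust)),
    if (length(models$interactions))
      paste0("casecontrol_", models$interactions),
    if (isTRUE(models$sex_stratified)) c("casecontrol_m", "casecontrol_f"),
    if (length(models$moderators)) paste0("mod_", models$moderators),
    if (length(models$subgroups)) paste0("subgroup_", models$subgroups))
}

#' @rdname study_manifest
#' @param path YAML manifest path.
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(study_manifest, y[intersect(names(y), names(formals(study_manifest)))])
}

#' @rdname study_manifest
#' @param manifest Manifest to write.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

#' Pipeline stages
#'
#' The three stages composed by [run_pipeline()], usable independently:
#' `pipeline_simulate` generates the subject-level data named by the
#' manifest; `pipeline_site` runs every configured per-site model and emits
#' the combined interchange records; `pipeline_meta` pools the records and
#' shapes the report tables.
#'
#' @param manifest A `study_manifest`.
#' @return `pipeline_simulate`: subject-level data.frame.
#' @export
pipeline_simulate <- function(manifest) {
  gen <- manifest$generator
  gen$seed <- manifest$seed
  cfg <- do.call(generator_config, gen)
  generate_multisite(cfg)
}

#' @rdname pipeline_simulate
#' @param data Subject-level data.frame.
#' @return `pipeline_site`: records data.frame (interchange schema) with an
#'   `"exclusions"` attribute aggregating per-model exclusion logs.
#' @export
pipeline_site <- function(data, manifest) {
  mod <- manifest$models
  parts <- list(); excl <- character(0)
  grab <- function(x) { excl <<- c(excl, attr(x, "exclusions")); x }
  for (met in mod$case_control)
    parts[[paste0("cc_", met)]] <- grab(site_effect_sizes(
      data, metric = met,
      spec = covariate_spec(model_id = paste0("casecontrol_", met))))
  if (length(mod$global_adjust)) {
    data <- add_global_covariates(data)
    for (adj in mod$global_adjust)
      parts[[paste0("adj_", adj)]] <- grab(site_effect_sizes(
        data, spec = covariate_spec(adjust = adj)))
  }
  for (ia in mod$interactions)
    parts[[paste0("ia_", ia)]] <- grab(site_effect_sizes(
      data, spec = covariate_spec(interaction = ia)))
  if (isTRUE(mod$sex_stratified))
    for (sx in c("M", "F"))
      parts[[paste0("strat_", sx)]] <- grab(site_effect_sizes(
        data, subset_sex = sx,
        spec = covariate_spec(model_id = "casecontrol")))
  for (md in mod$moderators) {
    include_age <- grepl("_agecov$", md)
    parts[[paste0("mod_", md)]] <- grab(moderator_regression(
      data, sub("_agecov$", "", md), include_age = include_age))
  }
  for (sg in mod$subgroups)
    parts[[paste0("sub_", sg)]] <- grab(subgroup_effect(data, grouping = sg))
  out <- do.call(rbind, unname(parts))
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' @rdname pipeline_simulate
#' @param records Site interchange records.
#' @return `pipeline_meta`: list with `report` (all pooled cells), `table1`
#'   (primary FA case-control shape: roi, d, se, p, I2, n_voxels),
#'   `table2` (duration-moderator shape, when run) and `forest` (per-site
#'   forest data for the primary model, keyed by ROI).
#' @export
pipeline_meta <- function(records, manifest) {
  report <- meta_pool(records, method = manifest$tau2_method,
                      alpha = manifest$alpha, m = manifest$m)
  reg <- roi_registry()
  t1 <- report[report$model_id == "casecontrol_FA", ]
  table1 <- data.frame(roi = t1$roi, d = t1$pooled, se = t1$se, p = t1$p,
                       I2 = t1$I2,
                       n_voxels = reg$n_voxels[match(t1$roi, reg$roi)],
                       significant = t1$significant,
                       stringsAsFactors = FALSE)
  t2 <- report[report$model_id == "mod_duration_years", ]
  table2 <- if (nrow(t2)) data.frame(
    roi = t2$roi, z = t2$z, beta = t2$pooled, se = t2$se, p = t2$p,
    significant = t2$significant, stringsAsFactors = FALSE) else NULL
  cc <- records[records$model_id == "casecontrol_FA", ]
  forest <- if (nrow(cc)) lapply(
    split(cc, cc$roi), forest_data, method = manifest$tau2_method) else NULL
  list(report = report, table1 = table1, table2 = table2, forest = forest)
}

#' Run the full two-stage pipeline from a manifest
#'
#' Executes simulate (or load) -> per-site models -> random-effects
#' meta-analysis -> report rendering, writing per-site interchange CSVs, the
#' primary-report CSVs, per-ROI forest-plot data, an exclusion log, and a
#' provenance record (manifest hash, seed, package and R versions). Rerunning
#' the same manifest reproduces identical outputs.
#'
#' @param manifest A `study_manifest` (or path to a YAML manifest).
#' @param data Optional pre-built subject table; bypasses the generator.
#' @return Invisibly, a list with `data`, `records`, `report`, `table1`,
#'   `table2`, `forest`, `out_dir` and `provenance`.
#' @export
run_pipeline <- function(manifest, data = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "study_manifest"))
  dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(data)) data <- pipeline_simulate(manifest)
  if (!is.null(manifest$site_attributes)) {
    bad <- setdiff(names(manifest$site_attributes), unique(data$site_id))
    if (length(bad)) stop("manifest references unknown site(s): ",
                          paste(bad, collapse = ", "))
  }
  records <- pipeline_site(data, manifest)
  for (s in unique(records$site_id))
    write_site_table(records[records$site_id == s, ],
                     file.path(manifest$out_dir,
                               paste0("records_", s, ".csv")))
  res <- pipeline_meta(records, manifest)
  .write_report_csv <- function(df, name) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], .fmt17)
    utils::write.csv(df, file.path(manifest$out_dir, name), row.names = FALSE)
  }
  .write_report_csv(res$report, "meta_report.csv")
  .write_report_csv(res$table1, "table1_casecontrol_fa.csv")
  if (!is.null(res$table2)) .write_report_csv(res$table2,
                                              "table2_duration.csv")
  if (!is.null(res$forest))
    for (r in names(res$forest))
      .write_report_csv(res$forest[[r]],
                        paste0("forest_casecontrol_FA_", r, ".csv"))
  writeLines(attr(records, "exclusions") %||% character(0),
             file.path(manifest$out_dir, "exclusions.log"))
  mpath <- file.path(manifest$out_dir, "manifest.yaml")
  write_manifest(manifest, mpath)
  prov <- list(manifest_md5 = unname(tools::md5sum(mpath)),
               seed = manifest$seed,
               package = as.character(utils::packageVersion("dtimeta")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               threshold = bonferroni_threshold(manifest$alpha, manifest$m))
  yaml::write_yaml(prov, file.path(manifest$out_dir, "provenance.yaml"))
  invisible(list(data = data, records = records, report = res$report,
                 table1 = res$table1, table2 = res$table2,
                 forest = res$forest, out_dir = manifest$out_dir,
                 provenance = prov))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled demonstration manifest
#'
#' A small six-site run exercising every model family, used by the examples
#' and the command-line `run` subcommand.
#'
#' @param out_dir Output directory.
#' @param seed Seed.
#' @return A `study_manifest`.
#' @export
demo_manifest <- function(out_dir = tempfile("dtimeta_demo_"), seed = 7L) {
  study_manifest(
    name = "demo", seed = seed, out_dir = out_dir,
    generator = list(n_sites = 6L, n_controls = c(40L, 90L),
                     n_patients = c(40L, 90L), site_scale_sd = 0.03,
                     coverage = list(onset = 6L, duration = 6L, cpz = 6L,
                                     panss = 6L, sans = 6L, saps = 6L,
                                     smoking = 6L, med = 6L)),
    models = list(case_control = "FA",
                  global_adjust = "average_fa",
                  interactions = c("dx_age", "dx_sex"),
                  sex_stratified = TRUE,
                  moderators = c("duration_years", "duration_years_agecov",
                                 "age_at_onset", "cpz", "panss_total"),
                  subgroups = "smoker"))
}
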