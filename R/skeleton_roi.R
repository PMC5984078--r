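#' Atlas label object for a flat skeleton
#'
#' Labels every skeleton voxel with either a leaf tract ROI (optionally with a
#' hemisphere suffix `_L`/`_R`, combined downstream) or the `"PERIPHERY"`
#' sentinel for skeleton voxels outside the atlas-defined tract core.
#' Indexing is flat: voxel geometry is irrelevant for ROI means.
#'
#' @param labels Character vector, one entry per voxel.
#' @return An object of class `atlas_labels` with elements `labels`,
#'   `n_voxels` and `voxel_counts` (per bilaterally-combined leaf ROI).
#' @export
atlas_labels <- function(labels) {
  stopifnot(is.character(labels), length(labels) > 0L, !anyNA(labels))
  base <- sub("_[LR]$", "", labels)
  known <- c(roi_leaves(), "PERIPHERY")
  bad <- setdiff(unique(base), known)
  if (length(bad))
    stop("unknown atlas labels: ", paste(bad, collapse = ", "))
  counts <- table(factor(base[base != "PERIPHERY"], levels = roi_leaves()))
  structure(list(labels = labels,
                 base_labels = base,
                 n_voxels = length(labels),
                 voxel_counts = c(counts)),
            class = "atlas_labels")
}

#' Build a small synthetic skeleton atlas
#'
#' Allocates `n_voxels` flat skeleton voxels to the 21 leaf tract ROIs and the
#' periphery, with ROI sizes proportional to the registry voxel counts (so the
#' core/periphery split matches the full-size skeleton's proportions: the
#' tract core covers about 28% of skeleton voxels). Each leaf ROI is split
#' into `_L`/`_R` hemisphere halves. Every ROI receives at least one voxel per
#' hemisphere. Intended as a test- and demo-scale stand-in for the full
#' 112 889-voxel template, which is not shipped.
#'
#' @param n_voxels Total number of skeleton voxels (default 2000).
#' @return An `atlas_labels` object.
#' @export
synthetic_atlas <- function(n_voxels = 2000L) {
  stopifnot(n_voxels >= 2L * length(roi_leaves()) + 1L)
  reg <- roi_registry()
  leaves <- reg[reg$type == "leaf", ]
  total <- reg$n_voxels[reg$roi == "AverageFA"]
  per_roi <- pmax(2L, round(n_voxels * leaves$n_voxels / total))
  per_roi <- per_roi + (per_roi %% 2L)         # even, so hemispheres split
  if (sum(per_roi) > n_voxels - 1L)
    stop("n_voxels too small for proportional allocation")
  labs <- unlist(mapply(function(roi, k) {
    c(rep(paste0(roi, "_L"), k / 2L), rep(paste0(roi, "_R"), k / 2L))
  }, leaves$roi, per_roi, SIMPLIFY = FALSE), use.names = FALSE)
  labs <- c(labs, rep("PERIPHERY", n_voxels - length(labs)))
  atlas_labels(labs)
}

#' Skeleton volume of voxelwise diffusion values
#'
#' @param values Numeric vector of voxel values, aligned with an atlas.
#' @param metric Metric tag, one of `"FA"`, `"MD"`, `"AD"`, `"RD"`.
#' @return Object of class `skeleton_volume`.
#' @export
skeleton_volume <- function(values, metric = "FA") {
  stopifnot(is.numeric(values), length(values) > 0L)
  metric <- match.arg(metric, c("FA", "MD", "AD", "RD"))
  if (metric == "FA" && any(values < 0 | values > 1, na.rm = TRUE))
    stop("FA voxel values must lie in [0, 1]")
  structure(list(values = as.numeric(values), metric = metric),
            class = "skeleton_volume")
}

#' Simulate one subject's skeleton volume
#'
#' Draws voxel values around per-ROI means: value = ROI mean + subject shift +
#' Gaussian voxel noise. Periphery voxels use the `PERIPHERY` entry of
#' `roi_mean` (or the mean of the supplied ROI means when absent).
#'
#' @param atlas An `atlas_labels` object.
#' @param roi_mean Named numeric vector of means for leaf ROIs (hemisphere
#'   suffixes not used) and optionally `PERIPHERY`.
#' @param subject_shift Additive subject-level offset (default 0).
#' @param noise_sd Voxel noise standard deviation (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @param metric Metric tag.
#' @return A `skeleton_volume`.
#' @export
generate_skeleton_subject <- function(atlas, roi_mean, subject_shift = 0,
                                      noise_sd = 0.02, seed = NULL,
                                      metric = "FA") {
  stopifnot(inherits(atlas, "atlas_labels"), noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (!"PERIPHERY" %in% names(roi_mean))
    roi_mean <- c(roi_mean, PERIPHERY = mean(roi_mean))
  missing_rois <- setdiff(unique(atlas$base_labels), names(roi_mean))
  if (length(missing_rois))
    stop("roi_mean missing entries for: ", paste(missing_rois, collapse = ", "))
  mu <- roi_mean[atlas$base_labels] + subject_shift
  vals <- mu + stats::rnorm(atlas$n_voxels, 0, noise_sd)
  if (metric == "FA") vals <- pmin(pmax(vals, 0), 1)
  skeleton_volume(vals, metric = metric)
}

#' Per-ROI means of a skeleton volume
#'
#' Arithmetic mean of each ROI's voxels. Hemisphere-specific labels are
#' combined by pooling the voxels of both hemispheres, i.e. a
#' voxel-count-weighted average of the two hemisphere means. Composite ROIs
#' (CC, CR, IC) are voxel-count-weighted means of their components. ROIs with
#' no voxels in the atlas are reported as `NA` (missing), never zero.
#'
#' @param volume A `skeleton_volume`.
#' @param atlas An `atlas_labels` object of matching length.
#' @return data.frame with columns `roi`, `mean`, `n_voxels` covering the 24
#'   tract ROIs of the registry.
#' @export
roi_means <- function(volume, atlas) {
  stopifnot(inherits(volume, "skeleton_volume"), inherits(atlas, "atlas_labels"))
  if (length(volume$values) != atlas$n_voxels)
    stop("volume length (", length(volume$values),
         ") does not match atlas (", atlas$n_voxels, ")")
  core <- atlas$base_labels != "PERIPHERY"
  f <- factor(atlas$base_labels[core], levels = roi_leaves())
  sums <- tapply(volume$values[core], f, sum, default = NA_real_)
  ns <- tabulate(f, nbins = nlevels(f))
  leaf <- data.frame(roi = roi_leaves(),
                     mean = as.numeric(sums) / ifelse(ns == 0L, NA_real_, ns),
                     n_voxels = ns, stringsAsFactors = FALSE)
  comp <- roi_components()
  comp_rows <- do.call(rbind, lapply(names(comp), function(cc) {
    part <- leaf[leaf$roi %in% comp[[cc]], ]
    n <- sum(part$n_voxels)
    m <- if (n > 0L && !anyNA(part$mean))
      sum(part$mean * part$n_voxels) / n else NA_real_
    data.frame(roi = cc, mean = m, n_voxels = n, stringsAsFactors = FALSE)
  }))
  out <- rbind(leaf, comp_rows)
  reg_order <- roi_registry()$roi
  out <- out[order(match(out$roi, reg_order)), ]
  rownames(out) <- NULL
  out
}

#' Average / core / periphery decomposition of a skeleton volume
#'
#' Splits the whole-skeleton average into the atlas-labeled tract "core" and
#' the unlabeled "periphery" (everything on the skeleton outside the atlas
#' ROIs), the three global covariates used to separate regional from global
#' effects. Satisfies the exact reconstruction identity
#' `n_total * average == n_core * core + n_periphery * periphery`.
#'
#' @inheritParams roi_means
#' @return List of class `roi_summary` with `average`, `core`, `periphery`,
#'   `n_total`, `n_core`, `n_periphery` and the `roi_means` table.
#' @export
decompose_core_periphery <- function(volume, atlas) {
  stopifnot(inherits(volume, "skeleton_volume"), inherits(atlas, "atlas_labels"))
  if (length(volume$values) != atlas$n_voxels)
    stop("volume length does not match atlas")
  is_core <- atlas$base_labels != "PERIPHERY"
  n_core <- sum(is_core)
  n_per <- sum(!is_core)
  avg <- mean(volume$values)
  core <- if (n_core > 0L) mean(volume$values[is_core]) else NA_real_
  periphery <- if (n_per > 0L) mean(volume$values[!is_core]) else NA_real_
  if (n_per == 0L)
    warning("atlas has no periphery voxels; periphery mean reported missing")
  structure(list(average = avg, core = core, periphery = periphery,
                 n_total = atlas$n_voxels, n_core = n_core,
                 n_periphery = n_per,
                 roi_means = roi_means(volume, atlas)),
            class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf(
    "skeleton summary: average %.4f (n=%d), core %.4f (n=%d), periphery %s (n=%d)\n",
    x$average, x$n_total, x$core, x$n_core,
    ifelse(is.na(x$periphery), "NA", sprintf("%.4f", x$periphery)),
    x$n_periphery))
  invisible(x)
}

#' Write / read atlas and volume CSV files
#'
#' Flat CSV interchange: `voxel_id,label` for atlases and `voxel_id,value`
#' for volumes, 0-based voxel ids, full double precision.
#'
#' @param atlas,volume Objects to write.
#' @param path Output file path.
#' @return `read_atlas_csv` returns an `atlas_labels`; `read_volume_csv` a
#'   `skeleton_volume`; the writers return `path` invisibly.
#' @name skeleton_io
#' @export
write_atlas_csv <- function(atlas, path) {
  stopifnot(inherits(atlas, "atlas_labels"))
  utils::write.csv(data.frame(voxel_id = seq_along(atlas$labels) - 1L,
                              label = atlas$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname skeleton_io
#' @export
read_atlas_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  atlas_labels(d$label[order(d$voxel_id)])
}

#' @rdname skeleton_io
#' @param metric Metric tag for the volume being read.
#' @export
write_volume_csv <- function(volume, path) {
  stopifnot(inherits(volume, "skeleton_volume"))
  utils::write.csv(data.frame(voxel_id = seq_along(volume$values) - 1L,
                              value = .fmt17(volume$values)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname skeleton_io
#' @export
read_volume_csv <- function(path, metric = "FA") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  skeleton_volume(as.numeric(d$value[order(d$voxel_id)]), metric = metric)
}
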