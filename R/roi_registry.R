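#' ROI registry for white-matter skeleton measures
#'
#' The analysis operates on 25 measures: the whole-skeleton average plus 24
#' bilaterally combined tract ROIs of the JHU white-matter atlas. Three of the
#' tract ROIs are composites of smaller ones (the full corpus callosum and the
#' full corona radiata / internal capsule); their voxel counts equal the sum of
#' their components. `n_voxels` is the number of skeleton voxels contributing
#' to each measure; `d_fa`, `se_fa` and `i2_fa` are reference case-control
#' fractional-anisotropy effect sizes (patients minus controls) used as the
#' default truth of the synthetic-cohort generator.
#'
#' @return A data.frame with one row per measure and columns `roi`,
#'   `n_voxels`, `d_fa`, `se_fa`, `i2_fa` and `type`
#'   (`"global"`, `"composite"` or `"leaf"`).
#' @examples
#' reg <- roi_registry()
#' nrow(reg) # 25 measures
#' @export
roi_registry <- function() {
  reg <- data.frame(
    roi = c("AverageFA", "ACR", "CC", "BCC", "GCC", "ALIC", "CR", "FXST",
            "FX", "PTR", "SS", "SFO", "CGC", "PCR", "SCC", "SLF", "EC",
            "IC", "UNC", "SCR", "RLIC", "IFO", "CGH", "CST", "PLIC"),
    n_voxels = c(112889L, 3129L, 7318L, 3173L, 1834L, 1510L, 7344L, 706L,
                 222L, 1987L, 1294L, 193L, 594L, 1437L, 2311L, 3503L, 2896L,
                 4781L, 125L, 2778L, 1496L, 88L, 524L, 167L, 1775L),
    d_fa = c(-0.42, -0.40, -0.40, -0.39, -0.37, -0.37, -0.33, -0.32,
             -0.31, -0.31, -0.30, -0.29, -0.27, -0.25, -0.22, -0.22, -0.21,
             -0.18, -0.16, -0.15, -0.13, -0.11, -0.11, -0.04, 0.04),
    se_fa = c(0.042, 0.045, 0.045, 0.045, 0.042, 0.046, 0.040, 0.042,
              0.045, 0.035, 0.040, 0.054, 0.045, 0.036, 0.048, 0.040, 0.040,
              0.042, 0.033, 0.034, 0.041, 0.038, 0.041, 0.038, 0.046),
    i2_fa = c(34.65, 43.83, 42.51, 43.24, 35.22, 46.30, 27.89, 36.39,
              43.25, 11.78, 30.34, 59.68, 42.87, 15.76, 50.94, 29.17, 31.01,
              36.25, 4.18, 7.84, 33.10, 22.70, 33.73, 24.20, 46.20),
    stringsAsFactors = FALSE
  )
  reg$type <- "leaf"
  reg$type[reg$roi == "AverageFA"] <- "global"
  reg$type[reg$roi %in% names(roi_components())] <- "composite"
  reg
}

#' Composite ROI definitions
#'
#' Maps each composite tract ROI to the leaf ROIs whose voxel union it covers:
#' corpus callosum = genu + body + splenium; corona radiata and internal
#' capsule = their anterior/superior-or-retrolenticular/posterior parts.
#'
#' @return Named list of character vectors of component ROI names.
#' @export
roi_components <- function() {
  list(CC = c("GCC", "BCC", "SCC"),
       CR = c("ACR", "SCR", "PCR"),
       IC = c("ALIC", "PLIC", "RLIC"))
}

#' Leaf tract ROI names
#'
#' The tract ROIs that label skeleton voxels directly (composites and the
#' whole-skeleton average excluded).
#'
#' @return Character vector of 21 ROI names.
#' @export
roi_leaves <- function() {
  reg <- roi_registry()
  reg$roi[reg$type == "leaf"]
}

#' Reference cohort bookkeeping
#'
#' Group sizes of the multi-site reference study design the generator
#' emulates: 29 cohorts totalling 2359 healthy controls and 1963 patients.
#'
#' @return Named integer vector with elements `controls`, `patients`, `sites`.
#' @export
cohort_sizes <- function() {
  c(controls = 2359L, patients = 1963L, sites = 29L)
}
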