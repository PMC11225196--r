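#' Region atlas for simulated regional morphometry
#'
#' A `region_atlas` describes the 34 cortical thickness regions (mm) and 17
#' subcortical volumes (mm^3), bilaterally averaged, that make up the
#' 51-feature morphometry panel, together with the parameters the synthetic
#' cohort generator needs per region: a healthy-elderly reference mean and SD,
#' a disease effect size (fraction of the healthy mean lost at full disease
#' expression, i.e. latent severity 1), a linear age slope (units/year) and,
#' for volumes only, a head-size (eTIV) slope (mm^3 per mm^3 eTIV).
#'
#' Disease expression is staged: a region only begins to atrophy once latent
#' severity exceeds its `onset`, following the canonical spread of
#' Alzheimer-type atrophy from the medial temporal lobe (onset 0) outward
#' into association and finally primary cortex. The realized fraction lost
#' is `effect * g(s)` with `g(s) = min(1, max(0, (s - onset) / span))`:
#' early regions saturate (atrophy floors) while later regions are still
#' catching up.
#'
#' @param cortical data.frame with columns `region`, `ref_mean`, `ref_sd`,
#'   `effect`, `age_slope` and optionally `onset` describing thickness
#'   regions.
#' @param subcortical data.frame with the same columns plus `etiv_slope`
#'   describing volumetric structures.
#' @return An object of class `region_atlas`: a data.frame with columns
#'   `region`, `type` (`"thickness"` or `"volume"`), `ref_mean`, `ref_sd`,
#'   `effect`, `onset`, `span`, `age_slope`, `etiv_slope`.
#' @seealso [default_atlas()]
#' @export
region_atlas <- function(cortical, subcortical) {
  need <- c("region", "ref_mean", "ref_sd", "effect", "age_slope")
  stopifnot(all(need %in% names(cortical)),
            all(c(need, "etiv_slope") %in% names(subcortical)))
  for (d in c("cortical", "subcortical")) {
    tab <- get(d)
    if (is.null(tab$onset)) tab$onset <- 0
    if (is.null(tab$span)) tab$span <- 1 - tab$onset
    assign(d, tab)
  }
  if (nrow(cortical) != 34L || nrow(subcortical) != 17L) {
    stop("atlas must have exactly 34 cortical and 17 subcortical regions")
  }
  cortical$type <- "thickness"
  cortical$etiv_slope <- 0
  subcortical$type <- "volume"
  cols <- c("region", "type", "ref_mean", "ref_sd", "effect", "onset",
            "span", "age_slope", "etiv_slope")
  atlas <- rbind(cortical[, cols], subcortical[, cols])
  if (anyDuplicated(atlas$region)) stop("region names must be unique")
  if (any(atlas$effect < 0)) stop("disease effect sizes must be >= 0")
  if (any(atlas$onset < 0 | atlas$onset >= 1) || any(atlas$span <= 0)) {
    stop("onset must lie in [0, 1) and span must be positive")
  }
  if (any(atlas$ref_mean <= 0) || any(atlas$ref_sd <= 0)) {
    stop("reference means and SDs must be positive")
  }
  rownames(atlas) <- NULL
  class(atlas) <- c("region_atlas", "data.frame")
  atlas
}

#' Default region atlas
#'
#' The default atlas uses the 34 Desikan-Killiany cortical parcels and a
#' 17-structure subcortical panel of bilaterally averaged segmentation
#' volumes (thalamus, caudate, putamen, pallidum, hippocampus, amygdala,
#' accumbens, ventral diencephalon, the four ventricular measures and the
#' five corpus-callosum segments). The subcortical list is a documented
#' stand-in: it has the correct count and a plausible composition for a
#' FreeSurfer-style panel after dropping whole-tissue summaries, brainstem
#' and cerebellum.
#'
#' Disease effect sizes are largest in the medial-temporal circuit
#' (hippocampus, entorhinal cortex, amygdala, inferior temporal gyrus),
#' moderate in adjacent temporo-parietal cortex and small in primary
#' sensorimotor/occipital regions, emulating the canonical early-AD atrophy
#' topography. The hippocampal and entorhinal reference means and effect
#' sizes are calibrated so that, under the default [cohort_spec()] severity
#' distributions and trajectories, simulated CN means are about
#' 3852.8 mm^3 / 2.95 mm and amyloid-positive aMCI means about
#' 3068.3 mm^3 / 2.37 mm, typical of an amyloid-stratified memory-clinic
#' cohort. Ventricular effect sizes are 0:
#' disease-related ventricular expansion is outside the multiplicative
#' tissue-loss model (see the methods vignette).
#'
#' @return A [region_atlas()] object with 51 rows.
#' @examples
#' atlas <- default_atlas()
#' table(atlas$type)
#' @export
default_atlas <- function() {
  cort <- data.frame(
    region = c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
               "cuneus", "entorhinal", "fusiform", "inferiorparietal",
               "inferiortemporal", "isthmuscingulate", "lateraloccipital",
               "lateralorbitofrontal", "lingual", "medialorbitofrontal",
               "middletemporal", "parahippocampal", "paracentral",
               "parsopercularis", "parsorbitalis", "parstriangularis",
               "pericalcarine", "postcentral", "posteriorcingulate",
               "precentral", "precuneus", "rostralanteriorcingulate",
               "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
               "superiortemporal", "supramarginal", "temporalpole",
               "transversetemporal", "insula", "frontalpole"),
    ref_mean = c(2.40, 2.60, 2.50, 1.80, 3.1312, 2.65, 2.40,
                 2.70, 2.30, 2.10, 2.60, 1.90, 2.40,
                 2.80, 2.70, 2.40, 2.50, 2.60, 2.40,
                 1.60, 2.00, 2.40, 2.50, 2.30, 2.80,
                 2.30, 2.60, 2.10, 2.70, 2.50, 3.60,
                 2.30, 2.90, 2.70),
    ref_sd = c(0.15, 0.20, 0.15, 0.12, 0.46, 0.15, 0.14,
               0.16, 0.18, 0.13, 0.15, 0.12, 0.15,
               0.16, 0.25, 0.14, 0.14, 0.17, 0.14,
               0.12, 0.13, 0.15, 0.15, 0.13, 0.20,
               0.13, 0.14, 0.12, 0.15, 0.14, 0.30,
               0.20, 0.17, 0.25),
    effect = c(0.06, 0.05, 0.07, 0.04, 0.2969, 0.05, 0.08,
               0.12, 0.06, 0.04, 0.07, 0.04, 0.07,
               0.05, 0.06, 0.04, 0.07, 0.06, 0.07,
               0.02, 0.04, 0.07, 0.04, 0.08, 0.05,
               0.07, 0.08, 0.07, 0.08, 0.07, 0.05,
               0.05, 0.06, 0.05),
    onset = c(0.45, 0.60, 0.60, 0.60, 0, 0, 0.45,
              0, 0.45, 0.60, 0.60, 0.60, 0.60,
              0, 0, 0.60, 0.60, 0.60, 0.60,
              0.60, 0.60, 0.45, 0.60, 0.45, 0.60,
              0.60, 0.60, 0.45, 0.45, 0.45, 0,
              0.60, 0.45, 0.60),
    age_slope = c(-0.004, -0.003, -0.005, -0.002, -0.008, -0.004, -0.005,
                  -0.005, -0.004, -0.003, -0.004, -0.002, -0.004,
                  -0.005, -0.005, -0.003, -0.004, -0.004, -0.004,
                  -0.001, -0.003, -0.004, -0.004, -0.004, -0.004,
                  -0.005, -0.005, -0.004, -0.005, -0.004, -0.006,
                  -0.004, -0.004, -0.004)
  )
  # medial-temporal regions begin atrophy at severity 0 and floor early
  cort$span <- ifelse(cort$onset == 0, 0.55, 1 - cort$onset)
  sub <- data.frame(
    region = c("thalamus", "caudate", "putamen", "pallidum", "hippocampus",
               "amygdala", "accumbens", "ventraldc", "lateral_ventricle",
               "inf_lat_ventricle", "third_ventricle", "fourth_ventricle",
               "cc_anterior", "cc_mid_anterior", "cc_central",
               "cc_mid_posterior", "cc_posterior"),
    ref_mean = c(6800, 3400, 4600, 1700, 4097.9,
                 1500, 550, 3800, 12000,
                 400, 1100, 1900,
                 900, 450, 450,
                 450, 950),
    ref_sd = c(650, 420, 520, 250, 431.44,
               220, 110, 400, 5500,
               300, 450, 600,
               150, 100, 100,
               100, 160),
    effect = c(0.07, 0.04, 0.06, 0.08, 0.3069,
               0.18, 0.06, 0.06, 0,
               0, 0, 0,
               0.08, 0.08, 0.08,
               0.08, 0.08),
    onset = c(0.45, 0.60, 0.60, 0.60, 0,
              0, 0, 0.60, 0,
              0, 0, 0,
              0.60, 0.60, 0.60,
              0.60, 0.60),
    age_slope = c(-28, -8, -18, -4, -24,
                  -6, -2, -10, 320,
                  12, 18, 10,
                  -2, -1, -1,
                  -1, -2)
  )
  sub$span <- ifelse(sub$onset == 0, 0.55, 1 - sub$onset)
  # head size explains a share of normal volumetric variance; ventricles scale
  # weakly with eTIV
  sub$etiv_slope <- 0.6 * sub$ref_mean / 1.565e6
  region_atlas(cort, sub)
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("Region atlas:", sum(x$type == "thickness"), "cortical thickness +",
      sum(x$type == "volume"), "subcortical volume regions\n")
  cat("Largest disease effects:",
      paste(x$region[order(-x$effect)][1:4], collapse = ", "), "\n")
  invisible(x)
}

#' Feature-column helpers for a region atlas
#'
#' @param atlas a [region_atlas()].
#' @return Character vector of region (feature) names; `volume_regions()`
#'   returns only the volumetric subset (the features subject to head-size
#'   adjustment).
#' @export
atlas_regions <- function(atlas) atlas$region

#' @rdname atlas_regions
#' @export
volume_regions <- function(atlas) atlas$region[atlas$type == "volume"]
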