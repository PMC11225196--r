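#' Specification of a synthetic memory-clinic cohort
#'
#' Defines group sizes, demographics, amyloid status, latent disease
#' severity distributions, the minimal-atrophy subgroup, measurement noise
#' and the longitudinal progression model used by [generate_cohort()] and
#' [generate_followup()]. Defaults emulate an amyloid-stratified
#' memory-clinic cohort: 220 amyloid-negative cognitively normal (CN)
#' elderly, 106 amyloid-positive amnestic MCI (aMCI), 39 AD-dementia (DEM)
#' patients and 139 subjective-cognitive-decline (SCD) subjects.
#'
#' Latent severity `s` in `[0, 1]` expresses how far a subject lies along the
#' disease atrophy axis: CN subjects sit near 0, aMCI around 0.55, dementia
#' around 0.8. The SCD group is a two-component mixture of CN-like subjects
#' and milder "prodromal" subjects (mean severity about 0.32). A fraction of
#' aMCI subjects (default 14%) carries the minimal-atrophy phenotype: they
#' keep the aMCI label but draw severity from the CN distribution.
#'
#' Progression follows a Weibull-baseline proportional-hazards model with
#' log-hazard contributions from latent severity and amyloid positivity,
#' discretized to yearly visits; a GDS score of 3 marks the progression
#' event.
#'
#' @param n named integer vector of group sizes (`CN`, `aMCI`, `DEM`, `SCD`).
#' @param age per-group list of `c(mean, sd)` in years.
#' @param age_range truncation bounds for simulated ages (years).
#' @param sex_female per-group probability of female sex.
#' @param amyloid per-group probability of amyloid positivity (CN, aMCI, DEM).
#' @param scd_mix mixture weights of the SCD group, `c(cn_like, prodromal)`;
#'   must sum to 1.
#' @param scd_amyloid amyloid-positive probability per SCD mixture component.
#' @param severity per-group Beta shape parameters `c(shape1, shape2)` for
#'   latent severity; `scd_prodromal` is the prodromal SCD component.
#' @param minimal_atrophy_fraction fraction of aMCI subjects whose severity is
#'   drawn from the CN distribution (minimal-atrophy phenotype).
#' @param etiv `c(mean, sd)` of estimated total intracranial volume (mm^3).
#' @param noise_frac per-region measurement noise SD as a fraction of the
#'   atlas reference SD; must be positive.
#' @param ref_age reference age (years) about which atlas age slopes act.
#' @param hazard list with Weibull baseline rate `h0`, shape `shape`, and
#'   log-hazard coefficients `beta_severity`, `beta_amyloid`.
#' @param dropout yearly probability of leaving follow-up (censoring).
#' @param horizon follow-up horizon in years (yearly visit grid `1:horizon`).
#' @param seed default random seed used when `generate_cohort()` is called
#'   without one.
#' @return An object of class `cohort_spec` (a list).
#' @export
cohort_spec <- function(n = c(CN = 220, aMCI = 106, DEM = 39, SCD = 139),
                        age = list(CN = c(72.3, 4.4), aMCI = c(72.1, 4.6),
                                   DEM = c(68.5, 8.4), SCD = c(70.1, 5.7)),
                        age_range = c(60, 90),
                        sex_female = c(CN = 0.52, aMCI = 0.52,
                                       DEM = 0.36, SCD = 0.43),
                        amyloid = c(CN = 0, aMCI = 1, DEM = 0.78),
                        scd_mix = c(cn_like = 0.5, prodromal = 0.5),
                        scd_amyloid = c(cn_like = 0.18, prodromal = 0.45),
                        severity = list(CN = c(1.2, 10), aMCI = c(11, 9),
                                        DEM = c(16, 4),
                                        scd_prodromal = c(4, 8.5)),
                        minimal_atrophy_fraction = 0.14,
                        etiv = c(mean = 1.565e6, sd = 1.45e5),
                        noise_frac = 0.7,
                        ref_age = 72,
                        hazard = list(h0 = 0.038, shape = 0.45,
                                      beta_severity = 4.5,
                                      beta_amyloid = log(3.4)),
                        dropout = 0.04,
                        horizon = 8,
                        seed = 1L) {
  groups <- c("CN", "aMCI", "DEM", "SCD")
  if (!all(groups %in% names(n))) stop("n must name CN, aMCI, DEM, SCD")
  if (any(n < 0)) stop("group sizes must be >= 0")
  fr <- c(sex_female, amyloid, scd_mix, scd_amyloid,
          minimal_atrophy = minimal_atrophy_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(scd_mix) - 1) > 1e-8) stop("SCD mixture weights must sum to 1")
  if (noise_frac <= 0) stop("noise SD fraction must be > 0")
  if (any(unlist(hazard[c("h0", "shape")]) < 0)) {
    stop("hazard parameters must be non-negative")
  }
  spec <- list(n = n[groups], age = age, age_range = age_range,
               sex_female = sex_female, amyloid = amyloid,
               scd_mix = scd_mix, scd_amyloid = scd_amyloid,
               severity = severity,
               minimal_atrophy_fraction = minimal_atrophy_fraction,
               etiv = etiv, noise_frac = noise_frac, ref_age = ref_age,
               hazard = hazard, dropout = dropout, horizon = horizon,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:",
      paste(sprintf("%s=%d", names(x$n), x$n), collapse = ", "), "\n")
  cat("minimal-atrophy fraction (aMCI):", x$minimal_atrophy_fraction,
      "| SCD mixture:", paste(round(x$scd_mix, 2), collapse = "/"), "\n")
  invisible(x)
}

rbeta_trunc <- function(n, shape) stats::rbeta(n, shape[1], shape[2])

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic cross-sectional cohort
#'
#' Draws demographics, amyloid status and a latent disease severity per
#' subject, then generates the 51-region morphometry panel as
#' `ref_mean * (1 - effect * g(severity)) + age_slope * (age - ref_age) +
#' etiv_slope * (eTIV - mean_eTIV) + noise`, where `g` is the region's
#' staged trajectory (see [region_atlas()]) and the noise SD equals
#' `noise_frac` times the atlas reference SD. Minimal-atrophy aMCI subjects
#' keep the aMCI label but draw severity from the CN distribution.
#'
#' @param spec a [cohort_spec()].
#' @param atlas a [region_atlas()].
#' @param seed integer seed; defaults to `spec$seed`. Identical `(spec, atlas,
#'   seed)` yield identical output.
#' @return A list with components `measures` (data.frame: `subject_id`,
#'   `group`, `age`, `sex`, `amyloid_positive`, `eTIV` and one column per
#'   region) and `subjects` (same metadata plus the hidden ground truth
#'   `latent_severity` and `minimal_atrophy`, retained for recovery tests).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = c(CN = 20, aMCI = 10, DEM = 5,
#'                                             SCD = 10)), default_atlas())
#' head(cohort$subjects)
#' @export
generate_cohort <- function(spec, atlas, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(atlas, "region_atlas"))
  set.seed(as.integer(seed))
  groups <- rep(names(spec$n), times = spec$n)
  ntot <- length(groups)
  if (ntot == 0L) stop("empty cohort requested")
  id <- sprintf("S%04d", seq_len(ntot))

  age <- numeric(ntot)
  sex <- character(ntot)
  amyloid <- logical(ntot)
  sev <- numeric(ntot)
  minimal <- logical(ntot)
  for (g in names(spec$n)) {
    idx <- which(groups == g)
    if (!length(idx)) next
    a <- spec$age[[g]]
    age[idx] <- rnorm_trunc(length(idx), a[1], a[2],
                            spec$age_range[1], spec$age_range[2])
    sex[idx] <- ifelse(stats::runif(length(idx)) < spec$sex_female[[g]],
                       "F", "M")
    if (g == "SCD") {
      prodromal <- stats::runif(length(idx)) < spec$scd_mix[["prodromal"]]
      sev[idx[prodromal]] <- rbeta_trunc(sum(prodromal),
                                         spec$severity$scd_prodromal)
      sev[idx[!prodromal]] <- rbeta_trunc(sum(!prodromal), spec$severity$CN)
      p_ab <- ifelse(prodromal, spec$scd_amyloid[["prodromal"]],
                     spec$scd_amyloid[["cn_like"]])
      amyloid[idx] <- stats::runif(length(idx)) < p_ab
    } else {
      amyloid[idx] <- stats::runif(length(idx)) < spec$amyloid[[g]]
      if (g == "aMCI") {
        mini <- stats::runif(length(idx)) < spec$minimal_atrophy_fraction
        sev[idx[mini]] <- rbeta_trunc(sum(mini), spec$severity$CN)
        sev[idx[!mini]] <- rbeta_trunc(sum(!mini), spec$severity$aMCI)
        minimal[idx] <- mini
      } else {
        sev[idx] <- rbeta_trunc(length(idx), spec$severity[[g]])
      }
    }
  }
  etiv <- rnorm_trunc(ntot, spec$etiv[["mean"]], spec$etiv[["sd"]],
                      spec$etiv[["mean"]] - 4 * spec$etiv[["sd"]],
                      spec$etiv[["mean"]] + 4 * spec$etiv[["sd"]])

  meta <- data.frame(subject_id = id, group = groups, age = age, sex = sex,
                     amyloid_positive = amyloid, eTIV = etiv,
                     stringsAsFactors = FALSE)
  x <- matrix(NA_real_, ntot, nrow(atlas),
              dimnames = list(NULL, atlas$region))
  for (j in seq_len(nrow(atlas))) {
    r <- atlas[j, ]
    g <- pmin(1, pmax(0, (sev - r$onset) / r$span))
    mu <- r$ref_mean * (1 - r$effect * g) +
      r$age_slope * (age - spec$ref_age) +
      r$etiv_slope * (etiv - spec$etiv[["mean"]])
    x[, j] <- mu + stats::rnorm(ntot, 0, spec$noise_frac * r$ref_sd)
  }
  x[x <= 0] <- 1e-3  # physical measures stay positive
  measures <- cbind(meta, as.data.frame(x))
  subjects <- cbind(meta, latent_severity = sev, minimal_atrophy = minimal)
  list(measures = measures, subjects = subjects)
}

#' Generate longitudinal GDS follow-up for a set of subjects
#'
#' Progression times are drawn from a Weibull-baseline proportional-hazards
#' model, `S(t) = exp(-h0 * t^shape * exp(beta_severity * s +
#' beta_amyloid * amyloid))`, and discretized to the first yearly visit at
#' which the Global Deterioration Scale reaches 3. GDS trajectories are
#' non-decreasing (progression is absorbing): 2 before progression, 3 from
#' the progression visit onward. Non-progressors are censored at a random
#' last-observed visit determined by a yearly dropout probability.
#'
#' @param subjects the `subjects` table from [generate_cohort()] (needs
#'   `subject_id`, `latent_severity`, `amyloid_positive`).
#' @param spec a [cohort_spec()] carrying the hazard model and horizon.
#' @param seed integer seed; defaults to `spec$seed + 1`.
#' @return A data.frame in long format with columns `subject_id`, `visit`
#'   (years from baseline, on the yearly grid) and `gds`; one row per
#'   observed visit. The last row per subject defines `last_observed`.
#' @export
generate_followup <- function(subjects, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "cohort_spec"),
            all(c("subject_id", "latent_severity", "amyloid_positive") %in%
                  names(subjects)))
  hz <- spec$hazard
  if (any(unlist(hz[c("h0", "shape")]) < 0)) {
    stop("hazard parameters must be non-negative")
  }
  set.seed(as.integer(seed))
  n <- nrow(subjects)
  eta <- hz$beta_severity * subjects$latent_severity +
    hz$beta_amyloid * as.numeric(subjects$amyloid_positive)
  u <- stats::runif(n)
  t_prog <- if (hz$h0 == 0) rep(Inf, n) else
    (-log(u) / (hz$h0 * exp(eta)))^(1 / hz$shape)
  # yearly visit at which progression is first observed
  visit_prog <- ifelse(is.finite(t_prog), ceiling(t_prog), Inf)
  # administrative censoring: geometric dropout over the yearly grid
  last <- pmin(spec$horizon,
               1L + stats::rgeom(n, prob = max(spec$dropout, 1e-12)))
  rows <- lapply(seq_len(n), function(i) {
    # followed until progression (absorbing) or dropout, whichever first
    stop_at <- if (visit_prog[i] <= last[i]) visit_prog[i] else last[i]
    visits <- seq_len(stop_at)
    gds <- ifelse(visits >= visit_prog[i], 3L, 2L)
    data.frame(subject_id = subjects$subject_id[i], visit = visits,
               gds = gds, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
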