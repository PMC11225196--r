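test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(small_spec(), default_atlas(), seed = 7)
  b <- generate_cohort(small_spec(), default_atlas(), seed = 7)
  expect_identical(a, b)
  c <- generate_cohort(small_spec(), default_atlas(), seed = 8)
  expect_false(identical(a$measures, c$measures))
})

test_that("zero disease effects give equal group means up to noise", {
  atlas <- default_atlas()
  atlas$effect <- 0
  spec <- cohort_spec(n = c(CN = 400, aMCI = 400, DEM = 400, SCD = 0),
                      age = list(CN = c(72, 0.1), aMCI = c(72, 0.1),
                                 DEM = c(72, 0.1), SCD = c(72, 0.1)))
  co <- generate_cohort(spec, atlas, seed = 11)
  m <- co$measures
  for (r in c("hippocampus", "entorhinal", "superiorfrontal")) {
    se <- atlas$ref_sd[atlas$region == r] * spec$noise_frac / sqrt(400)
    means <- tapply(m[[r]], m$group, mean)
    expect_lt(max(means) - min(means), 5 * se)
  }
})

test_that("default atlas reproduces memory-clinic anchor means", {
  # CN ~ 3852.79 mm^3 / 2.95 mm, amyloid-positive aMCI ~ 3068.25 mm^3 /
  # 2.37 mm; tolerance two standard errors at the reference group size 91
  spec <- cohort_spec(n = c(CN = 3000, aMCI = 3000, DEM = 5, SCD = 5))
  co <- generate_cohort(spec, default_atlas(), seed = 5)
  m <- co$measures
  hip <- tapply(m$hippocampus, m$group, mean)
  ent <- tapply(m$entorhinal, m$group, mean)
  expect_lt(abs(hip[["CN"]] - 3852.79), 2 * 431.44 / sqrt(91))
  expect_lt(abs(hip[["aMCI"]] - 3068.25), 2 * 419.99 / sqrt(91))
  expect_lt(abs(ent[["CN"]] - 2.95), 2 * 0.46 / sqrt(91))
  expect_lt(abs(ent[["aMCI"]] - 2.37), 2 * 0.38 / sqrt(91))
})

test_that("raising a region's effect size lowers its dementia-group mean", {
  atlas1 <- default_atlas()
  atlas2 <- atlas1
  atlas2$effect[atlas2$region == "amygdala"] <-
    atlas1$effect[atlas1$region == "amygdala"] + 0.1
  spec <- cohort_spec(n = c(CN = 5, aMCI = 5, DEM = 300, SCD = 5))
  m1 <- generate_cohort(spec, atlas1, seed = 3)$measures
  m2 <- generate_cohort(spec, atlas2, seed = 3)$measures
  expect_lt(mean(m2$amygdala[m2$group == "DEM"]),
            mean(m1$amygdala[m1$group == "DEM"]))
  # identical noise draws: every expressed subject is strictly lowered
  expect_true(all(m2$amygdala[m2$group == "DEM"] <=
                    m1$amygdala[m1$group == "DEM"]))
})

test_that("volumes scale with eTIV as configured, thickness does not", {
  spec <- cohort_spec(n = c(CN = 800, aMCI = 0, DEM = 0, SCD = 0))
  co <- generate_cohort(spec, default_atlas(), seed = 13)
  m <- co$measures
  # partial correlation given age (CN only, so group is constant)
  pc <- function(v) {
    rv <- stats::resid(stats::lm(m[[v]] ~ m$age))
    re <- stats::resid(stats::lm(m$eTIV ~ m$age))
    stats::cor(rv, re)
  }
  expect_gt(pc("hippocampus"), 0.1)
  expect_gt(pc("thalamus"), 0.1)
  expect_lt(abs(pc("entorhinal")), 0.1)
})

test_that("minimal-atrophy aMCI subjects keep the label but not the atrophy", {
  co <- generate_cohort(cohort_spec(n = c(CN = 5, aMCI = 400, DEM = 5,
                                          SCD = 5)),
                        default_atlas(), seed = 19)
  s <- co$subjects[co$subjects$group == "aMCI", ]
  expect_gt(sum(s$minimal_atrophy), 0)
  expect_lt(mean(s$latent_severity[s$minimal_atrophy]), 0.2)
  expect_gt(mean(s$latent_severity[!s$minimal_atrophy]), 0.4)
})

test_that("follow-up respects the yearly grid, monotone GDS and horizon", {
  co <- make_cohort(seed = 2)
  spec <- small_spec()
  fu <- generate_followup(co$subjects[co$subjects$group == "SCD", ], spec,
                          seed = 21)
  expect_identical(fu, generate_followup(
    co$subjects[co$subjects$group == "SCD", ], spec, seed = 21))
  expect_true(all(fu$visit >= 1 & fu$visit <= spec$horizon))
  by_subj <- split(fu, fu$subject_id)
  expect_true(all(vapply(by_subj, function(d) {
    all(diff(d$visit) > 0) && all(diff(d$gds) >= 0)
  }, logical(1))))
})

test_that("a null hazard produces no progressors", {
  co <- make_cohort(seed = 3)
  spec <- small_spec(hazard = list(h0 = 0, shape = 0.45,
                                   beta_severity = 3, beta_amyloid = 1))
  fu <- generate_followup(co$subjects, spec, seed = 4)
  ev <- derive_events(fu)
  expect_identical(sum(ev$event), 0L)
})

test_that("the generative amyloid hazard ratio is recovered by the Cox fit", {
  # log-HR for amyloid is log(3.4) in the default spec; a large simulated
  # SCD cohort must recover it within the Wald 95% CI
  spec <- cohort_spec(n = c(CN = 0, aMCI = 0, DEM = 0, SCD = 4000))
  co <- generate_cohort(spec, default_atlas(), seed = 31)
  scd <- co$subjects
  fu <- generate_followup(scd, spec, seed = 32)
  ev <- derive_events(fu)
  ev <- ev[match(scd$subject_id, ev$subject_id), ]
  fit <- cox_fit(ev, data.frame(latent_severity = scd$latent_severity,
                                amyloid = as.numeric(scd$amyloid_positive)))
  row <- fit$table[fit$table$term == "amyloid", ]
  expect_gt(3.4, row$lower)
  expect_lt(3.4, row$upper)
  expect_lt(abs(row$hr - 3.4) / 3.4, 0.25)
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(scd_mix = c(cn_like = 0.4, prodromal = 0.4)),
               "sum to 1")
  expect_error(cohort_spec(noise_frac = 0), "> 0")
  expect_error(cohort_spec(hazard = list(h0 = -1, shape = 0.5,
                                         beta_severity = 1,
                                         beta_amyloid = 1)),
               "non-negative")
  atlas <- default_atlas()
  expect_error(region_atlas(atlas[atlas$type == "thickness", ][-1, ],
                            atlas[atlas$type == "volume", ]),
               "exactly 34")
})
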