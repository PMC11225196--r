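bilateral_table <- function() {
  data.frame(subject_id = c("a", "b"), age = c(70, 75),
             lh_hippocampus = c(4000, 3900), rh_hippocampus = c(3600, 3700),
             lh_entorhinal = c(3.1, 2.9), rh_entorhinal = c(2.9, 3.1))
}

test_that("hemisphere averaging takes the arithmetic mean and keeps metadata", {
  out <- average_hemispheres(bilateral_table())
  expect_equal(out$hippocampus, c(3800, 3800))
  expect_equal(out$entorhinal, c(3.0, 3.0))
  expect_equal(out$age, c(70, 75))
  # already-averaged tables pass through
  expect_identical(average_hemispheres(out), out)
  # symmetric input equals either hemisphere
  sym <- bilateral_table()
  sym$rh_hippocampus <- sym$lh_hippocampus
  expect_equal(average_hemispheres(sym)$hippocampus, sym$lh_hippocampus)
})

test_that("a missing hemisphere is reported by region name", {
  tab <- bilateral_table()
  tab$rh_entorhinal <- NULL
  expect_error(average_hemispheres(tab), "unpaired region.*entorhinal")
})

noiseless_volume_table <- function(n = 30, slope = 0.002, seed = 1) {
  set.seed(seed)
  etiv <- seq(1.3e6, 1.8e6, length.out = n)
  data.frame(subject_id = sprintf("s%02d", 1:n), age = runif(n, 60, 85),
             eTIV = etiv,
             hippocampus = 1200 + slope * etiv,
             thalamus = 5000 + 0.001 * etiv,
             entorhinal = rep(3, n))
}

test_that("eTIV slopes are recovered exactly on noiseless linear volumes", {
  tab <- noiseless_volume_table()
  fit <- fit_etiv_adjustment(tab, tab$subject_id,
                             volumes = c("hippocampus", "thalamus"))
  expect_equal(unname(fit$slopes["hippocampus"]), 0.002, tolerance = 1e-10)
  expect_equal(unname(fit$slopes["thalamus"]), 0.001, tolerance = 1e-10)
  # thickness features are exempt: no slope stored
  expect_false("entorhinal" %in% names(fit$slopes))
})

test_that("eTIV slopes on eTIV-independent volumes are near zero", {
  set.seed(42)
  n <- 2000
  tab <- data.frame(subject_id = as.character(1:n), age = runif(n, 60, 85),
                    eTIV = rnorm(n, 1.5e6, 1.5e5),
                    hippocampus = rnorm(n, 3800, 400))
  fit <- fit_etiv_adjustment(tab, tab$subject_id, volumes = "hippocampus")
  se <- 400 / (sd(tab$eTIV) * sqrt(n))
  expect_lt(abs(fit$slopes[["hippocampus"]]), 3 * se)
})

test_that("eTIV adjustment centers, decorrelates and is idempotent", {
  tab <- noiseless_volume_table()
  set.seed(6)
  # independent variation so the eTIV residuals are not constant
  tab$hippocampus <- tab$hippocampus + rnorm(nrow(tab), 0, 50)
  tab$thalamus <- tab$thalamus + rnorm(nrow(tab), 0, 80)
  vols <- c("hippocampus", "thalamus")
  fit <- fit_etiv_adjustment(tab, tab$subject_id, volumes = vols)
  adj <- apply_etiv_adjustment(tab, fit)
  # subject at the reference-mean eTIV is unchanged
  probe <- tab[1, ]
  probe$eTIV <- fit$ref_mean
  expect_equal(apply_etiv_adjustment(probe, fit)$hippocampus,
               probe$hippocampus)
  # OLS residuals are numerically uncorrelated with eTIV
  for (v in vols) expect_lt(abs(cor(adj[[v]], adj$eTIV)), 1e-10)
  # refitting on adjusted data yields zero slopes, so applying twice = once
  refit <- fit_etiv_adjustment(adj, adj$subject_id, volumes = vols)
  expect_lt(max(abs(refit$slopes)), 1e-10)
  expect_equal(apply_etiv_adjustment(adj, refit), adj)
  # thickness untouched
  expect_equal(adj$entorhinal, tab$entorhinal)
  expect_error(fit_etiv_adjustment(within(tab, eTIV <- 1.5e6),
                                   tab$subject_id, vols), "zero variance")
})

test_that("age detrending recovers the normative slope and preserves deficits", {
  set.seed(3)
  n <- 60
  age <- seq(60, 85, length.out = n)
  cn <- data.frame(subject_id = sprintf("cn%02d", 1:n), age = age,
                   eTIV = 1.5e6, entorhinal = 3.2 - 0.01 * age)
  dis <- cn
  dis$subject_id <- sprintf("d%02d", 1:n)
  dis$entorhinal <- dis$entorhinal - 0.4   # age-independent deficit
  fit <- fit_age_detrend(cn, cn$subject_id, "entorhinal")
  expect_equal(unname(fit$slopes["entorhinal"]), -0.01, tolerance = 1e-10)
  cn_d <- apply_age_detrend(cn, fit)
  dis_d <- apply_age_detrend(dis, fit)
  expect_lt(abs(.ols <- coef(lm(cn_d$entorhinal ~ cn_d$age))[2]), 1e-10)
  expect_equal(mean(cn_d$entorhinal) - mean(dis_d$entorhinal), 0.4,
               tolerance = 1e-10)
  # subject at the reference mean age is unchanged
  probe <- cn[which.min(abs(cn$age - fit$ref_mean)), ]
  probe$age <- fit$ref_mean
  expect_equal(apply_age_detrend(probe, fit)$entorhinal, probe$entorhinal)
  expect_error(fit_age_detrend(within(cn, age <- 70), cn$subject_id,
                               "entorhinal"), "zero age variance")
})

test_that("the scaler standardizes training data and round-trips", {
  co <- make_cohort(seed = 4)
  feats <- atlas_regions(default_atlas())
  sc <- fit_scaler(co$cn, feats)
  x <- apply_scaler(co$cn, sc)
  expect_lt(max(abs(colMeans(x))), 1e-12)
  expect_equal(unname(apply(x, 2, sd)), rep(1, length(feats)),
               tolerance = 1e-12)
  expect_identical(apply_scaler(co$cn, sc), x)
  # a subject at the training mean maps to the zero row
  probe <- co$cn[1, ]
  probe[feats] <- as.list(sc$center)
  expect_lt(max(abs(apply_scaler(probe, sc))), 1e-12)
  degenerate <- co$cn
  degenerate$hippocampus <- 1
  expect_error(fit_scaler(degenerate, feats), "zero-SD.*hippocampus")
})

test_that("the PCA screen flags planted outliers and only those", {
  co <- make_cohort(seed = 5, spec = small_spec(n = c(CN = 100, aMCI = 0,
                                                      DEM = 0, SCD = 0)))
  feats <- atlas_regions(default_atlas())
  rep0 <- pca_outlier_screen(co$cn, feats)
  expect_identical(sum(rep0$flagged), 0L)   # homogeneous group: no flags at 4 SD
  # displace one subject far along the first within-group eigenvector
  tab <- co$cn
  pc <- prcomp(scale(as.matrix(tab[, feats])))
  shift <- 10 * sd(pc$x[, 1]) * pc$rotation[, 1] *
    apply(tab[, feats], 2, sd)
  tab[3, feats] <- tab[3, feats] + as.list(shift)
  rep1 <- pca_outlier_screen(tab, feats)
  expect_true(rep1$flagged[rep1$subject_id == tab$subject_id[3]])
  expect_identical(sum(rep1$flagged), 1L)
  # infinite threshold flags nobody
  rep2 <- pca_outlier_screen(tab, feats, threshold = Inf)
  expect_identical(sum(rep2$flagged), 0L)
})

test_that("control matching is exact on sex and optimal on small instances", {
  cases <- data.frame(subject_id = c("c1", "c2"), age = c(70, 75),
                      sex = c("F", "M"))
  pool <- data.frame(subject_id = c("p1", "p2", "p3"),
                     age = c(69, 80, 75), sex = c("F", "F", "M"))
  expect_setequal(match_controls(pool, cases), c("p1", "p3"))
  # identical pool gives a perfect zero-difference match
  pool2 <- cases
  pool2$subject_id <- c("q1", "q2")
  m <- match_controls(pool2, cases)
  expect_setequal(m, c("q1", "q2"))
  # exhaustive-search oracle on random instances (case groups of size <= 5)
  set.seed(8)
  for (rep in 1:20) {
    nc <- sample(2:5, 1)
    cases_r <- data.frame(subject_id = paste0("c", 1:nc),
                          age = round(runif(nc, 60, 85), 1),
                          sex = sample(c("F", "M"), nc, replace = TRUE))
    np <- nc + sample(2:4, 1)
    pool_r <- data.frame(subject_id = paste0("p", 1:np),
                         age = round(runif(np, 60, 85), 1),
                         sex = sample(c("F", "M"), np, replace = TRUE))
    for (s in unique(cases_r$sex)) {
      deficit <- sum(cases_r$sex == s) - sum(pool_r$sex == s)
      if (deficit > 0) {
        extra <- data.frame(subject_id = paste0("x", s, seq_len(deficit)),
                            age = round(runif(deficit, 60, 85), 1), sex = s)
        pool_r <- rbind(pool_r, extra)
      }
    }
    matched <- match_controls(pool_r, cases_r)
    expect_identical(anyDuplicated(matched), 0L)
    achieved <- 0
    best_cost <- 0
    for (s in unique(cases_r$sex)) {
      ca <- sort(cases_r$age[cases_r$sex == s])
      po <- pool_r[pool_r$sex == s, ]
      picked <- sort(po$age[po$subject_id %in% matched])
      # within fixed sets the order-preserving pairing is optimal in 1-D
      achieved <- achieved + sum(abs(ca - picked))
      # exhaustive minimum over all control subsets and assignments
      idx_sets <- utils::combn(nrow(po), length(ca), simplify = FALSE)
      best_cost <- best_cost + min(vapply(idx_sets, function(ix) {
        min(vapply(combinat_perms(length(ca)), function(p) {
          sum(abs(ca - po$age[ix][p]))
        }, numeric(1)))
      }, numeric(1)))
    }
    expect_equal(achieved, best_cost, tolerance = 1e-9)
  }
  # missing sex in the pool is an error
  pool3 <- pool[pool$sex == "F", ]
  expect_error(match_controls(pool3, cases), "insufficient controls")
})
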