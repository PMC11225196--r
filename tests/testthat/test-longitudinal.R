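fu_row <- function(id, visits, gds) {
  data.frame(subject_id = id, visit = visits, gds = gds,
             stringsAsFactors = FALSE)
}

test_that("events are the first GDS crossing, otherwise censoring", {
  fu <- rbind(fu_row("a", 1:4, c(2, 2, 3, 3)),
              fu_row("b", 1:8, rep(2, 8)),
              fu_row("c", c(1, 3), c(3, 5)))
  ev <- derive_events(fu)
  ev <- ev[match(c("a", "b", "c"), ev$subject_id), ]
  expect_equal(ev$time, c(3, 8, 1))
  expect_equal(ev$event, c(1L, 0L, 1L))
  # unattainable threshold censors everyone
  ev8 <- derive_events(fu, gds_threshold = 8)
  expect_identical(sum(ev8$event), 0L)
  expect_error(derive_events(fu_row("x", 0, 2)), "non-positive")
})

test_that("confusion metrics reproduce hand arithmetic and partition n", {
  lab <- data.frame(subject_id = as.character(1:6),
                    label = c(rep("disease-like", 6)))
  ev <- data.frame(subject_id = as.character(1:6),
                   event = c(1, 1, 0, 0, 1, 0))
  cm <- confusion_metrics(lab, ev)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 0)
  expect_identical(cm$TP + cm$FP + cm$TN + cm$FN, cm$n)
  expect_error(confusion_metrics(lab[1:5, ], ev), "same subjects")
})

test_that("trapezoid AUC equals the Mann-Whitney count", {
  # fixed 6-subject instance with a tie
  sev <- c(0.2, 0.5, 0.5, 0.7, 0.9, 0.1)
  out <- c(0, 0, 1, 1, 1, 0)
  expect_equal(roc_curve(sev, out)$auc, mw_auc(sev, out))
  set.seed(30)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    s <- round(rnorm(n), sample(c(1, 2), 1))  # rounding forces ties
    o <- rbinom(n, 1, 0.4)
    if (length(unique(o)) < 2) next
    expect_equal(roc_curve(s, o)$auc, mw_auc(s, o), tolerance = 1e-12)
  }
  # perfect ranking
  expect_equal(roc_curve(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  # uninformative score: AUC near 1/2 at large n
  set.seed(31)
  o <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_curve(rnorm(4000), o)$auc - 0.5), 0.03)
  expect_error(roc_curve(1:4, rep(1, 4)), "both outcome classes")
})

test_that("DeLong comparison degenerates to p = 1 on identical scores", {
  set.seed(32)
  sev <- rnorm(50)
  out <- rbinom(50, 1, 0.5)
  expect_warning(res <- delong_test(sev, sev, out), "zero variance")
  expect_equal(res$p, 1)
  expect_equal(res$diff, 0)
  # informative vs pure-noise scores on a strong signal: small p
  out2 <- rep(c(0, 1), each = 100)
  good <- out2 + rnorm(200, sd = 0.3)
  noise <- rnorm(200)
  res2 <- delong_test(good, noise, out2)
  expect_lt(res2$p, 0.01)
  expect_gt(res2$auc1, res2$auc2)
  expect_gte(res2$var_diff, 0)
})

test_that("Kaplan-Meier equals empirical survival without censoring", {
  set.seed(33)
  times <- sample(1:8, 40, replace = TRUE)
  ev <- data.frame(subject_id = as.character(1:40), time = times,
                   event = rep(1L, 40))
  km <- km_curve(ev, rep("all", 40))
  emp <- vapply(km$table$time, function(t) mean(times > t), numeric(1))
  expect_equal(km$table$surv, emp, tolerance = 1e-12)
  expect_true(all(diff(km$table$surv) <= 0))
  expect_equal(max(km$table$surv), mean(times > min(times)))
})

test_that("log-rank is null on identical groups and detects real differences", {
  ev <- data.frame(subject_id = as.character(1:20),
                   time = rep(c(1, 2, 3, 4, 6), 4),
                   event = rep(c(1, 1, 0, 1, 0), 4))
  same <- log_rank(ev, rep(c("g1", "g2"), each = 10))
  # identical event patterns in both groups
  expect_lt(same$chisq, 1e-8)
  expect_equal(same$p, 1, tolerance = 1e-6)
  set.seed(34)
  n <- 400
  grp <- rep(c("lo", "hi"), each = n / 2)
  rate <- ifelse(grp == "hi", 0.4, 0.1)
  t_true <- rexp(n, rate)
  ev2 <- data.frame(subject_id = as.character(1:n),
                    time = pmin(t_true, 8),
                    event = as.integer(t_true <= 8))
  lr <- log_rank(ev2, grp)
  expect_lt(lr$p, 1e-6)
  expect_identical(lr$df, 1L)
})

test_that("Cox beta matches a grid-search partial-likelihood oracle", {
  # 6 subjects, binary covariate, no ties
  ev <- data.frame(subject_id = letters[1:6],
                   time = c(1.5, 2.1, 3.7, 4.2, 5.9, 7.3),
                   event = c(1, 1, 1, 0, 1, 1))
  xv <- c(1, 0, 1, 1, 0, 0)
  fit <- cox_fit(ev, data.frame(x = xv))
  # independent oracle: direct maximization of the Cox partial likelihood
  neg_logpl <- function(beta) {
    ll <- 0
    for (i in which(ev$event == 1)) {
      risk <- ev$time >= ev$time[i]
      ll <- ll + beta * xv[i] - log(sum(exp(beta * xv[risk])))
    }
    -ll
  }
  grid <- seq(-4, 4, by = 1e-4)
  beta_oracle <- grid[which.min(vapply(grid, neg_logpl, numeric(1)))]
  expect_equal(fit$table$coef, beta_oracle, tolerance = 1e-4)
  expect_true(fit$table$lower <= fit$table$hr &&
                fit$table$hr <= fit$table$upper)
  expect_gt(fit$table$hr, 0)
  expect_identical(fit$ties, "efron")
  expect_error(cox_fit(ev, data.frame(x = rep(1, 6))),
               "degenerate covariate")
})
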