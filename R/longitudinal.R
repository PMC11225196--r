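#' Derive progression events from GDS follow-up
#'
#' The progression event is the first yearly visit at which the Global
#' Deterioration Scale reaches the threshold (default 3, i.e. progression
#' to MCI or dementia); progression is absorbing, so later visits are
#' ignored. Subjects who never cross the threshold are censored at their
#' last observed visit.
#'
#' @param followup long-format follow-up table (`subject_id`, `visit`,
#'   `gds`), as from [generate_followup()].
#' @param gds_threshold GDS score defining progression (default 3).
#' @return data.frame with `subject_id`, `time` (years from baseline) and
#'   `event` (1 = progressed, 0 = censored).
#' @export
derive_events <- function(followup, gds_threshold = 3) {
  stopifnot(all(c("subject_id", "visit", "gds") %in% names(followup)))
  if (any(followup$visit <= 0)) stop("non-positive visit time")
  if (anyNA(followup$gds)) stop("missing GDS at an observed visit")
  out <- lapply(split(followup, followup$subject_id), function(d) {
    d <- d[order(d$visit), ]
    hit <- which(d$gds >= gds_threshold)
    if (length(hit)) {
      data.frame(subject_id = d$subject_id[1], time = d$visit[hit[1]],
                 event = 1L, stringsAsFactors = FALSE)
    } else {
      data.frame(subject_id = d$subject_id[1], time = max(d$visit),
                 event = 0L, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Confusion metrics of a baseline classification against progression
#'
#' Positive = `disease-like` label at baseline; condition-positive =
#' progression event at any observed time within the follow-up horizon
#' (censoring time is not weighted). Sensitivity is the fraction of
#' progressors labelled disease-like; specificity the fraction of
#' non-progressors labelled CN-like.
#'
#' @param labels data.frame with `subject_id` and `label`
#'   (`"disease-like"`/`"CN-like"`), as from [classify_subjects()] or
#'   [predict.severity_model()].
#' @param events data.frame with `subject_id` and `event`, as from
#'   [derive_events()].
#' @return An object of class `confusion_result`: list with `TP`, `FP`,
#'   `TN`, `FN`, `sensitivity`, `specificity`, `prevalence`, `n`.
#' @export
confusion_metrics <- function(labels, events) {
  if (!setequal(labels$subject_id, events$subject_id)) {
    stop("labels and events must cover the same subjects")
  }
  m <- merge(labels, events, by = "subject_id")
  pos <- m$label == "disease-like"
  ev <- m$event == 1
  res <- list(TP = sum(pos & ev), FP = sum(pos & !ev),
              TN = sum(!pos & !ev), FN = sum(!pos & ev))
  res$sensitivity <- res$TP / (res$TP + res$FN)
  res$specificity <- res$TN / (res$TN + res$FP)
  res$prevalence <- mean(ev)
  res$n <- nrow(m)
  class(res) <- "confusion_result"
  res
}

#' @export
print.confusion_result <- function(x, ...) {
  cat(sprintf("n = %d | TP %d FP %d TN %d FN %d\n", x$n, x$TP, x$FP,
              x$TN, x$FN))
  cat(sprintf("sensitivity %.1f%% | specificity %.1f%% | progression prevalence %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$prevalence))
  invisible(x)
}

#' ROC curve of the severity index against progression
#'
#' Threshold sweep over the observed severity values with trapezoidal AUC;
#' ties are handled in the Mann-Whitney convention (1/2 per tied pair), so
#' the AUC equals the normalized Mann-Whitney statistic between progressors
#' and non-progressors. Higher severity is taken to indicate higher
#' progression risk.
#'
#' @param severity numeric severity indices.
#' @param event 0/1 progression flags (both classes required).
#' @return An object of class `severity_roc`: list with `curve`
#'   (data.frame `threshold`, `tpr`, `fpr`), `auc` and the underlying
#'   `pROC::roc` object (`roc`).
#' @export
roc_curve <- function(severity, event) {
  event <- as.numeric(event)
  if (length(unique(event)) < 2) stop("both outcome classes required")
  r <- pROC::roc(response = event, predictor = as.numeric(severity),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  curve <- data.frame(threshold = r$thresholds,
                      tpr = r$sensitivities,
                      fpr = 1 - r$specificities)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  structure(list(curve = curve, auc = as.numeric(pROC::auc(r)), roc = r),
            class = "severity_roc")
}

#' @export
print.severity_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d thresholds)\n", x$auc, nrow(x$curve)))
  invisible(x)
}

#' @export
plot.severity_roc <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Compares the AUCs of two severity indices evaluated on the same
#' subjects and outcomes using DeLong's nonparametric method (placement
#' values / structural components), with a two-sided normal p-value and no
#' continuity correction. Identical rankings give a zero-variance
#' difference, reported as p = 1 with a warning.
#'
#' @param severity1,severity2 severity indices of the two models, same
#'   subjects in the same order.
#' @param event 0/1 progression flags.
#' @return An object of class `delong_result`: list with `auc1`, `auc2`,
#'   `diff`, `var_diff`, `z`, `p`.
#' @export
delong_test <- function(severity1, severity2, event) {
  event <- as.numeric(event)
  if (length(unique(event)) < 2) stop("both outcome classes required")
  r1 <- pROC::roc(event, as.numeric(severity1), levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  r2 <- pROC::roc(event, as.numeric(severity2), levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  a1 <- as.numeric(pROC::auc(r1))
  a2 <- as.numeric(pROC::auc(r2))
  v <- pROC::var(r1, method = "delong") + pROC::var(r2, method = "delong") -
    2 * pROC::cov(r1, r2, method = "delong")
  if (v <= .Machine$double.eps) {
    warning("zero variance of the AUC difference (identical rankings); p = 1")
    res <- list(auc1 = a1, auc2 = a2, diff = a1 - a2, var_diff = 0,
                z = 0, p = 1)
  } else {
    tst <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
    res <- list(auc1 = a1, auc2 = a2, diff = a1 - a2, var_diff = v,
                z = as.numeric(tst$statistic), p = tst$p.value)
  }
  class(res) <- "delong_result"
  res
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong paired AUC comparison: %.3f vs %.3f (diff %.3f)\n",
              x$auc1, x$auc2, x$diff))
  cat(sprintf("z = %.3f, two-sided p = %.4g\n", x$z, x$p))
  invisible(x)
}

#' DeLong variance of a single AUC
#'
#' @param severity numeric severity indices.
#' @param event 0/1 progression flags.
#' @return variance of the AUC estimate from DeLong structural components.
#' @export
delong_auc_variance <- function(severity, event) {
  r <- pROC::roc(as.numeric(event), as.numeric(severity), levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::var(r, method = "delong"))
}

#' Kaplan-Meier curves per classification group
#'
#' Product-limit estimator of progression-free survival per group.
#'
#' @param events data.frame with `time` and `event` (see [derive_events()]).
#' @param group group label per row of `events`.
#' @return An object of class `km_curve`: list with `table` (data.frame
#'   `group`, `time`, `n_risk`, `n_event`, `surv`) and the underlying
#'   `survival::survfit` object (`fit`).
#' @export
km_curve <- function(events, group) {
  group <- as.factor(group)
  if (any(table(group) == 0)) stop("empty group")
  fit <- survival::survfit(survival::Surv(events$time, events$event) ~ group)
  strata <- if (is.null(fit$strata)) {
    rep(levels(group)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  tab <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, fit = fit), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(x$fit, xlab = "years from baseline",
                 ylab = "progression-free survival", ...)
  invisible(x)
}

#' Log-rank test between classification groups
#'
#' @inheritParams km_curve
#' @return An object of class `logrank_result`: list with `chisq`, `df`,
#'   `p`.
#' @export
log_rank <- function(events, group) {
  group <- as.factor(group)
  if (sum(events$event) < 1) stop("log-rank needs at least one event")
  sd <- survival::survdiff(survival::Surv(events$time, events$event) ~ group)
  df <- length(sd$n) - 1L
  structure(list(chisq = sd$chisq, df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f (df = %d), p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Cox proportional-hazards model of progression
#'
#' Partial-likelihood fit via `survival::coxph` with the Efron tie-handling
#' approximation (yearly visit grids produce heavily tied event times),
#' Wald confidence intervals and p-values per covariate.
#'
#' @param events data.frame with `time` and `event`.
#' @param covariates data.frame of covariates (rows aligned with `events`);
#'   factors and logicals allowed. Constant covariates are rejected.
#' @param conf_level confidence level for hazard-ratio intervals.
#' @return An object of class `cox_result`: list with `table` (data.frame
#'   `term`, `coef`, `hr`, `lower`, `upper`, `se`, `z`, `p`), `ties`
#'   (`"efron"`) and the underlying `coxph` fit (`fit`).
#' @export
cox_fit <- function(events, covariates, conf_level = 0.95) {
  if (sum(events$event) < 1) stop("need at least one event")
  covariates <- as.data.frame(covariates)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2) {
      stop("degenerate covariate: ", nm)
    }
  }
  dat <- cbind(events[, c("time", "event")], covariates)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron",
                         control = survival::coxph.control(eps = 1e-8,
                                                           iter.max = 50))
  s <- summary(fit, conf.int = conf_level)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    lower = s$conf.int[, 3],
                    upper = s$conf.int[, 4],
                    se = s$coefficients[, "se(coef)"],
                    z = s$coefficients[, "z"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(!is.finite(tab$se)) || any(abs(tab$coef) > 15)) {
    warning("possible monotone likelihood (complete separation); ",
            "estimates unreliable")
  }
  structure(list(table = tab, ties = "efron", fit = fit,
                 conf_level = conf_level), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties):\n")
  tab <- x$table
  tab[, -1] <- round(tab[, -1], 4)
  print(tab)
  invisible(x)
}
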