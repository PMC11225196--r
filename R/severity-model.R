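#' Fit a deployable severity model (matching, preprocessing, OPLS, cutoff)
#'
#' Assembles the full atrophy-pattern classifier for one model flavor. In
#' order: (1) age/sex-matched controls are selected from the CN pool, one
#' per disease-group case; (2) head-size (eTIV) slopes are fitted on the
#' matched amyloid-negative CN subjects and applied to everyone; (3) age
#' detrending slopes are fitted on the full CN pool (the normative anchor)
#' and applied to everyone; (4) the unit-variance scaler and the OPLS-DA
#' model (CN = 0, disease = 1) are fitted on the matched training set;
#' (5) the smoothed-CDF maximum-separation cutoff is derived from the
#' fitted training scores; (6) optionally, disease-group training subjects
#' projected as CN-like (the minimal-atrophy phenotype) are removed and
#' steps 1-5 are refitted (`prune_passes` times, default 1); (7) the final
#' model is cross-validated with full per-fold refitting of the scaler and
#' the eTIV/age adjustments to avoid information leakage.
#'
#' @param cn data.frame of the CN pool (metadata + 51 feature columns, as
#'   from [generate_cohort()]`$measures`).
#' @param disease data.frame of the disease training group (aMCI or
#'   dementia).
#' @param features feature (region) names; default from [default_atlas()].
#' @param volumes volumetric feature subset receiving eTIV adjustment.
#' @param flavor `"dementia-based"` or `"aMCI-based"` (informational label).
#' @param n_ortho orthogonal OPLS components (default 1).
#' @param cv_k cross-validation folds (default 10).
#' @param prune_passes minimal-atrophy pruning passes (default 1; 0 skips
#'   pruning).
#' @param bandwidth cutoff smoothing bandwidth (default Silverman).
#' @param seed integer seed (cross-validation fold assignment).
#' @return An object of class `severity_model`: list with `flavor`,
#'   `preproc` (eTIV/age/scaler parameters), `opls`, `cutoff`, `cv`
#'   (`Q2`, `R2`, `sensitivity`, `specificity`, held-out scores),
#'   `matched_cn_ids`, `disease_ids`, `removed_ids`, `features`,
#'   `volumes`, `seed`.
#' @seealso [predict.severity_model()], [prune_minimal_atrophy()],
#'   [write_severity_model()]
#' @export
severity_model <- function(cn, disease,
                           features = atlas_regions(default_atlas()),
                           volumes = volume_regions(default_atlas()),
                           flavor = c("dementia-based", "aMCI-based"),
                           n_ortho = 1, cv_k = 10, prune_passes = 1,
                           bandwidth = NULL, seed = 1L) {
  flavor <- match.arg(flavor)
  if (!nrow(disease)) stop("schema error: empty disease table")
  .check_measure_table(cn, features)
  .check_measure_table(disease, features)
  fit <- .fit_bundle(cn, disease, features, volumes, n_ortho, bandwidth)
  removed <- character(0)
  pass <- 0L
  while (pass < prune_passes) {
    pass <- pass + 1L
    dis_sev <- fit$train_severity[fit$train_y == 1]
    cn_like <- names(dis_sev)[dis_sev < fit$cutoff$cutoff]
    if (!length(cn_like)) break
    keep <- !(disease$subject_id %in% c(removed, cn_like))
    if (!any(keep)) stop("pruning would empty the disease group")
    removed <- c(removed, cn_like)
    fit <- .fit_bundle(cn, disease[disease$subject_id %in%
                                     setdiff(disease$subject_id, removed), ],
                       features, volumes, n_ortho, bandwidth)
  }
  cv <- .bundle_cv(cn, fit, features, volumes, n_ortho, cv_k, seed)
  structure(list(flavor = flavor, preproc = fit$preproc, opls = fit$opls,
                 cutoff = fit$cutoff, cv = cv,
                 matched_cn_ids = fit$matched_cn_ids,
                 disease_ids = fit$disease_ids, removed_ids = removed,
                 train_severity = fit$train_severity,
                 train_y = fit$train_y,
                 features = features, volumes = volumes,
                 n_ortho = n_ortho, prune_passes = prune_passes,
                 seed = as.integer(seed)),
            class = "severity_model")
}

.check_measure_table <- function(table, features) {
  need <- c("subject_id", "age", "sex", "eTIV", features)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("schema error: missing columns ", paste(utils::head(miss, 5), collapse = ", "))
  }
  if (anyNA(table[, features])) stop("schema error: missing feature values")
  invisible(TRUE)
}

# one full fit: match -> eTIV adjust -> detrend -> scale -> OPLS -> cutoff
.fit_bundle <- function(cn, disease, features, volumes, n_ortho, bandwidth) {
  matched_ids <- match_controls(cn, disease)
  cn_matched <- cn[match(matched_ids, cn$subject_id), ]
  train <- rbind(cn_matched, disease)

  # eTIV slopes: matched amyloid-negative CN (fall back to all matched CN)
  etiv_ref <- cn_matched$subject_id
  if ("amyloid_positive" %in% names(cn_matched) &&
      sum(!cn_matched$amyloid_positive) >= 3) {
    etiv_ref <- cn_matched$subject_id[!cn_matched$amyloid_positive]
  }
  etiv <- fit_etiv_adjustment(train, etiv_ref, volumes)
  cn_adj <- apply_etiv_adjustment(cn, etiv)
  train_adj <- apply_etiv_adjustment(train, etiv)

  # age detrend: normative slopes from the full CN pool
  agefit <- fit_age_detrend(cn_adj, cn_adj$subject_id, features)
  train_adj <- apply_age_detrend(train_adj, agefit)

  scaler <- fit_scaler(train_adj, features)
  xtr <- apply_scaler(train_adj, scaler)
  y <- as.numeric(train$subject_id %in% disease$subject_id)
  fit <- opls(xtr, y, n_ortho = n_ortho)
  sev <- stats::setNames(fit$fitted, train$subject_id)
  cut <- max_separation_cutoff(sev[y == 0], sev[y == 1],
                               bandwidth = bandwidth)
  list(preproc = list(etiv = etiv, age = agefit, scaler = scaler),
       opls = fit, cutoff = cut,
       matched_cn_ids = matched_ids, disease_ids = disease$subject_id,
       train = train, train_y = y, train_severity = sev)
}

# honest CV: refit eTIV/age/scaler and OPLS on each training split
.bundle_cv <- function(cn, fit, features, volumes, n_ortho, k, seed) {
  train <- fit$train
  y <- fit$train_y
  set.seed(as.integer(seed))
  folds <- .stratified_folds(y, k)
  heldout <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (!any(!tr)) next
    dtr <- train[tr, ]
    dte <- train[!tr, ]
    cn_tr <- dtr$subject_id[y[tr] == 0]
    etiv_ref <- cn_tr
    if ("amyloid_positive" %in% names(dtr)) {
      ab_neg <- dtr$subject_id[y[tr] == 0 & !dtr$amyloid_positive]
      if (length(ab_neg) >= 3) etiv_ref <- ab_neg
    }
    etiv <- fit_etiv_adjustment(dtr, etiv_ref, volumes)
    dtr_a <- apply_etiv_adjustment(dtr, etiv)
    dte_a <- apply_etiv_adjustment(dte, etiv)
    agefit <- fit_age_detrend(dtr_a, cn_tr, features)
    dtr_a <- apply_age_detrend(dtr_a, agefit)
    dte_a <- apply_age_detrend(dte_a, agefit)
    scaler <- fit_scaler(dtr_a, features)
    m <- opls(apply_scaler(dtr_a, scaler), y[tr], n_ortho = n_ortho)
    heldout[!tr] <- predict(m, apply_scaler(dte_a, scaler))
  }
  ssy <- sum((y - mean(y))^2)
  lab <- heldout >= fit$cutoff$cutoff
  list(Q2 = 1 - sum((y - heldout)^2) / ssy, R2 = fit$opls$R2Y,
       k = k, folds = folds, heldout = heldout,
       sensitivity = mean(lab[y == 1]), specificity = mean(!lab[y == 0]),
       seed = as.integer(seed))
}

#' Remove minimal-atrophy training cases and retrain
#'
#' Projects the disease-group training subjects through the current model;
#' those classified CN-like (low severity despite the disease label, i.e.
#' the minimal-atrophy phenotype) are removed and the whole bundle —
#' control matching, preprocessing, OPLS and cutoff — is refitted on the
#' reduced set. Repeated `n_passes` times; `n_passes = 0` returns the model
#' unchanged.
#'
#' @param model a fitted [severity_model()].
#' @param cn,disease the original training tables.
#' @param n_passes pruning passes (default 1).
#' @return list with `model` (retrained [severity_model()]) and `removed`
#'   (character vector of pruned disease-group subject ids, the removal
#'   log).
#' @export
prune_minimal_atrophy <- function(model, cn, disease, n_passes = 1) {
  stopifnot(inherits(model, "severity_model"))
  if (n_passes == 0) return(list(model = model, removed = character(0)))
  refit <- severity_model(cn, disease, features = model$features,
                          volumes = model$volumes, flavor = model$flavor,
                          n_ortho = model$n_ortho, cv_k = model$cv$k,
                          prune_passes = n_passes, seed = model$seed)
  list(model = refit, removed = refit$removed_ids)
}

#' Project subjects through a severity model
#'
#' Applies the frozen preprocessing parameters (eTIV adjustment, age
#' detrending, training scaler), projects through the OPLS model and
#' classifies at the stored cutoff.
#'
#' @param object a [severity_model()].
#' @param newdata regional measure table (metadata + feature columns).
#' @param ... unused.
#' @return data.frame with `subject_id`, `severity`, `label`.
#' @export
predict.severity_model <- function(object, newdata, ...) {
  .check_measure_table(newdata, object$features)
  adj <- apply_etiv_adjustment(newdata, object$preproc$etiv)
  adj <- apply_age_detrend(adj, object$preproc$age)
  x <- apply_scaler(adj, object$preproc$scaler)
  sev <- predict(object$opls, x)
  classify_subjects(stats::setNames(sev, newdata$subject_id),
                    object$cutoff$cutoff)
}

#' @export
print.severity_model <- function(x, ...) {
  cat("Severity model (", x$flavor, ")\n", sep = "")
  cat(sprintf("  training: %d matched CN + %d disease (%d pruned as minimal atrophy)\n",
              length(x$matched_cn_ids), length(x$disease_ids),
              length(x$removed_ids)))
  cat(sprintf("  OPLS: 1 predictive + %d orthogonal; R2 = %.3f, %d-fold Q2 = %.3f\n",
              x$n_ortho, x$cv$R2, x$cv$k, x$cv$Q2))
  cat(sprintf("  cutoff = %.3f | CV sensitivity %.1f%%, specificity %.1f%%\n",
              x$cutoff$cutoff, 100 * x$cv$sensitivity,
              100 * x$cv$specificity))
  invisible(x)
}

#' @export
summary.severity_model <- function(object, ...) {
  out <- list(flavor = object$flavor,
              n_cn = length(object$matched_cn_ids),
              n_disease = length(object$disease_ids),
              n_removed = length(object$removed_ids),
              R2 = object$cv$R2, Q2 = object$cv$Q2,
              cutoff = object$cutoff$cutoff,
              cv_sensitivity = object$cv$sensitivity,
              cv_specificity = object$cv$specificity,
              top_weights = sort(abs(coef(object$opls)),
                                 decreasing = TRUE)[1:6])
  class(out) <- "summary.severity_model"
  out
}

#' @export
print.summary.severity_model <- function(x, ...) {
  cat(sprintf("Severity model (%s): %d CN + %d disease, %d pruned\n",
              x$flavor, x$n_cn, x$n_disease, x$n_removed))
  cat(sprintf("R2 = %.3f  Q2 = %.3f  cutoff = %.3f  CV sens/spec = %.1f%%/%.1f%%\n",
              x$R2, x$Q2, x$cutoff, 100 * x$cv_sensitivity,
              100 * x$cv_specificity))
  cat("Largest |weights|:\n")
  print(round(x$top_weights, 3))
  invisible(x)
}

#' Training-score CDF plot of a severity model
#'
#' Plots the smoothed cumulative distribution functions of the training CN
#' and disease severity scores with the maximum-separation cutoff.
#'
#' @param x a [severity_model()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.severity_model <- function(x, ...) {
  sev <- x$train_severity
  y <- x$train_y
  h <- x$cutoff$bandwidth
  grid <- seq(min(sev) - 3 * h, max(sev) + 3 * h, length.out = 400)
  f <- function(s) rowMeans(stats::pnorm(outer(grid, s, "-") / h))
  graphics::plot(grid, f(sev[y == 0]), type = "l", col = "steelblue",
                 xlab = "severity index", ylab = "smoothed CDF", ...)
  graphics::lines(grid, f(sev[y == 1]), col = "firebrick")
  graphics::abline(v = x$cutoff$cutoff, lty = 2)
  invisible(x)
}

#' Serialize / restore a severity model
#'
#' `write_severity_model()` writes a directory with the preprocessing
#' parameters (`preprocess.yaml`), the OPLS model (`opls.json`), the cutoff
#' (`cutoff.json`) and a training provenance CSV. `read_severity_model()`
#' restores a functionally identical model (prediction-equivalent).
#'
#' @param model a [severity_model()].
#' @param dir target directory (created if needed).
#' @return `write_severity_model()`: `dir`, invisibly.
#'   `read_severity_model()`: a `severity_model` object (without the
#'   cross-validation component, which is not serialized).
#' @export
write_severity_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- model$preproc
  yaml::write_yaml(list(
    flavor = model$flavor, n_ortho = model$n_ortho, seed = model$seed,
    etiv = list(slopes = as.list(pp$etiv$slopes), ref_mean = pp$etiv$ref_mean,
                reference_ids = pp$etiv$reference_ids),
    age = list(slopes = as.list(pp$age$slopes), ref_mean = pp$age$ref_mean),
    scaler = list(center = as.list(pp$scaler$center),
                  scale = as.list(pp$scaler$scale))
  ), file.path(dir, "preprocess.yaml"), precision = 15L)
  o <- model$opls
  jsonlite::write_json(list(
    w = o$w, p1 = o$p1, w_o = o$w_o, p_o = o$p_o, b = o$b,
    y_mean = o$y_mean, n_ortho = o$n_ortho, features = model$features
  ), file.path(dir, "opls.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(unclass(model$cutoff), file.path(dir, "cutoff.json"),
                       digits = NA, auto_unbox = TRUE)
  prov <- data.frame(
    subject_id = c(model$matched_cn_ids, model$disease_ids,
                   model$removed_ids),
    role = c(rep("matched_cn", length(model$matched_cn_ids)),
             rep("disease", length(model$disease_ids)),
             rep("removed_minimal_atrophy", length(model$removed_ids))))
  utils::write.csv(prov, file.path(dir, "provenance.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_severity_model
#' @export
read_severity_model <- function(dir) {
  pp <- yaml::read_yaml(file.path(dir, "preprocess.yaml"))
  oj <- jsonlite::read_json(file.path(dir, "opls.json"), simplifyVector = TRUE)
  cj <- jsonlite::read_json(file.path(dir, "cutoff.json"), simplifyVector = TRUE)
  prov <- utils::read.csv(file.path(dir, "provenance.csv"),
                          stringsAsFactors = FALSE)
  features <- oj$features
  o <- list(w = stats::setNames(unlist(oj$w), features),
            p1 = stats::setNames(unlist(oj$p1), features),
            w_o = matrix(unlist(oj$w_o), nrow = length(features)),
            p_o = matrix(unlist(oj$p_o), nrow = length(features)),
            b = oj$b, y_mean = oj$y_mean, n_ortho = oj$n_ortho)
  class(o) <- "opls"
  preproc <- list(
    etiv = list(slopes = unlist(pp$etiv$slopes), ref_mean = pp$etiv$ref_mean,
                reference_ids = unlist(pp$etiv$reference_ids)),
    age = list(slopes = unlist(pp$age$slopes), ref_mean = pp$age$ref_mean),
    scaler = list(center = unlist(pp$scaler$center),
                  scale = unlist(pp$scaler$scale), features = features))
  cut <- structure(as.list(cj), class = "cutoff_result")
  structure(list(flavor = pp$flavor, preproc = preproc, opls = o,
                 cutoff = cut,
                 matched_cn_ids = prov$subject_id[prov$role == "matched_cn"],
                 disease_ids = prov$subject_id[prov$role == "disease"],
                 removed_ids = prov$subject_id[prov$role ==
                                                 "removed_minimal_atrophy"],
                 features = features,
                 volumes = names(preproc$etiv$slopes),
                 n_ortho = pp$n_ortho, seed = pp$seed),
            class = "severity_model")
}
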